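#' Built-in ligand masses (average-mass cations)
#'
#' Small table of G4-binding ligand cations known to the package. Berberine,
#' a planar isoquinoline alkaloid cation, is the default ligand.
#'
#' @return Named numeric vector of average cation masses in Da.
#' @export
ligand_masses <- function() {
  c(berberine = 336.4)
}

resolve_ligand_mass <- function(ligand) {
  if (is.numeric(ligand)) {
    if (ligand <= 0) stop("ligand mass must be positive", call. = FALSE)
    return(unname(ligand))
  }
  tab <- ligand_masses()
  if (!ligand %in% names(tab))
    stop(sprintf("unknown ligand '%s'; give a numeric mass or one of: %s",
                 ligand, paste(names(tab), collapse = ", ")), call. = FALSE)
  unname(tab[[ligand]])
}

#' Define an electrospray ion species for a DNA-ammonium-ligand complex
#'
#' Describes a negative-mode ion [DNA + a NH4+ + b L+ - (z+a+b) H+]^z- : one
#' oligonucleotide retaining `a` ammonium cations and `b` ligand cations, at
#' net charge -z. Each retained cation displaces one additional proton, the
#' bookkeeping implied by ion formulas such as [S1+2NH4+-6H+]4-.
#'
#' @param z charge magnitude (negative mode), >= 1.
#' @param a number of retained ammonium cations (>= 0).
#' @param b number of retained ligand cations (>= 0).
#' @param ligand ligand name in [ligand_masses()] or a numeric cation mass (Da).
#' @return An object of class `"ion_species"`.
#' @examples
#' ion_species(z = 4, a = 2, b = 0)                  # [S1+2NH4-6H]4-
#' ion_species(z = 4, a = 0, b = 2, ligand = "berberine")
#' @export
ion_species <- function(z, a = 0L, b = 0L, ligand = "berberine") {
  if (z < 1L) stop("charge z must be >= 1", call. = FALSE)
  if (a < 0L || b < 0L) stop("adduct counts must be >= 0", call. = FALSE)
  structure(list(z = as.integer(z), a = as.integer(a), b = as.integer(b),
                 ligand_mass = resolve_ligand_mass(ligand)),
            class = "ion_species")
}

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("<ion_species> [M%s%s-%dH]%d-\n",
              if (x$a > 0) sprintf("+%dNH4", x$a) else "",
              if (x$b > 0) sprintf("+%dL", x$b) else "",
              x$z + x$a + x$b, x$z))
  invisible(x)
}

species_label <- function(sp) {
  sprintf("a%d_b%d_z%d", sp$a, sp$b, sp$z)
}

#' Theoretical m/z of a negative-mode complex ion
#'
#' m/z = (M + a m(NH4) + b M_L - (z + a + b) m(H)) / z: the neutral mass plus
#' retained cations, minus one proton per retained cation and one per unit of
#' net negative charge.
#'
#' @param M_oligo neutral oligonucleotide mass in Da (see [oligo_mass()]).
#' @param species an [ion_species()].
#' @param mode `"average"` (default) or `"monoisotopic"`.
#' @return m/z in thomson.
#' @examples
#' theoretical_mz(oligo_mass("GGGAGGGAAGGGAAGGG"), ion_species(z = 4, a = 2))
#' @export
theoretical_mz <- function(M_oligo, species, mode = c("average", "monoisotopic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(species, "ion_species"))
  if (M_oligo <= 0) stop("M_oligo must be positive", call. = FALSE)
  mH <- hydrogen_mass(mode)
  (M_oligo + species$a * nh4_mass(mode) + species$b * species$ligand_mass -
      (species$z + species$a + species$b) * mH) / species$z
}

#' Construct a centroided mass spectrum
#'
#' Peaks are sorted by m/z; intensities are normalized to percent of the base
#' peak unless `normalize = FALSE`, in which case they must already satisfy
#' 0 < I <= 100 with exactly one base peak at 100.
#'
#' @param mz numeric vector of peak positions (Th), distinct.
#' @param intensity numeric vector of positive intensities.
#' @param label spectrum label.
#' @param normalize normalize to percent of base peak (default TRUE).
#' @return Object of class `"mass_spectrum"` with fields `mz`,
#'   `rel_intensity` and `label`.
#' @export
mass_spectrum <- function(mz, intensity, label = "spectrum", normalize = TRUE) {
  if (length(mz) != length(intensity))
    stop("mz and intensity lengths differ", call. = FALSE)
  if (length(mz) > 0L) {
    if (any(intensity <= 0)) stop("intensities must be positive", call. = FALSE)
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
    if (any(diff(mz) <= 0)) stop("mz values must be distinct", call. = FALSE)
    if (normalize) {
      intensity <- 100 * intensity / max(intensity)
    } else if (abs(max(intensity) - 100) > 1e-9 || sum(intensity == max(intensity)) != 1L) {
      stop("non-normalized spectrum must have exactly one base peak at 100%",
           call. = FALSE)
    }
  }
  structure(list(mz = as.numeric(mz), rel_intensity = as.numeric(intensity),
                 label = label), class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("<mass_spectrum> %s: %d peaks", x$label, length(x$mz)))
  if (length(x$mz))
    cat(sprintf(", base peak at %.2f Th, range %.1f-%.1f Th",
                x$mz[which.max(x$rel_intensity)], min(x$mz), max(x$mz)))
  cat("\n")
  invisible(x)
}

#' Read a mass spectrum from a two-column CSV
#'
#' Expects columns (mz, intensity); intensities are normalized to percent of
#' the base peak.
#'
#' @param path CSV path.
#' @param label spectrum label (defaults to the file name).
#' @return A [mass_spectrum()].
#' @export
read_ms_csv <- function(path, label = basename(path)) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2L) stop("spectrum CSV needs two columns (mz, intensity)",
                         call. = FALSE)
  mass_spectrum(d[[1L]], d[[2L]], label = label)
}

#' Assign spectrum peaks to candidate ion species
#'
#' Greedy nearest-match assignment: candidate-peak pairs are considered in
#' order of increasing absolute m/z error (ties broken toward smaller ligand
#' count b), and a pair is accepted when both the peak and the species are
#' still unassigned and the error is within `tol`. Each species claims at
#' most one peak and each peak at most one species.
#'
#' @param spectrum a [mass_spectrum()].
#' @param oligo an [oligo()] or sequence string (gives the neutral mass).
#' @param candidates list of [ion_species()].
#' @param tol matching tolerance in Th (default 1.0, suited to broad ion-trap
#'   peaks at the 4- charge state).
#' @param mode mass mode passed to [theoretical_mz()].
#' @return Object of class `"peak_assignments"`: a data frame with one row per
#'   assigned peak (`peak`, `mz`, `rel_intensity`, `a`, `b`, `z`, `mz_theor`,
#'   `mz_error`) plus attribute `unassigned` (indices of unmatched peaks).
#' @export
assign_peaks <- function(spectrum, oligo, candidates, tol = 1.0,
                         mode = c("average", "monoisotopic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spectrum, "mass_spectrum"))
  if (length(candidates) == 0L) stop("empty candidate list", call. = FALSE)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  M <- oligo_mass(oligo, mode)

  theor <- vapply(candidates, function(sp) theoretical_mz(M, sp, mode), 0)
  pairs <- expand.grid(peak = seq_along(spectrum$mz),
                       cand = seq_along(candidates))
  pairs$err <- spectrum$mz[pairs$peak] - theor[pairs$cand]
  pairs <- pairs[abs(pairs$err) <= tol, , drop = FALSE]
  b_of <- vapply(candidates, `[[`, 0L, "b")
  pairs <- pairs[order(abs(pairs$err), b_of[pairs$cand]), , drop = FALSE]

  used_peak <- logical(length(spectrum$mz))
  used_cand <- logical(length(candidates))
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    p <- pairs$peak[k]; ci <- pairs$cand[k]
    if (used_peak[p] || used_cand[ci]) next
    used_peak[p] <- TRUE; used_cand[ci] <- TRUE
    sp <- candidates[[ci]]
    rows[[length(rows) + 1L]] <- data.frame(
      peak = p, mz = spectrum$mz[p], rel_intensity = spectrum$rel_intensity[p],
      a = sp$a, b = sp$b, z = sp$z, mz_theor = theor[ci], mz_error = pairs$err[k])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peak = integer(), mz = numeric(), rel_intensity = numeric(),
               a = integer(), b = integer(), z = integer(),
               mz_theor = numeric(), mz_error = numeric())
  out <- out[order(out$peak), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unassigned") <- which(!used_peak)
  class(out) <- c("peak_assignments", class(out))
  out
}

#' Construct a ligand-stoichiometry binding table
#'
#' Summed percent intensities keyed by ligand stoichiometry b = 0..3: the
#' free G-quadruplex ions and the 1:1, 1:2 and 1:3 complex ions, pooled over
#' charge states and ammonium counts.
#'
#' @param intensities numeric vector of length 4 (b = 0, 1, 2, 3), all >= 0,
#'   at least one > 0.
#' @return Object of class `"binding_table"`.
#' @examples
#' binding_table(c(30, 100, 75, 0))
#' @export
binding_table <- function(intensities) {
  x <- as.numeric(intensities)
  if (length(x) != 4L) stop("need 4 intensities (b = 0..3)", call. = FALSE)
  if (any(x < 0)) stop("intensities must be >= 0", call. = FALSE)
  if (all(x == 0)) stop("all-zero binding table", call. = FALSE)
  names(x) <- paste0("b", 0:3)
  structure(x, empty = FALSE, class = "binding_table")
}

#' @export
print.binding_table <- function(x, ...) {
  cat("<binding_table> summed rel. intensities (%):\n")
  print(unclass(x))
  invisible(x)
}

#' Binding table from peak assignments
#'
#' Sums the relative intensities of assigned peaks by ligand stoichiometry b,
#' pooling charge states and ammonium counts. Stoichiometries with no
#' assigned peak contribute 0. An empty assignment set yields an all-zero
#' table flagged with attribute `empty = TRUE` (and a warning); [ira()] on
#' such a table is an error.
#'
#' @param assignments a `"peak_assignments"` object from [assign_peaks()].
#' @return A [binding_table()].
#' @export
binding_table_from_assignments <- function(assignments) {
  stopifnot(inherits(assignments, "peak_assignments"))
  x <- vapply(0:3, function(b)
    sum(assignments$rel_intensity[assignments$b == b]), 0)
  if (all(x == 0)) {
    warning("no assigned peaks: binding table is all zero", call. = FALSE)
    names(x) <- paste0("b", 0:3)
    return(structure(x, empty = TRUE, class = "binding_table"))
  }
  binding_table(x)
}

#' Relative binding-affinity intensity ratio (IRa)
#'
#' IRa = [sum I(G+P) + sum I(G+2P) + sum I(G+3P)] /
#'       [sum I(G) + sum I(G+P) + sum I(G+2P) + sum I(G+3P)]:
#' the intensity of all DNA-ligand complex ions over the total of free and
#' complex ions in a native ESI mass spectrum, a dimensionless relative
#' binding-affinity statistic in [0, 1].
#'
#' @param table a [binding_table()].
#' @param round_to decimals for reporting (default 2).
#' @return IRa, rounded to `round_to` decimals.
#' @examples
#' ira(binding_table(c(30, 100, 75, 0)))   # 0.85
#' @export
ira <- function(table, round_to = 2L) {
  stopifnot(inherits(table, "binding_table"))
  total <- sum(table)
  if (total == 0) stop("undefined IRa: all-zero table", call. = FALSE)
  round(sum(table[2:4]) / total, round_to)
}
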