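#' Melting presets for the three measured buffer conditions
#'
#' Returns the built-in melting presets used by [gen_melting_curve()]:
#' `"KCl-free"` (G4 alone in 100 mM KCl, Tm 67 degC), `"KCl-berberine"`
#' (G4 + berberine 1:4 in KCl, Tm 77 degC) and `"LiCl-free"` (G4 in 100 mM
#' LiCl, a poorly stabilizing cation, Tm 37 degC). All presets use a van't
#' Hoff enthalpy of -200 kJ/mol, a typical value for a sharp three-tetrad
#' intramolecular transition, with gently sloping linear baselines.
#'
#' @return Named list of preset parameter lists (`Tm` degC, `dH` J/mol,
#'   baseline intercepts/slopes, default temperature grid).
#' @export
melt_presets <- function() {
  base <- list(dH = -200000,
               folded_intercept = 10, folded_slope = -0.012,
               unfolded_intercept = 2, unfolded_slope = -0.004)
  list(
    "KCl-free"      = c(base, list(Tm = 67, t_min = 20, t_max = 95)),
    "KCl-berberine" = c(base, list(Tm = 77, t_min = 20, t_max = 95)),
    "LiCl-free"     = c(base, list(Tm = 37, t_min = 10, t_max = 75))
  )
}

#' Generate a synthetic two-state melting curve
#'
#' Simulates a CD melting curve from the intramolecular two-state model:
#' theta(T) = K/(1+K) with ln K = -(dH/R)(1/T - 1/Tm_K), and
#' signal = unfolded(T) + (folded(T) - unfolded(T)) theta with linear
#' baselines. Gaussian noise with sd = `noise_sd` x transition amplitude is
#' added when `noise_sd > 0`. The generating parameters are attached as
#' attribute `"truth"`, so downstream normalization/fitting is a
#' parameter-recovery exercise.
#'
#' @param preset preset name (see [melt_presets()]) or a list with the same
#'   fields.
#' @param t_min,t_max,t_step temperature grid in degC (defaults from the
#'   preset; step 0.5).
#' @param noise_sd noise, as a fraction of the transition amplitude.
#' @param seed RNG seed (required semantics: same seed, same curve).
#' @param strand_concentration optional molar concentration recorded on the
#'   curve.
#' @return A [melting_curve()] with attribute `truth`.
#' @examples
#' raw <- gen_melting_curve("KCl-free", noise_sd = 0)
#' attr(raw, "truth")$Tm
#' @export
gen_melting_curve <- function(preset = "KCl-free", t_min = NULL, t_max = NULL,
                              t_step = 0.5, noise_sd = 0, seed = NULL,
                              strand_concentration = NA_real_) {
  p <- if (is.character(preset)) {
    ps <- melt_presets()
    if (!preset %in% names(ps))
      stop(sprintf("unknown preset '%s'", preset), call. = FALSE)
    ps[[preset]]
  } else preset
  if (is.null(t_min)) t_min <- p$t_min
  if (is.null(t_max)) t_max <- p$t_max

  tt <- seq(t_min, t_max, by = t_step)
  TK <- tt + 273.15
  Tm_K <- p$Tm + 273.15
  lnK <- -(p$dH / .R_GAS) * (1 / TK - 1 / Tm_K)
  theta <- exp(lnK) / (1 + exp(lnK))
  folded <- p$folded_intercept + p$folded_slope * tt
  unfolded <- p$unfolded_intercept + p$unfolded_slope * tt
  signal <- unfolded + (folded - unfolded) * theta

  amplitude <- abs((p$folded_intercept + p$folded_slope * p$Tm) -
                     (p$unfolded_intercept + p$unfolded_slope * p$Tm))
  warn <- character()
  if (p$Tm < t_min || p$Tm > t_max)
    warn <- "temperature grid does not bracket Tm"
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    signal <- signal + stats::rnorm(length(signal), 0, noise_sd * amplitude)
  }

  label <- if (is.character(preset)) preset else "custom"
  out <- melting_curve(tt, signal, label = label,
                       strand_concentration = strand_concentration)
  attr(out, "truth") <- list(preset = label, Tm = p$Tm, dH = p$dH,
                             theta = theta,
                             folded = c(p$folded_intercept, p$folded_slope),
                             unfolded = c(p$unfolded_intercept, p$unfolded_slope),
                             noise_sd = noise_sd, seed = seed,
                             warnings = warn)
  out
}

#' Build the candidate ion-species grid for peak assignment
#'
#' All combinations of charge state, retained ammonium count and ligand
#' stoichiometry.
#'
#' @param charges charge magnitudes to consider (default 3:5).
#' @param max_nh4 maximum retained ammonium ions (default 3).
#' @param max_ligand maximum ligand stoichiometry (default 3).
#' @param ligand ligand name or numeric cation mass.
#' @return List of [ion_species()].
#' @export
candidate_species <- function(charges = 3:5, max_nh4 = 3L, max_ligand = 3L,
                              ligand = "berberine") {
  grid <- expand.grid(z = charges, a = 0:max_nh4, b = 0:max_ligand)
  lapply(seq_len(nrow(grid)), function(i)
    ion_species(z = grid$z[i], a = grid$a[i], b = grid$b[i], ligand = ligand))
}

#' Generate a synthetic native ESI mass spectrum
#'
#' Lays down a Gaussian peak profile (FWHM `peak_fwhm`) at the theoretical
#' m/z of each requested species, then centroids the profile back to a peak
#' list by local-maximum detection with intensity-weighted centroiding.
#' Species whose centers fall within one FWHM of each other merge into a
#' single centroid; a warning is issued. Optional low-level baseline noise
#' peaks can be added below `noise_floor`.
#'
#' @param species_intensities list of `list(species = ion_species, intensity
#'   = percent)`; intensities in (0, 100] with exactly one equal to 100.
#' @param oligo an [oligo()] or sequence string.
#' @param peak_fwhm profile peak full width at half maximum in Th
#'   (default 0.6, a broad ion-trap peak).
#' @param mz_step profile grid step in Th.
#' @param n_noise_peaks number of spurious baseline peaks to add.
#' @param noise_floor maximum relative intensity of noise peaks (percent).
#' @param seed RNG seed for the noise peaks.
#' @param mode mass mode for [theoretical_mz()].
#' @return A [mass_spectrum()] with attribute `truth` (species, programmed
#'   intensities, theoretical m/z).
#' @export
gen_ms_spectrum <- function(species_intensities, oligo, peak_fwhm = 0.6,
                            mz_step = 0.02, n_noise_peaks = 0L,
                            noise_floor = 5, seed = NULL,
                            mode = c("average", "monoisotopic")) {
  mode <- match.arg(mode)
  ints <- vapply(species_intensities, `[[`, 0, "intensity")
  if (any(ints <= 0 | ints > 100) || sum(ints == 100) != 1L)
    stop("intensities must be in (0, 100] with exactly one base peak at 100",
         call. = FALSE)
  M <- oligo_mass(oligo, mode)
  centers <- vapply(species_intensities, function(s)
    theoretical_mz(M, s$species, mode), 0)
  if (any(diff(sort(centers)) < peak_fwhm))
    warning("species closer than one FWHM: peaks merge", call. = FALSE)

  sd <- peak_fwhm / (2 * sqrt(2 * log(2)))
  grid <- seq(min(centers) - 5, max(centers) + 5, by = mz_step)
  profile <- rep(0, length(grid))
  for (i in seq_along(centers))
    profile <- profile + ints[i] * exp(-(grid - centers[i])^2 / (2 * sd^2))

  # centroid: local maxima above a small floor, intensity-weighted position
  n <- length(grid)
  i <- 2:(n - 1L)
  peak_idx <- i[profile[i] > profile[i - 1L] & profile[i] >= profile[i + 1L] &
                  profile[i] > 0.2]
  mz <- vapply(peak_idx, function(k) {
    w <- abs(grid - grid[k]) <= peak_fwhm
    sum(grid[w] * profile[w]) / sum(profile[w])
  }, 0)
  intensity <- profile[peak_idx]

  if (n_noise_peaks > 0L) {
    if (!is.null(seed)) set.seed(seed)
    nmz <- stats::runif(n_noise_peaks, min(grid), max(grid))
    keep <- vapply(nmz, function(x) all(abs(x - mz) > peak_fwhm), TRUE)
    nmz <- nmz[keep]
    mz <- c(mz, nmz)
    intensity <- c(intensity, stats::runif(length(nmz), 0.2, noise_floor))
  }
  out <- mass_spectrum(mz, intensity, label = "synthetic ESI-MS")
  attr(out, "truth") <- list(species = lapply(species_intensities, `[[`,
                                              "species"),
                             intensities = ints, centers = centers,
                             peak_fwhm = peak_fwhm, seed = seed)
  out
}

#' Generate a synthetic CD spectrum for a given topology
#'
#' Sum of Gaussian bands: `"parallel"` has a positive band at 264 nm and a
#' negative band at 242 nm; `"antiparallel"` a positive band at 295 nm and a
#' negative band at 265 nm; `"mutant272"` (a non-G4 conformation control)
#' a single positive band at 272 nm. Optional Gaussian noise with
#' sd = `noise_sd` x maximum band amplitude.
#'
#' @param topology `"parallel"`, `"antiparallel"` or `"mutant272"`.
#' @param wl_min,wl_max,wl_step wavelength grid in nm (default 220-320 by 0.5).
#' @param amplitude scale factor applied to all bands (mdeg).
#' @param noise_sd noise as a fraction of the maximum band amplitude.
#' @param seed RNG seed.
#' @return A [cd_spectrum()] with attribute `truth` (band table).
#' @export
gen_cd_spectrum <- function(topology = c("parallel", "antiparallel", "mutant272"),
                            wl_min = 220, wl_max = 320, wl_step = 0.5,
                            amplitude = 1, noise_sd = 0, seed = NULL) {
  topology <- match.arg(topology)
  bands <- switch(topology,
    parallel     = data.frame(center = c(264, 242), amp = c(10, -5),
                              width = c(8, 7)),
    antiparallel = data.frame(center = c(295, 265), amp = c(8, -4),
                              width = c(8, 8)),
    mutant272    = data.frame(center = 272, amp = 4, width = 9))
  bands$amp <- bands$amp * amplitude

  wl <- seq(wl_min, wl_max, by = wl_step)
  y <- rep(0, length(wl))
  for (i in seq_len(nrow(bands)))
    y <- y + bands$amp[i] * exp(-(wl - bands$center[i])^2 / (2 * bands$width[i]^2))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(length(y), 0, noise_sd * max(abs(bands$amp)))
  }
  out <- cd_spectrum(wl, y, label = paste0("synthetic CD (", topology, ")"))
  attr(out, "truth") <- list(topology = topology, bands = bands,
                             noise_sd = noise_sd, seed = seed)
  out
}
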