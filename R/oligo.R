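#' Construct a DNA oligonucleotide
#'
#' Represents a single-stranded DNA oligonucleotide read 5'->3'. Input is
#' case-insensitive; the sequence is stored uppercase and must use only the
#' four-letter DNA alphabet.
#'
#' @param sequence character scalar over A/C/G/T (case-insensitive).
#' @param name optional label for the strand.
#' @return An object of class `"oligo"` with fields `name` and `sequence`.
#' @examples
#' s1 <- oligo("GGGAGGGAAGGGAAGGG", name = "S1")
#' nchar(s1$sequence)
#' @export
oligo <- function(sequence, name = "oligo") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("'sequence' must be a single character string", call. = FALSE)
  seq <- toupper(gsub("[[:space:]]", "", sequence))
  if (nchar(seq) == 0L)
    stop("empty sequence", call. = FALSE)
  if (grepl("[^ACGT]", seq))
    stop("invalid DNA alphabet: only A, C, G, T are allowed", call. = FALSE)
  structure(list(name = as.character(name), sequence = seq), class = "oligo")
}

#' @export
print.oligo <- function(x, ...) {
  cat(sprintf("<oligo> %s: 5'-%s-3' (%d nt)\n", x$name, x$sequence,
              nchar(x$sequence)))
  invisible(x)
}

as_oligo <- function(x, name = "oligo") {
  if (inherits(x, "oligo")) x else oligo(x, name = name)
}

#' Read oligonucleotides from a FASTA file
#'
#' Multi-record FASTA is supported; each record becomes one [oligo()].
#'
#' @param path path to a FASTA file of DNA sequences.
#' @return A named list of `"oligo"` objects.
#' @export
read_fasta_oligos <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no sequences in FASTA file", call. = FALSE)
  out <- lapply(seq_along(set), function(i)
    oligo(as.character(set[[i]]), name = names(set)[i]))
  names(out) <- names(set)
  out
}

## Elemental composition of internal deoxynucleotide residues
## (nucleoside 5'-monophosphate minus water), plus water itself.
## Order of atoms: C, H, N, O, P.
.residue_formula <- list(
  A = c(C = 10, H = 12, N = 5, O = 5, P = 1),
  C = c(C = 9,  H = 12, N = 3, O = 6, P = 1),
  G = c(C = 10, H = 12, N = 5, O = 6, P = 1),
  T = c(C = 10, H = 13, N = 2, O = 7, P = 1)
)
.water_formula <- c(C = 0, H = 2, N = 0, O = 1, P = 0)

.atomic_mass <- list(
  average      = c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, P = 30.973762),
  monoisotopic = c(C = 12, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, P = 30.97376151)
)

formula_mass <- function(formula, mode = c("average", "monoisotopic")) {
  mode <- match.arg(mode)
  m <- .atomic_mass[[mode]]
  sum(formula * m[names(formula)])
}

#' Neutral mass of a DNA oligonucleotide
#'
#' Computes the neutral molecular mass by accumulating per-residue elemental
#' compositions and adding one water: mass = sum(residues) + H2O. The residue
#' table uses phosphodiester residues (one phosphate per residue), which makes
#' the mass strictly additive under concatenation --
#' mass(s1 + s2) = mass(s1) + mass(s2) - mass(H2O).
#'
#' @param seq an [oligo()] or a plain sequence string.
#' @param mode `"average"` (default) or `"monoisotopic"` atomic masses.
#' @return Mass in daltons (numeric scalar).
#' @examples
#' oligo_mass("AT")
#' oligo_mass(oligo("GGGAGGGAAGGGAAGGG", "S1"))
#' @export
oligo_mass <- function(seq, mode = c("average", "monoisotopic")) {
  mode <- match.arg(mode)
  seq <- as_oligo(seq)
  bases <- strsplit(seq$sequence, "")[[1]]
  total <- .water_formula
  for (b in bases) total <- total + .residue_formula[[b]]
  formula_mass(total, mode)
}

## Masses of adduct species used by the native-MS module.
nh4_mass <- function(mode = c("average", "monoisotopic")) {
  formula_mass(c(C = 0, H = 4, N = 1, O = 0, P = 0), match.arg(mode))
}

hydrogen_mass <- function(mode = c("average", "monoisotopic")) {
  formula_mass(c(C = 0, H = 1, N = 0, O = 0, P = 0), match.arg(mode))
}
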