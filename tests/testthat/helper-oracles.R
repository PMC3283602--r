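# Independent oracles kept deliberately separate from the package internals.

# Elemental-composition mass oracle: accumulate C/H/N/O/P atom counts for a
# DNA strand built from nucleoside-monophosphate residues plus one water,
# then apply standard atomic masses.
oracle_atoms <- list(
  A = c(C = 10, H = 12, N = 5, O = 5, P = 1),
  C = c(C = 9,  H = 12, N = 3, O = 6, P = 1),
  G = c(C = 10, H = 12, N = 5, O = 6, P = 1),
  T = c(C = 10, H = 13, N = 2, O = 7, P = 1)
)
oracle_avg_mass  <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999,
                      P = 30.973762)
oracle_mono_mass <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                      O = 15.9949146221, P = 30.97376151)

oracle_formula <- function(seq, extra = c(C = 0, H = 2, N = 0, O = 1, P = 0)) {
  f <- extra   # one water by default
  for (b in strsplit(toupper(seq), "")[[1]]) f <- f + oracle_atoms[[b]]
  f
}

oracle_mass <- function(seq, mode = "average") {
  m <- if (mode == "average") oracle_avg_mass else oracle_mono_mass
  sum(oracle_formula(seq) * m)
}

# Regular-expression motif oracle: a putative-quadruplex substring must
# fully match G{m,} (loop G{m,}){3,}.
oracle_regex_ok <- function(subseq, min_tract = 3, loop_min = 1,
                            loop_max = 7) {
  pat <- sprintf("^G{%d,}([ACGT]{%d,%d}G{%d,}){3,}$",
                 min_tract, loop_min, loop_max, min_tract)
  grepl(pat, toupper(subseq), perl = TRUE)
}

# Brute-force oracle with the scanner's maximal-run semantics, built
# independently on run-length encoding: G-runs >= min_tract are tracts;
# consecutive tracts chain when the distance between them is within the
# loop bounds; a maximal chain of >= 4 tracts is one motif.
oracle_motif_spans <- function(seq, min_tract = 3, loop_min = 1,
                               loop_max = 7) {
  r <- rle(strsplit(toupper(seq), "")[[1]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths          # 0-based starts
  is_tract <- r$values == "G" & r$lengths >= min_tract
  ts <- starts[is_tract]; te <- ends[is_tract]
  out <- data.frame(start = integer(), end = integer())
  if (length(ts) == 0) return(out)
  chain_start <- 1
  for (k in seq_along(ts)) {
    gap_ok <- k < length(ts) &&
      (ts[k + 1] - te[k]) >= loop_min && (ts[k + 1] - te[k]) <= loop_max
    if (!gap_ok) {
      if (k - chain_start + 1 >= 4)
        out <- rbind(out, data.frame(start = ts[chain_start], end = te[k]))
      chain_start <- k + 1
    }
  }
  out
}

random_dna <- function(n, prob = c(0.2, 0.15, 0.45, 0.2)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}
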