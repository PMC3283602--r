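#' Scan a sequence for putative G-quadruplex motifs
#'
#' Finds runs of >= `min_tract` consecutive guanines (G-tracts) and groups
#' consecutive tracts whose intervening loops are `loop_min`..`loop_max`
#' nucleotides long. A maximal group of at least four tracts is reported as
#' one motif. Tracts are greedy maximal G-runs: a run of k >= `min_tract` Gs
#' is a single tract and is never split, so overlapping alternative motif
#' decompositions are not enumerated.
#'
#' @param seq an [oligo()] or plain sequence string.
#' @param min_tract minimum G-tract length (default 3).
#' @param loop_min,loop_max allowed loop-length bounds in nt (defaults 1 and 7).
#' @return A list of `"g4_motif"` objects, ordered 5'->3' by start. Each has
#'   fields `parent`, `tracts` (matrix of 0-based half-open start/end),
#'   `loops` (character), `n_tracts` and `min_tract_len`.
#' @examples
#' scan_g4_motifs("GGGAGGGAAGGGAAGGG")    # one 4-tract motif
#' scan_g4_motifs("GTGAGTGAAGTGAAGTG")    # none
#' @export
scan_g4_motifs <- function(seq, min_tract = 3L, loop_min = 1L, loop_max = 7L) {
  seq <- as_oligo(seq)
  if (min_tract < 2L) stop("'min_tract' must be >= 2", call. = FALSE)
  if (loop_min < 1L || loop_min > loop_max)
    stop("need 1 <= loop_min <= loop_max", call. = FALSE)

  s <- seq$sequence
  runs <- gregexpr(sprintf("G{%d,}", min_tract), s)[[1]]
  if (runs[1L] == -1L) return(list())
  start0 <- as.integer(runs) - 1L                      # 0-based
  end0 <- start0 + attr(runs, "match.length")          # half-open

  ## group consecutive runs with in-bound loop lengths; maximal groups only
  motifs <- list()
  i <- 1L
  n <- length(start0)
  while (i <= n) {
    j <- i
    while (j < n) {
      gap <- start0[j + 1L] - end0[j]
      if (gap < loop_min || gap > loop_max) break
      j <- j + 1L
    }
    if (j - i + 1L >= 4L) {
      idx <- i:j
      tracts <- cbind(start = start0[idx], end = end0[idx])
      loops <- substring(s, end0[idx[-length(idx)]] + 1L, start0[idx[-1L]])
      motifs[[length(motifs) + 1L]] <- structure(
        list(parent = seq,
             tracts = tracts,
             loops = loops,
             n_tracts = nrow(tracts),
             min_tract_len = min(tracts[, "end"] - tracts[, "start"])),
        class = "g4_motif")
    }
    i <- j + 1L
  }
  motifs
}

#' @export
print.g4_motif <- function(x, ...) {
  lens <- x$tracts[, "end"] - x$tracts[, "start"]
  cat(sprintf("<g4_motif> in %s: %d G-tracts (lengths %s), loops %s\n",
              x$parent$name, x$n_tracts, paste(lens, collapse = ","),
              paste(shQuote(x$loops, "cmd"), collapse = ",")))
  invisible(x)
}

#' Predicted tetrad layers of a G4 motif
#'
#' An intramolecular G-quadruplex stacks as many G-tetrad layers as its
#' shortest G-tract is long, and monovalent cations (K+, NH4+) occupy the
#' sites between adjacent layers, so a motif with minimum tract length L
#' predicts L layers and L - 1 interlayer cation sites. Native ESI-MS adduct
#' counts (retained ammonium ions) can be compared against the latter.
#'
#' @param motif a `"g4_motif"` from [scan_g4_motifs()].
#' @return A list with `layers` and `interlayer_cation_sites`.
#' @examples
#' m <- scan_g4_motifs("GGGAGGGAAGGGAAGGG")[[1]]
#' predicted_tetrad_layers(m)   # 3 layers, 2 cation sites
#' @export
predicted_tetrad_layers <- function(motif) {
  stopifnot(inherits(motif, "g4_motif"))
  layers <- as.integer(motif$min_tract_len)
  list(layers = layers, interlayer_cation_sites = layers - 1L)
}
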