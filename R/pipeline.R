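#' Run the end-to-end G-quadruplex characterization pipeline
#'
#' Orchestrates the stages of the characterization workflow on a single
#' configuration list: motif scanning, native-MS peak assignment and the IRa
#' binding statistic, CD topology classification, and melting thermodynamics
#' with a free-vs-bound stabilization report. Stages are independent: a
#' failure in one is recorded in the report and does not abort the others.
#' With fixed seeds the report is exactly reproducible.
#'
#' @param config a list with any of the sections below; omitted sections are
#'   skipped.
#' \describe{
#'   \item{sequence}{a sequence string, an [oligo()], or
#'     `list(fasta = path)`; optional `min_tract`, `loop_min`, `loop_max`.}
#'   \item{ms}{`list(csv = path)` or `list(simulate = list(intensities =
#'     c(b0, b1, b2, b3), a = 2, z = 4))`; optional `ligand`, `tol`,
#'     `charges`, `max_nh4`, `max_ligand`, `seed`.}
#'   \item{cd}{`list(csv = path)` or `list(simulate = "parallel")`; optional
#'     `window`.}
#'   \item{melting}{named sub-lists `free` and (optionally) `bound`, each
#'     `list(csv = path)` or `list(preset = "KCl-free")`; optional
#'     `noise_sd`, `seed`, `t_ref` (kelvin, default 340.15).}
#' }
#' @param out optional path: write the report as JSON.
#' @return Object of class `"run_report"`: per-stage results (`motifs`,
#'   `ms`, `cd`, `melting`), `config` echo, package `version` and a
#'   `timestamp`.
#' @examples
#' cfg <- list(
#'   sequence = "GGGAGGGAAGGGAAGGG",
#'   ms = list(simulate = list(intensities = c(30, 100, 75, 0))),
#'   cd = list(simulate = "parallel"),
#'   melting = list(free = list(preset = "KCl-free"),
#'                  bound = list(preset = "KCl-berberine")))
#' rep <- run_characterization(cfg)
#' rep$ms$ira
#' @export
run_characterization <- function(config, out = NULL) {
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  report <- list(config = config,
                 version = as.character(utils::packageVersion("g4char")),
                 timestamp = format(Sys.time(), tz = "UTC"))

  run_stage <- function(expr) {
    tryCatch(expr, error = function(e) list(error = conditionMessage(e)))
  }

  seq_obj <- NULL
  if (!is.null(config$sequence)) {
    report$motifs <- run_stage({
      sc <- config$sequence
      seq_obj <- if (is.list(sc) && !is.null(sc$fasta))
        read_fasta_oligos(sc$fasta)[[1L]]
      else as_oligo(if (is.list(sc)) sc$seq else sc, name = "query")
      motifs <- scan_g4_motifs(seq_obj,
                               min_tract = config$min_tract %||% 3L,
                               loop_min = config$loop_min %||% 1L,
                               loop_max = config$loop_max %||% 7L)
      list(sequence = seq_obj$sequence,
           n_motifs = length(motifs),
           motifs = lapply(motifs, function(m) {
             layers <- predicted_tetrad_layers(m)
             list(tracts = m$tracts, loops = m$loops,
                  n_tracts = m$n_tracts,
                  layers = layers$layers,
                  interlayer_cation_sites = layers$interlayer_cation_sites)
           }))
    })
  }

  if (!is.null(config$ms)) {
    report$ms <- run_stage({
      msc <- config$ms
      if (is.null(seq_obj)) stop("ms stage needs a sequence section")
      ligand <- msc$ligand %||% "berberine"
      spec <- if (!is.null(msc$csv)) read_ms_csv(msc$csv) else {
        sim <- msc$simulate
        ints <- sim$intensities
        z <- sim$z %||% 4L; a <- sim$a %||% 2L
        sp <- lapply(which(ints > 0), function(i)
          list(species = ion_species(z = z, a = a, b = i - 1L,
                                     ligand = ligand),
               intensity = ints[i]))
        gen_ms_spectrum(sp, seq_obj, seed = msc$seed %||% 1L)
      }
      cand <- candidate_species(charges = msc$charges %||% 3:5,
                                max_nh4 = msc$max_nh4 %||% 3L,
                                max_ligand = msc$max_ligand %||% 3L,
                                ligand = ligand)
      asn <- assign_peaks(spec, seq_obj, cand, tol = msc$tol %||% 1.0)
      tab <- suppressWarnings(binding_table_from_assignments(asn))
      base_b <- if (length(spec$mz)) {
        bp <- which.max(spec$rel_intensity)
        hit <- asn$b[asn$peak == bp]
        if (length(hit)) hit else NA_integer_
      } else NA_integer_
      list(n_peaks = length(spec$mz),
           n_assigned = nrow(asn),
           assignments = as.data.frame(asn),
           binding_table = as.numeric(tab),
           base_peak_ligands = base_b,
           dominant_complex = isTRUE(base_b >= 1L),
           ira = if (isTRUE(attr(tab, "empty"))) NA_real_ else ira(tab))
    })
  }

  if (!is.null(config$cd)) {
    report$cd <- run_stage({
      cdc <- config$cd
      spec <- if (!is.null(cdc$csv)) read_cd_csv(cdc$csv)
      else gen_cd_spectrum(cdc$simulate, noise_sd = cdc$noise_sd %||% 0,
                           seed = cdc$seed %||% 1L)
      call <- classify_topology(spec, window = cdc$window %||% 6)
      list(call = call$call, evidence = call$evidence)
    })
  }

  if (!is.null(config$melting)) {
    report$melting <- run_stage({
      mc <- config$melting
      t_ref <- mc$t_ref %||% 340.15
      fit_one <- function(sec) {
        curve <- if (!is.null(sec$csv)) read_melting_csv(sec$csv)
        else gen_melting_curve(sec$preset, noise_sd = mc$noise_sd %||% 0,
                               seed = mc$seed %||% 1L)
        vant_hoff_fit(normalize_curve(curve))
      }
      free <- fit_one(mc$free)
      res <- list(free = c(coef(free), r_squared = free$r_squared))
      if (!is.null(mc$bound)) {
        bound <- fit_one(mc$bound)
        st <- stabilization(free, bound, T_ref = t_ref)
        res$bound <- c(coef(bound), r_squared = bound$r_squared)
        res$stabilization <- list(ddH = st$ddH, ddS = st$ddS, ddG = st$ddG,
                                  dTm = st$dTm, T_ref = t_ref)
      }
      res
    })
  }

  class(report) <- "run_report"
  if (!is.null(out))
    jsonlite::write_json(unclass(report), out, auto_unbox = TRUE,
                         digits = NA, force = TRUE, pretty = TRUE)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_report <- function(x, ...) {
  cat("G-quadruplex characterization report (g4char", x$version, ")\n")
  if (!is.null(x$motifs)) {
    if (!is.null(x$motifs$error))
      cat("  motifs: ERROR -", x$motifs$error, "\n")
    else
      cat(sprintf("  motifs: %d found in %s\n", x$motifs$n_motifs,
                  x$motifs$sequence))
  }
  if (!is.null(x$ms)) {
    if (!is.null(x$ms$error)) cat("  ms: ERROR -", x$ms$error, "\n")
    else cat(sprintf("  ms: %d/%d peaks assigned, IRa = %s\n",
                     x$ms$n_assigned, x$ms$n_peaks, format(x$ms$ira)))
  }
  if (!is.null(x$cd)) {
    if (!is.null(x$cd$error)) cat("  cd: ERROR -", x$cd$error, "\n")
    else cat("  cd: topology", x$cd$call, "\n")
  }
  if (!is.null(x$melting)) {
    if (!is.null(x$melting$error))
      cat("  melting: ERROR -", x$melting$error, "\n")
    else {
      cat(sprintf("  melting: free Tm = %.1f degC", x$melting$free[["Tm"]]))
      if (!is.null(x$melting$stabilization))
        cat(sprintf(", dTm = %.1f degC, ddG = %.1f kJ/mol",
                    x$melting$stabilization$dTm, x$melting$stabilization$ddG))
      cat("\n")
    }
  }
  invisible(x)
}
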