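#' Construct a circular-dichroism spectrum
#'
#' @param wavelength strictly increasing wavelength grid in nm (>= 10 points;
#'   the 200-350 nm region is what topology classification uses).
#' @param ellipticity CD signal per wavelength (mdeg).
#' @param label spectrum label.
#' @return Object of class `"cd_spectrum"`.
#' @export
cd_spectrum <- function(wavelength, ellipticity, label = "cd") {
  wavelength <- as.numeric(wavelength)
  ellipticity <- as.numeric(ellipticity)
  if (length(wavelength) != length(ellipticity))
    stop("wavelength and ellipticity lengths differ", call. = FALSE)
  if (length(wavelength) < 10L)
    stop("spectrum too short: need >= 10 points", call. = FALSE)
  if (any(diff(wavelength) <= 0))
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  structure(list(wavelength = wavelength, ellipticity = ellipticity,
                 label = label), class = "cd_spectrum")
}

#' @export
print.cd_spectrum <- function(x, ...) {
  cat(sprintf("<cd_spectrum> %s: %d points, %.1f-%.1f nm\n", x$label,
              length(x$wavelength), min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' Read a CD spectrum from a two-column CSV (wavelength, ellipticity)
#'
#' @param path CSV path.
#' @param label spectrum label (defaults to the file name).
#' @return A [cd_spectrum()].
#' @export
read_cd_csv <- function(path, label = basename(path)) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2L) stop("CD CSV needs two columns (wavelength, ellipticity)",
                         call. = FALSE)
  cd_spectrum(d[[1L]], d[[2L]], label = label)
}

moving_average <- function(y, window) {
  if (window == 1L) return(y)
  n <- length(y)
  half <- (window - 1L) %/% 2L
  # shrink the window symmetrically at the edges
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(y[lo:hi])
  }, 0)
}

#' Detect positive maxima and negative minima in a CD spectrum
#'
#' The signal is smoothed with a centered moving average, then local maxima
#' with positive smoothed value and local minima with negative smoothed value
#' are reported at their grid wavelengths.
#'
#' @param spec a [cd_spectrum()].
#' @param smooth_window moving-average window in points (odd, default 5).
#' @return List with data frames `maxima` and `minima`, each with columns
#'   `wavelength` and `ellipticity` (smoothed value at the extremum).
#' @export
find_extrema <- function(spec, smooth_window = 5L) {
  stopifnot(inherits(spec, "cd_spectrum"))
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 1L || smooth_window %% 2L == 0L)
    stop("smooth_window must be odd and >= 1", call. = FALSE)
  if (smooth_window >= length(spec$wavelength))
    stop("smooth_window must be smaller than the grid", call. = FALSE)

  y <- moving_average(spec$ellipticity, smooth_window)
  n <- length(y)
  i <- 2:(n - 1L)
  is_max <- y[i] > y[i - 1L] & y[i] >= y[i + 1L] & y[i] > 0
  is_min <- y[i] < y[i - 1L] & y[i] <= y[i + 1L] & y[i] < 0
  list(
    maxima = data.frame(wavelength = spec$wavelength[i][is_max],
                        ellipticity = y[i][is_max]),
    minima = data.frame(wavelength = spec$wavelength[i][is_min],
                        ellipticity = y[i][is_min])
  )
}

#' Classify G-quadruplex topology from a CD spectrum
#'
#' Band-position rule: a parallel G-quadruplex shows its characteristic
#' positive maximum near 264 nm (with a negative band near 242 nm); an
#' antiparallel one shows the positive maximum near 295 nm. The call is
#' `"parallel"` if the global positive maximum of the smoothed spectrum lies
#' within `window` nm of `parallel_max`, `"antiparallel"` if within `window`
#' of `antiparallel_max`, and `"other"` otherwise (including spectra with no
#' positive signal anywhere). Classification is invariant under uniform
#' positive scaling of the signal.
#'
#' @param spec a [cd_spectrum()].
#' @param parallel_max,antiparallel_max diagnostic band positions in nm
#'   (defaults 264 and 295).
#' @param window half-width tolerance in nm (default 6: a 272-nm maximum,
#'   typical of a non-G4 conformation, is not called parallel).
#' @param smooth_window passed to [find_extrema()].
#' @return Object of class `"topology_call"`: list with `call` in
#'   \{"parallel", "antiparallel", "other"\} and `evidence` (detected
#'   positive-maximum and negative-minimum wavelengths, NA when absent).
#' @export
classify_topology <- function(spec, parallel_max = 264, antiparallel_max = 295,
                              window = 6, smooth_window = 5L) {
  stopifnot(inherits(spec, "cd_spectrum"))
  ext <- find_extrema(spec, smooth_window)

  pos_wl <- NA_real_; neg_wl <- NA_real_
  if (nrow(ext$maxima) > 0L)
    pos_wl <- ext$maxima$wavelength[which.max(ext$maxima$ellipticity)]
  if (nrow(ext$minima) > 0L)
    neg_wl <- ext$minima$wavelength[which.min(ext$minima$ellipticity)]

  call <- "other"
  if (!is.na(pos_wl)) {
    if (abs(pos_wl - parallel_max) <= window) call <- "parallel"
    else if (abs(pos_wl - antiparallel_max) <= window) call <- "antiparallel"
  }
  structure(list(call = call,
                 evidence = c(positive_max_nm = pos_wl,
                              negative_min_nm = neg_wl)),
            class = "topology_call")
}

#' @export
print.topology_call <- function(x, ...) {
  cat(sprintf("<topology_call> %s (positive max %s nm, negative min %s nm)\n",
              x$call,
              ifelse(is.na(x$evidence[1L]), "-", format(x$evidence[1L])),
              ifelse(is.na(x$evidence[2L]), "-", format(x$evidence[2L]))))
  invisible(x)
}
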