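## Gas constant, J/(mol K)
.R_GAS <- 8.314

#' Construct a thermal melting curve
#'
#' Temperature-resolved signal (typically CD ellipticity monitored at a fixed
#' wavelength, 264 nm for a parallel G-quadruplex) along a strictly
#' increasing temperature grid in degrees Celsius. For baseline
#' normalization and van't Hoff fitting the curve should have at least 15
#' points spanning at least 30 degrees.
#'
#' @param temperature temperatures in degC, strictly increasing.
#' @param signal observed signal at each temperature.
#' @param label curve label.
#' @param strand_concentration optional strand concentration (molar), used by
#'   [intramolecularity_check()].
#' @return Object of class `"melting_curve"`.
#' @export
melting_curve <- function(temperature, signal, label = "melt",
                          strand_concentration = NA_real_) {
  temperature <- as.numeric(temperature)
  signal <- as.numeric(signal)
  if (length(temperature) != length(signal))
    stop("temperature and signal lengths differ", call. = FALSE)
  if (length(temperature) < 2L || any(diff(temperature) <= 0))
    stop("temperature grid must be strictly increasing", call. = FALSE)
  structure(list(temperature = temperature, signal = signal, label = label,
                 strand_concentration = strand_concentration),
            class = "melting_curve")
}

#' @export
print.melting_curve <- function(x, ...) {
  cat(sprintf("<melting_curve> %s: %d points, %.1f-%.1f degC\n", x$label,
              length(x$temperature), min(x$temperature), max(x$temperature)))
  invisible(x)
}

#' Read a melting curve from a two-column CSV (temperature, signal)
#'
#' @param path CSV path.
#' @param label curve label (defaults to the file name).
#' @param strand_concentration optional molar strand concentration.
#' @return A [melting_curve()].
#' @export
read_melting_csv <- function(path, label = basename(path),
                             strand_concentration = NA_real_) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2L) stop("melting CSV needs two columns (temperature, signal)",
                         call. = FALSE)
  melting_curve(d[[1L]], d[[2L]], label = label,
                strand_concentration = strand_concentration)
}

window_fit <- function(curve, window) {
  sel <- curve$temperature >= window[1L] & curve$temperature <= window[2L]
  if (sum(sel) < 3L)
    stop("baseline window must contain at least 3 points", call. = FALSE)
  stats::lm(signal ~ temperature,
            data = data.frame(temperature = curve$temperature[sel],
                              signal = curve$signal[sel]))
}

#' Baseline-normalize a melting curve to fraction folded
#'
#' Fits linear baselines in a low-temperature window (folded state) and a
#' high-temperature window (unfolded state) and converts the signal to the
#' fraction folded theta(T) = (upper(T) - y(T)) / (upper(T) - lower(T)),
#' where upper/lower denote the baselines fitted in the upper/lower
#' temperature windows. The expression is self-orienting: theta -> 1 where
#' the signal follows the low-temperature baseline, regardless of the sign
#' of the melting transition.
#'
#' Because a two-state transition decays only exponentially, some folded
#' (or unfolded) fraction always leaks into baseline windows chosen inside
#' the measured span, which biases window-only baselines. By default the
#' window fits therefore serve as the initialization of a global fit of the
#' complete model -- two linear baselines plus a two-state van't Hoff
#' sigmoid -- and the refined baselines are used for normalization. Set
#' `refine = FALSE` for plain window-only baselines.
#'
#' @param raw a [melting_curve()].
#' @param lower_window,upper_window length-2 numeric ranges (degC) inside the
#'   curve's span, each containing >= 3 points, non-overlapping. Defaults:
#'   the lowest and highest 15 percent of the temperature span.
#' @param refine refine the baselines by a global two-state fit (default
#'   TRUE); falls back to the window fits with a warning if the global fit
#'   does not converge.
#' @return Object of class `"normalized_melt"`: `temperature_K`, `theta`,
#'   `label`, `strand_concentration`, plus the fitted `baselines`.
#' @export
normalize_curve <- function(raw, lower_window = NULL, upper_window = NULL,
                            refine = TRUE) {
  stopifnot(inherits(raw, "melting_curve"))
  tt <- raw$temperature
  if (length(tt) < 15L || diff(range(tt)) < 30)
    stop("curve too short for normalization: need >= 15 points over >= 30 degC",
         call. = FALSE)
  span <- range(tt)
  if (is.null(lower_window))
    lower_window <- c(span[1L], span[1L] + 0.15 * diff(span))
  if (is.null(upper_window))
    upper_window <- c(span[2L] - 0.15 * diff(span), span[2L])
  if (lower_window[2L] >= upper_window[1L])
    stop("baseline windows must not overlap", call. = FALSE)
  if (lower_window[1L] < span[1L] - 1e-9 || upper_window[2L] > span[2L] + 1e-9)
    stop("baseline windows must lie inside the temperature span", call. = FALSE)

  fit_lo <- window_fit(raw, lower_window)
  fit_hi <- window_fit(raw, upper_window)
  nd <- data.frame(temperature = tt)
  b_lo <- stats::predict(fit_lo, nd)
  b_hi <- stats::predict(fit_hi, nd)

  mid <- mean(span)
  amplitude <- abs(stats::predict(fit_hi, data.frame(temperature = mid)) -
                     stats::predict(fit_lo, data.frame(temperature = mid)))
  noise <- max(stats::sigma(fit_lo), stats::sigma(fit_hi))
  if (amplitude <= max(5 * noise, 1e-8 * max(abs(raw$signal), 1)))
    stop("no melting transition detected: baselines coincide within noise",
         call. = FALSE)

  c_lo <- stats::coef(fit_lo)
  c_hi <- stats::coef(fit_hi)
  if (refine) {
    ref <- refine_baselines(tt, raw$signal, c_lo, c_hi)
    if (is.null(ref)) {
      warning("global baseline refinement did not converge; ",
              "using window-only baselines", call. = FALSE)
    } else {
      c_lo <- ref$c_lo; c_hi <- ref$c_hi
    }
  }

  b_lo <- c_lo[[1L]] + c_lo[[2L]] * tt
  b_hi <- c_hi[[1L]] + c_hi[[2L]] * tt
  theta <- (b_hi - raw$signal) / (b_hi - b_lo)
  structure(list(temperature_K = tt + 273.15, theta = as.numeric(theta),
                 label = raw$label,
                 strand_concentration = raw$strand_concentration,
                 baselines = list(lower = c_lo, upper = c_hi)),
            class = "normalized_melt")
}

## Global fit of (linear folded baseline) + (linear unfolded baseline) +
## two-state van't Hoff sigmoid. Returns refined baseline coefficients, or
## NULL if the nonlinear fit fails to converge.
refine_baselines <- function(tt, y, c_lo, c_hi) {
  TK <- tt + 273.15
  theta0 <- ((c_hi[[1L]] + c_hi[[2L]] * tt) - y) /
    ((c_hi[[1L]] + c_hi[[2L]] * tt) - (c_lo[[1L]] + c_lo[[2L]] * tt))
  cross <- which(diff(sign(theta0 - 0.5)) != 0)
  Tm0 <- if (length(cross)) TK[cross[1L]] else stats::median(TK)
  start <- list(l0 = c_lo[[1L]], l1 = c_lo[[2L]],
                u0 = c_hi[[1L]], u1 = c_hi[[2L]],
                dH = -150000, TmK = Tm0)
  model_parts <- function(p) {
    th <- 1 / (1 + exp((p[["dH"]] / .R_GAS) * (1 / TK - 1 / p[["TmK"]])))
    bu <- p[["u0"]] + p[["u1"]] * tt
    bl <- p[["l0"]] + p[["l1"]] * tt
    list(th = th, bu = bu, bl = bl, mu = bu + (bl - bu) * th)
  }
  resid_fn <- function(p) y - model_parts(p)$mu
  jac_fn <- function(p) {   # Jacobian of the residuals (analytic)
    m <- model_parts(p)
    D <- m$bl - m$bu
    dth <- -m$th * (1 - m$th)
    -cbind(l0 = m$th, l1 = tt * m$th,
           u0 = 1 - m$th, u1 = tt * (1 - m$th),
           dH = D * dth * (1 / TK - 1 / p[["TmK"]]) / .R_GAS,
           TmK = D * dth * (p[["dH"]] / .R_GAS) / p[["TmK"]]^2)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn, jac = jac_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) return(NULL)
  co <- fit$par
  list(c_lo = c(co[["l0"]], co[["l1"]]), c_hi = c(co[["u0"]], co[["u1"]]),
       dH = co[["dH"]], Tm_K = co[["TmK"]])
}

#' @export
print.normalized_melt <- function(x, ...) {
  cat(sprintf("<normalized_melt> %s: %d points, theta %.3f-%.3f\n", x$label,
              length(x$theta), min(x$theta), max(x$theta)))
  invisible(x)
}

#' Fit the intramolecular two-state van't Hoff melting model
#'
#' For an intramolecular (unimolecular) two-state transition the folding
#' equilibrium constant is K(T) = theta / (1 - theta), and
#' ln K = -dH/(R T) + dS/R. A linear regression of ln K on 1/T over the
#' points with theta inside `theta_band` yields dH (van't Hoff enthalpy,
#' from the slope), dS (from the intercept) and Tm as the temperature where
#' the fitted ln K crosses zero (Tm = dH/dS in kelvin). Restricting theta to
#' a central band avoids the divergence of ln K where baselines dominate.
#'
#' @param curve a `"normalized_melt"` from [normalize_curve()].
#' @param theta_band inclusive theta interval used for the regression
#'   (default c(0.15, 0.85)). Theta is clipped to (0, 1) before ln K.
#' @return Object of class `"vanthoff"` with components `dH` (J/mol), `dS`
#'   (J/(mol K)), `Tm` (degC), `r_squared`, `n_points`, `diagnostics`
#'   (raw theta = 0.5 crossing, monotonicity warning), the regression `fit`,
#'   the in-band `data`, and `strand_concentration`.
#' @seealso [gibbs()], [stabilization()], [predict.vanthoff()]
#' @examples
#' raw <- gen_melting_curve("KCl-free", noise_sd = 0)
#' fit <- vant_hoff_fit(normalize_curve(raw))
#' coef(fit)
#' @export
vant_hoff_fit <- function(curve, theta_band = c(0.15, 0.85)) {
  stopifnot(inherits(curve, "normalized_melt"))
  th <- pmin(pmax(curve$theta, 1e-12), 1 - 1e-12)
  sel <- curve$theta >= theta_band[1L] & curve$theta <= theta_band[2L]
  if (sum(sel) < 5L)
    stop("insufficient transition: need >= 5 points with theta in the band",
         call. = FALSE)

  warnings <- character()
  if (any(diff(th[sel]) > 0))
    warnings <- c(warnings, "theta not monotone decreasing inside the band")

  d <- data.frame(inv_T = 1 / curve$temperature_K[sel],
                  lnK = log(th[sel] / (1 - th[sel])))
  fit <- stats::lm(lnK ~ inv_T, data = d)
  co <- stats::coef(fit)
  dH <- -co[["inv_T"]] * .R_GAS
  dS <- co[["(Intercept)"]] * .R_GAS
  Tm_K <- dH / dS
  if (!is.finite(Tm_K) || Tm_K <= 0) {
    warnings <- c(warnings, "ln K = 0 crossing outside the physical range")
    Tm_K <- NA_real_
  }

  # raw theta = 0.5 crossing by linear interpolation, for diagnostics
  raw_Tm <- NA_real_
  cross <- which(diff(sign(curve$theta - 0.5)) != 0)
  if (length(cross)) {
    i <- cross[1L]
    t1 <- curve$temperature_K[i]; t2 <- curve$temperature_K[i + 1L]
    y1 <- curve$theta[i]; y2 <- curve$theta[i + 1L]
    raw_Tm <- t1 + (0.5 - y1) * (t2 - t1) / (y2 - y1) - 273.15
  } else if (any(curve$theta == 0.5)) {
    raw_Tm <- curve$temperature_K[which(curve$theta == 0.5)[1L]] - 273.15
  }

  sst <- sum((d$lnK - mean(d$lnK))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  structure(list(dH = dH, dS = dS, Tm = Tm_K - 273.15,
                 r_squared = r2,
                 n_points = sum(sel),
                 diagnostics = list(raw_crossing_Tm = raw_Tm,
                                    warnings = warnings),
                 fit = fit,
                 data = data.frame(temperature_K = curve$temperature_K[sel],
                                   theta = curve$theta[sel]),
                 strand_concentration = curve$strand_concentration,
                 label = curve$label),
            class = "vanthoff")
}

#' Bundle externally obtained thermodynamic parameters
#'
#' Builds a minimal object usable wherever a fitted [vant_hoff_fit()] result
#' is accepted ([gibbs()] arithmetic, [stabilization()]), e.g. for published
#' (dH, dS) pairs.
#'
#' @param dH enthalpy in J/mol.
#' @param dS entropy in J/(mol K).
#' @param Tm optional melting temperature in degC.
#' @return Object of classes `"thermo_params"` and `"vanthoff"`.
#' @export
thermo_params <- function(dH, dS, Tm = NA_real_) {
  structure(list(dH = dH, dS = dS, Tm = Tm, r_squared = NA_real_,
                 n_points = NA_integer_,
                 diagnostics = list(raw_crossing_Tm = NA_real_,
                                    warnings = character()),
                 fit = NULL, data = NULL,
                 strand_concentration = NA_real_, label = "params"),
            class = c("thermo_params", "vanthoff"))
}

#' @export
print.vanthoff <- function(x, digits = 4, ...) {
  cat("Two-state van't Hoff melting fit\n")
  cat(sprintf("  dH = %s J/mol, dS = %s J/(mol K), Tm = %s degC\n",
              format(x$dH, digits = digits), format(x$dS, digits = digits),
              format(x$Tm, digits = digits)))
  if (!is.na(x$r_squared))
    cat(sprintf("  R^2 = %.6f on %d in-band points\n", x$r_squared, x$n_points))
  for (w in x$diagnostics$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @export
coef.vanthoff <- function(object, ...) {
  c(dH = object$dH, dS = object$dS, Tm = object$Tm)
}

#' @export
summary.vanthoff <- function(object, T_ref = 340.15, ...) {
  structure(list(fit = object, T_ref = T_ref,
                 dG = gibbs(object$dH, object$dS, T_ref, round_to = 4)),
            class = "summary.vanthoff")
}

#' @export
print.summary.vanthoff <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  dG(%.2f K) = %.4f kJ/mol\n", x$T_ref, x$dG))
  if (!is.na(x$fit$diagnostics$raw_crossing_Tm))
    cat(sprintf("  raw theta=0.5 crossing at %.2f degC\n",
                x$fit$diagnostics$raw_crossing_Tm))
  invisible(x)
}

#' Predicted fraction folded from a van't Hoff fit
#'
#' @param object a `"vanthoff"` fit.
#' @param newdata temperatures in degC (numeric vector); defaults to the
#'   fitted in-band temperatures.
#' @param ... unused.
#' @return Predicted theta values.
#' @export
predict.vanthoff <- function(object, newdata = NULL, ...) {
  TK <- if (is.null(newdata)) object$data$temperature_K else
    as.numeric(newdata) + 273.15
  lnK <- -object$dH / (.R_GAS * TK) + object$dS / .R_GAS
  K <- exp(lnK)
  K / (1 + K)
}

#' @export
residuals.vanthoff <- function(object, ...) {
  if (is.null(object$fit)) return(numeric())
  stats::residuals(object$fit)
}

#' @export
plot.vanthoff <- function(x, ...) {
  if (is.null(x$data)) stop("no data stored in this fit", call. = FALSE)
  tc <- x$data$temperature_K - 273.15
  graphics::plot(tc, x$data$theta, xlab = "temperature (degC)",
                 ylab = "fraction folded", main = x$label, ...)
  grid_t <- seq(min(tc) - 5, max(tc) + 5, length.out = 200)
  graphics::lines(grid_t, predict(x, grid_t))
  graphics::abline(h = 0.5, lty = 3)
  if (!is.na(x$Tm)) graphics::abline(v = x$Tm, lty = 3)
  invisible(x)
}

#' Simulate normalized melting curves from a fitted model
#'
#' Draws `nsim` replicate fraction-folded curves from the fitted two-state
#' model on the fit's temperature grid, adding Gaussian noise to theta.
#'
#' @param object a `"vanthoff"` fit with stored data.
#' @param nsim number of replicates.
#' @param seed optional RNG seed.
#' @param noise_sd standard deviation of added Gaussian noise on theta.
#' @param ... unused.
#' @return A data frame: `temperature_K` plus one `sim_i` column per replicate.
#' @export
simulate.vanthoff <- function(object, nsim = 1, seed = NULL, noise_sd = 0.02,
                              ...) {
  if (is.null(object$data)) stop("no data stored in this fit", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  TK <- object$data$temperature_K
  mu <- predict(object, TK - 273.15)
  out <- data.frame(temperature_K = TK)
  for (i in seq_len(nsim))
    out[[paste0("sim_", i)]] <- mu + stats::rnorm(length(TK), 0, noise_sd)
  out
}

#' Gibbs free energy from enthalpy and entropy
#'
#' dG(T_ref) = (dH - T_ref dS) / 1000, in kJ/mol.
#'
#' @param dH enthalpy in J/mol.
#' @param dS entropy in J/(mol K).
#' @param T_ref reference temperature in kelvin.
#' @param round_to decimals for reporting (default 1).
#' @return dG in kJ/mol.
#' @examples
#' gibbs(-2110.2, 35.3, 340.15)   # -14.1
#' @export
gibbs <- function(dH, dS, T_ref, round_to = 1L) {
  if (any(T_ref < 0)) stop("T_ref must be >= 0 kelvin", call. = FALSE)
  round((dH - T_ref * dS) / 1000, round_to)
}

#' Ligand-induced stabilization report
#'
#' Component-wise differences bound - free of the fitted thermodynamic
#' parameters: ddH (J/mol), ddS (J/(mol K)), ddG at `T_ref` (kJ/mol,
#' differenced at full precision before rounding) and dTm (degC).
#'
#' @param free,bound `"vanthoff"` fits (or [thermo_params()]) for the DNA
#'   alone and the DNA-ligand complex.
#' @param T_ref reference temperature in kelvin (default 340.15 K = 67 degC).
#' @return Object of class `"stabilization_report"`.
#' @examples
#' stabilization(thermo_params(-2110.2, 35.3, 67),
#'               thermo_params(-4201.0, 61.4, 77))
#' @export
stabilization <- function(free, bound, T_ref = 340.15) {
  stopifnot(inherits(free, "vanthoff"), inherits(bound, "vanthoff"))
  dG_free <- (free$dH - T_ref * free$dS) / 1000
  dG_bound <- (bound$dH - T_ref * bound$dS) / 1000
  structure(list(ddH = bound$dH - free$dH,
                 ddS = bound$dS - free$dS,
                 ddG = round(dG_bound - dG_free, 1L),
                 dTm = bound$Tm - free$Tm,
                 T_ref = T_ref,
                 dG_free = round(dG_free, 1L), dG_bound = round(dG_bound, 1L)),
            class = "stabilization_report")
}

#' @export
print.stabilization_report <- function(x, ...) {
  cat("Ligand-induced stabilization (bound - free)\n")
  cat(sprintf("  ddH = %.1f J/mol\n  ddS = %.1f J/(mol K)\n", x$ddH, x$ddS))
  cat(sprintf("  ddG(%.2f K) = %.1f kJ/mol\n", x$T_ref, x$ddG))
  cat(sprintf("  dTm = %.1f degC\n", x$dTm))
  invisible(x)
}

#' Concentration-independence (intramolecularity) check
#'
#' An intramolecular transition has a concentration-independent Tm: the check
#' passes when the maximum pairwise Tm difference across fits at distinct
#' strand concentrations is within `tol`.
#'
#' @param fits list of `"vanthoff"` fits, each carrying a strand
#'   concentration (from its source curve) or supplied via `concentrations`.
#' @param concentrations optional numeric vector overriding the fits'
#'   concentrations.
#' @param tol tolerance on Tm agreement in degC (default 1.0).
#' @return List with `intramolecular` (logical), `max_dTm` and a per-fit
#'   `table` of (concentration, Tm).
#' @export
intramolecularity_check <- function(fits, concentrations = NULL, tol = 1.0) {
  if (length(fits) < 2L)
    stop("need fits at >= 2 strand concentrations", call. = FALSE)
  if (is.null(concentrations))
    concentrations <- vapply(fits, `[[`, 0, "strand_concentration")
  if (anyNA(concentrations))
    stop("every fit needs a strand concentration", call. = FALSE)
  if (length(unique(concentrations)) < 2L)
    stop("concentrations must be distinct", call. = FALSE)
  Tm <- vapply(fits, `[[`, 0, "Tm")
  max_dTm <- max(Tm) - min(Tm)
  list(intramolecular = max_dTm <= tol,
       max_dTm = max_dTm,
       table = data.frame(concentration = concentrations, Tm = Tm))
}
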