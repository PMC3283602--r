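test_that("normalization recovers the generator's fraction folded", {
  # zero-slope baselines
  p <- list(Tm = 67, dH = -200000, folded_intercept = 10, folded_slope = 0,
            unfolded_intercept = 2, unfolded_slope = 0,
            t_min = 20, t_max = 95)
  raw <- gen_melting_curve(p)
  nc <- normalize_curve(raw)
  expect_lt(max(abs(nc$theta - attr(raw, "truth")$theta)), 1e-9)

  # sloping baselines (generator defaults)
  raw2 <- gen_melting_curve("KCl-free")
  nc2 <- normalize_curve(raw2)
  expect_lt(max(abs(nc2$theta - attr(raw2, "truth")$theta)), 0.01)

  # window-only baselines remain available and are close but biased
  nc3 <- normalize_curve(raw2, refine = FALSE)
  expect_lt(max(abs(nc3$theta - attr(raw2, "truth")$theta)), 0.1)
})

test_that("degenerate and invalid curves are rejected", {
  tt <- seq(20, 95, by = 0.5)
  expect_error(normalize_curve(melting_curve(tt, 2 + 0.01 * tt)),
               "no melting transition")
  expect_error(normalize_curve(melting_curve(seq(20, 40, 2), rnorm(11))),
               "too short")
  raw <- gen_melting_curve("KCl-free")
  expect_error(normalize_curve(raw, c(20, 60), c(55, 95)), "overlap")
  expect_error(normalize_curve(raw, c(10, 30), c(85, 95)), "span")
})

test_that("van't Hoff fit recovers preset parameters from noiseless curves", {
  for (case in list(list(p = "KCl-free", Tm = 67),
                    list(p = "KCl-berberine", Tm = 77),
                    list(p = "LiCl-free", Tm = 37))) {
    fit <- vant_hoff_fit(normalize_curve(gen_melting_curve(case$p)))
    expect_lt(abs(fit$Tm - case$Tm), 0.2)
    expect_lt(abs(fit$dH + 200000) / 200000, 0.01)
    expect_gt(fit$r_squared, 0.999)
    # slope/intercept consistency: dS = dH / Tm(K)
    expect_equal(fit$dS, fit$dH / (fit$Tm + 273.15), tolerance = 1e-6)
    # dG vanishes at Tm
    expect_lt(abs(gibbs(fit$dH, fit$dS, fit$Tm + 273.15, round_to = 6)), 1e-3)
  }
})

test_that("parameter recovery holds across a (Tm, dH) grid", {
  base <- melt_presets()[["KCl-free"]]
  for (Tm in c(40, 60, 85)) {
    for (dH in c(-100000, -250000, -400000)) {
      p <- list(Tm = Tm, dH = dH,
                folded_intercept = base$folded_intercept,
                folded_slope = base$folded_slope,
                unfolded_intercept = base$unfolded_intercept,
                unfolded_slope = base$unfolded_slope,
                t_min = max(Tm - 35, 5), t_max = Tm + 30)
      fit <- vant_hoff_fit(normalize_curve(gen_melting_curve(p)))
      expect_lt(abs(fit$Tm - Tm), 0.2)
      expect_lt(abs(fit$dH - dH) / abs(dH), 0.01)
    }
  }
})

test_that("noisy curves still localize Tm", {
  errs <- vapply(1:25, function(s) {
    raw <- gen_melting_curve("KCl-free", noise_sd = 0.02, seed = s)
    fit <- vant_hoff_fit(suppressWarnings(normalize_curve(raw)))
    fit$Tm - 67
  }, 0)
  expect_lt(median(abs(errs)), 0.5)
})

test_that("fit reports Tm at an exact theta = 0.5 grid point", {
  # Tm = 67.0 lies on the 0.5-degC grid, so theta(67) = 0.5 exactly
  raw <- gen_melting_curve("KCl-free")
  nc <- normalize_curve(raw)
  i <- which(nc$temperature_K == 67 + 273.15)
  expect_equal(nc$theta[i], 0.5, tolerance = 1e-9)
  fit <- vant_hoff_fit(nc)
  expect_equal(fit$Tm, 67, tolerance = 1e-6)
  expect_equal(fit$diagnostics$raw_crossing_Tm, 67, tolerance = 1e-6)
})

test_that("step-like curves give an insufficient-transition error", {
  tt <- seq(20, 95, by = 0.5)
  theta <- ifelse(tt < 60, 1, 0)
  nc <- structure(list(temperature_K = tt + 273.15, theta = theta,
                       label = "step", strand_concentration = NA_real_,
                       baselines = NULL), class = "normalized_melt")
  expect_error(vant_hoff_fit(nc), "insufficient transition")
})

test_that("Gibbs arithmetic reproduces the published thermodynamic table", {
  expect_identical(gibbs(-2110.2, 35.3, 340.15), -14.1)
  expect_identical(gibbs(-4201.0, 61.4, 340.15), -25.1)
  # T -> 0 limit: dG = dH / 1000
  expect_equal(gibbs(-5000, 123, 0), -5)
  # linear in both arguments (unrounded)
  h <- -3000; s <- 50; Tr <- 340.15
  expect_equal(gibbs(2 * h, 2 * s, Tr, round_to = 8),
               2 * gibbs(h, s, Tr, round_to = 8))
  expect_equal(gibbs(h + 1000, s, Tr, round_to = 8),
               gibbs(h, s, Tr, round_to = 8) + 1)
})

test_that("stabilization reproduces the published ligand-induced deltas", {
  free <- thermo_params(-2110.2, 35.3, Tm = 67)
  bound <- thermo_params(-4201.0, 61.4, Tm = 77)
  st <- stabilization(free, bound, T_ref = 340.15)
  expect_equal(st$ddH, -2090.8)
  expect_identical(st$ddG, -11.0)
  expect_equal(st$dTm, 10)
  expect_identical(st$dG_free, -14.1)
  expect_identical(st$dG_bound, -25.1)

  # identical fits give an all-zero report
  st0 <- stabilization(free, free)
  expect_equal(st0$ddH, 0); expect_equal(st0$ddS, 0)
  expect_identical(st0$ddG, 0); expect_equal(st0$dTm, 0)
})

test_that("intramolecularity check compares Tm across concentrations", {
  f10 <- thermo_params(-200000, -588, Tm = 67.0)
  f10$strand_concentration <- 10e-6
  f20 <- thermo_params(-200000, -588, Tm = 67.0)
  f20$strand_concentration <- 20e-6
  chk <- intramolecularity_check(list(f10, f20))
  expect_true(chk$intramolecular)
  expect_equal(chk$max_dTm, 0)

  f20b <- f20; f20b$Tm <- 65
  f10b <- f10; f10b$Tm <- 60
  chk2 <- intramolecularity_check(list(f10b, f20b))
  expect_false(chk2$intramolecular)
  expect_equal(chk2$max_dTm, 5)

  expect_error(intramolecularity_check(list(f10)), "2 strand concentrations")
})

test_that("vanthoff model methods are coherent", {
  fit <- vant_hoff_fit(normalize_curve(gen_melting_curve("KCl-free")))
  expect_named(coef(fit), c("dH", "dS", "Tm"))
  # predict: theta = 0.5 at Tm, monotone decreasing in T
  expect_equal(predict(fit, fit$Tm), 0.5, tolerance = 1e-9)
  th <- predict(fit, c(40, 60, 80))
  expect_true(all(diff(th) < 0))
  # residuals near zero for a noiseless curve
  expect_lt(max(abs(residuals(fit))), 1e-6)
  # simulate is seed-reproducible
  s1 <- simulate(fit, nsim = 2, seed = 3)
  s2 <- simulate(fit, nsim = 2, seed = 3)
  expect_identical(s1, s2)
  sm <- summary(fit)
  expect_s3_class(sm, "summary.vanthoff")
  expect_equal(sm$dG, gibbs(fit$dH, fit$dS, 340.15, round_to = 4))
})

test_that("melting CSV reader round-trips a generated curve", {
  raw <- gen_melting_curve("KCl-free")
  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(temperature = raw$temperature, signal = raw$signal),
            csv, row.names = FALSE)
  rd <- read_melting_csv(csv, strand_concentration = 1e-5)
  fit <- vant_hoff_fit(normalize_curve(rd))
  expect_lt(abs(fit$Tm - 67), 0.2)
  expect_equal(rd$strand_concentration, 1e-5)
})
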