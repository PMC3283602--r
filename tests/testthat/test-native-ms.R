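S1 <- "GGGAGGGAAGGGAAGGG"

test_that("theoretical m/z matches the full-adduct elemental oracle", {
  # [S1 + 2 NH4 - 6 H]4-: add 2 x NH4 and remove 6 x H from the neutral
  # formula, then divide the adduct mass by the charge
  f <- oracle_formula(S1)
  f["N"] <- f["N"] + 2; f["H"] <- f["H"] + 2 * 4 - 6
  want <- sum(f * oracle_avg_mass) / 4
  got <- theoretical_mz(oligo_mass(S1), ion_species(z = 4, a = 2, b = 0))
  expect_equal(got, want)

  # singly deprotonated ion
  expect_equal(theoretical_mz(1000, ion_species(z = 1)), 1000 - 1.008)
  # each extra ligand shifts m/z by (M_L - m_H)/z at fixed z and a
  m1 <- theoretical_mz(5000, ion_species(z = 4, a = 2, b = 1))
  m2 <- theoretical_mz(5000, ion_species(z = 4, a = 2, b = 2))
  expect_equal(m2 - m1, (336.4 - 1.008) / 4)
  expect_error(ion_species(z = 0), "charge")
})

test_that("charge series recovers a consistent adduct mass", {
  M <- oligo_mass(S1)
  for (a in 0:2) for (b in 0:2) {
    recovered <- vapply(3:6, function(z) {
      sp <- ion_species(z = z, a = a, b = b)
      z * (theoretical_mz(M, sp) + 1.008)
    }, 0)
    expect_lt(max(recovered) - min(recovered), 1e-6)
  }
})

test_that("peak assignment round-trips and respects the tolerance", {
  specs <- list(list(species = ion_species(4, 2, 0), intensity = 30),
                list(species = ion_species(4, 2, 1), intensity = 100),
                list(species = ion_species(4, 2, 2), intensity = 75))
  sp <- gen_ms_spectrum(specs, S1)
  cand <- candidate_species(charges = 3:5)
  asn <- assign_peaks(sp, S1, cand, tol = 0.5)
  expect_equal(nrow(asn), 3L)
  expect_equal(sort(asn$b), 0:2)
  expect_true(all(abs(asn$mz_error) < 0.05))
  expect_length(attr(asn, "unassigned"), 0L)

  shifted <- mass_spectrum(sp$mz + 5, sp$rel_intensity, normalize = FALSE)
  asn5 <- assign_peaks(shifted, S1, cand, tol = 0.5)
  expect_equal(nrow(asn5), 0L)
  expect_length(attr(asn5, "unassigned"), 3L)

  expect_error(assign_peaks(sp, S1, list(), tol = 0.5), "empty")
  expect_error(assign_peaks(sp, S1, cand, tol = 0), "tol")
})

test_that("assignment picks the closest candidate, ties toward smaller b", {
  M <- oligo_mass(S1)
  c1 <- ion_species(4, 2, 0)
  c2 <- ion_species(4, 2, 1)
  mz1 <- theoretical_mz(M, c1)
  mz2 <- theoretical_mz(M, c2)

  # one peak nearer to c2 than to c1 (both within a huge tolerance)
  peak <- mz2 + 0.1
  sp <- mass_spectrum(peak, 100)
  asn <- assign_peaks(sp, S1, list(c1, c2), tol = abs(peak - mz1) + 1)
  # brute force: the pair with minimal |error| wins
  expect_equal(asn$b, which.min(c(abs(peak - mz1), abs(peak - mz2))) - 1L)
  expect_equal(asn$b, 1L)

  # midpoint peak: brute-force oracle (min |error|, ties toward smaller b)
  mid <- (mz1 + mz2) / 2
  e <- c(abs(mid - mz1), abs(mid - mz2))
  want_b <- if (e[1] <= e[2]) 0L else 1L
  sp_mid <- mass_spectrum(mid, 100)
  asn_mid <- assign_peaks(sp_mid, S1, list(c2, c1), tol = abs(mz2 - mz1))
  expect_equal(asn_mid$b, want_b)
})

test_that("binding table pools charge states and flags empty assignments", {
  M <- oligo_mass(S1)
  specs <- list(list(species = ion_species(4, 2, 1), intensity = 100),
                list(species = ion_species(5, 2, 1), intensity = 40),
                list(species = ion_species(4, 2, 0), intensity = 20))
  sp <- gen_ms_spectrum(specs, S1)
  asn <- assign_peaks(sp, S1, candidate_species(charges = 3:5))
  tab <- binding_table_from_assignments(asn)
  # the two charge states of the 1:1 complex pool into b = 1
  expect_equal(unname(round(as.numeric(tab))), c(20, 140, 0, 0))

  empty <- assign_peaks(mass_spectrum(100.123, 100), S1,
                        candidate_species(), tol = 0.5)
  expect_warning(tab0 <- binding_table_from_assignments(empty), "all zero")
  expect_true(attr(tab0, "empty"))
  expect_error(ira(tab0), "all-zero")
})

test_that("IRa reproduces the worked example and its edge cases", {
  expect_identical(ira(binding_table(c(30, 100, 75, 0))), 0.85)
  expect_identical(ira(binding_table(c(100, 0, 0, 0))), 0)
  expect_identical(ira(binding_table(c(0, 50, 0, 0))), 1)
  expect_error(binding_table(c(0, 0, 0, 0)), "all-zero")
  expect_error(binding_table(c(-1, 2, 3, 4)), ">= 0")
})

test_that("IRa is bounded, monotone, and matches brute-force re-summation", {
  set.seed(11)
  for (i in 1:100) {
    x <- round(runif(4, 0, 100), 1)
    if (all(x == 0)) x[1] <- 1
    v <- ira(binding_table(x), round_to = 10)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, round(sum(x[-1]) / sum(x), 10))
  }
  base <- c(30, 10, 5, 1)
  v0 <- ira(binding_table(base), round_to = 8)
  # more complex signal raises IRa; more free G4 lowers it
  for (j in 2:4) {
    up <- base; up[j] <- up[j] + 10
    expect_gt(ira(binding_table(up), round_to = 8), v0)
  }
  down <- base; down[1] <- down[1] + 10
  expect_lt(ira(binding_table(down), round_to = 8), v0)
})

test_that("spectrum constructor and CSV reader normalize intensities", {
  expect_error(mass_spectrum(c(1, 1), c(2, 3)), "distinct")
  expect_error(mass_spectrum(1, -2), "positive")
  sp <- mass_spectrum(c(200, 100), c(5, 10))
  expect_equal(sp$mz, c(100, 200))            # sorted
  expect_equal(sp$rel_intensity, c(100, 50))  # percent of base peak

  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(mz = c(1391.1, 1475.0, 1558.8),
                       intensity = c(3e4, 1e5, 7.5e4)), csv, row.names = FALSE)
  rd <- read_ms_csv(csv)
  expect_equal(max(rd$rel_intensity), 100)
  expect_equal(rd$rel_intensity, c(30, 100, 75))
})
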