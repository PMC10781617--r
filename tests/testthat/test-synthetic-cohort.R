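test_that("identical seeds give byte-identical cohorts; domains use separate streams", {
  sc <- synthetic_scenario(n_individuals = 12, n_sites = 300, seed = 11)
  a <- generate_cohort(sc)
  b <- generate_cohort(sc)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$ibd$segments, b$ibd$segments)
  expect_identical(a$radiocarbon, b$radiocarbon)
  expect_identical(a$truth, b$truth)

  # different seed changes output
  c2 <- generate_cohort(synthetic_scenario(n_individuals = 12, n_sites = 300,
                                           seed = 12))
  expect_false(identical(a$genotypes$dosages, c2$genotypes$dosages))
})

test_that("degenerate scenarios are rejected", {
  expect_error(synthetic_scenario(n_individuals = 3), "n_individuals")
  expect_error(synthetic_scenario(n_sites = 50), "n_sites")
  expect_error(synthetic_scenario(turnover_times = c(4850, 5900)),
               "strictly decreasing")
  expect_error(stratum_spec("x", ibd_rate_within = 5, ibd_rate_between = 10),
               "must exceed")
})

test_that("zero between-stratum rate forces zero cross-stratum sharing", {
  strata <- list(
    stratum_spec("a", ibd_rate_within = 40, ibd_rate_between = 0),
    stratum_spec("b", ibd_rate_within = 40, ibd_rate_between = 0))
  sc <- synthetic_scenario(n_individuals = 10, n_sites = 150,
                           turnover_times = 5000, strata = strata, seed = 4)
  coh <- generate_cohort(sc)
  m <- sharing_matrix(coh$ibd, coh$meta$id, 3500, min_segment_cM = 0)
  cross <- outer(coh$truth$stratum, coh$truth$stratum, "!=")
  expect_true(all(m$total_cM[cross] == 0))
  expect_true(any(m$total_cM[!cross & upper.tri(cross)] > 0))
})

test_that("generated FST matches the Balding-Nichols drift target (brute-force oracle)", {
  strata <- list(
    stratum_spec("a", ibd_rate_within = 20, ibd_rate_between = 1),
    stratum_spec("b", ibd_rate_within = 20, ibd_rate_between = 1))
  sc <- synthetic_scenario(n_individuals = 20, n_sites = 10000,
                           turnover_times = 5000, strata = strata,
                           fst_divergence = 0.1, seed = 21)
  coh <- generate_cohort(sc)
  g1 <- coh$truth$stratum == "a"
  fst <- hudson_fst(coh$genotypes$dosages[, g1],
                    coh$genotypes$dosages[, !g1])
  expect_lt(abs(fst - 0.1), 0.03)
})

test_that("zero isotope SDs pin isotopes to stratum means", {
  strata <- list(
    stratum_spec("a", isotope_means = c(-15, 13), isotope_sds = c(0, 0),
                 ibd_rate_within = 20, ibd_rate_between = 1),
    stratum_spec("b", isotope_means = c(-20, 10), isotope_sds = c(0, 0),
                 ibd_rate_within = 20, ibd_rate_between = 1))
  sc <- synthetic_scenario(n_individuals = 8, n_sites = 150,
                           turnover_times = 5000, strata = strata, seed = 2)
  coh <- generate_cohort(sc)
  a <- coh$truth$stratum == "a"
  expect_equal(coh$isotopes$d13c[a], rep(-15, sum(a)))
  expect_equal(coh$isotopes$d15n[!a], rep(10, sum(!a)))
})

test_that("calibration curve: identity values, determinism, interpolation oracle", {
  crv <- generate_calibration_curve("identity", window = c(6000, 4000),
                                    noise_sd = 0)
  expect_equal(paleoturnover:::curve_mu(crv, 5000), 5000)
  expect_equal(paleoturnover:::curve_sigma(crv, 5000), 0)

  w1 <- generate_calibration_curve("wiggled", window = c(6000, 4000),
                                   noise_sd = 15, seed = 5)
  w2 <- generate_calibration_curve("wiggled", window = c(6000, 4000),
                                   noise_sd = 15, seed = 5)
  expect_identical(w1$grid, w2$grid)

  # linear interpolation between two adjacent knots, by hand
  g <- w1$grid
  t_mid <- (g$cal_bp[10] + g$cal_bp[11]) / 2
  by_hand <- (g$mu_c14[10] + g$mu_c14[11]) / 2
  expect_equal(paleoturnover:::curve_mu(w1, t_mid), by_hand)
})

test_that("identity-curve roundtrip recovers true dates within grid resolution", {
  # fully terrestrial diets (d13c below the terrestrial endmember) so the
  # synthetic 14C age carries no reservoir offset
  strata <- list(
    stratum_spec("a", isotope_means = c(-22, 8), isotope_sds = c(0, 0),
                 ibd_rate_within = 20, ibd_rate_between = 1),
    stratum_spec("b", isotope_means = c(-22, 8), isotope_sds = c(0, 0),
                 ibd_rate_within = 20, ibd_rate_between = 1))
  sc <- synthetic_scenario(n_individuals = 8, n_sites = 150, seed = 6,
                           turnover_times = 5000, strata = strata,
                           c14_sigma = 1)
  coh <- generate_cohort(sc)
  for (i in seq_len(8)) {
    d <- radiocarbon_date(coh$radiocarbon$lab_id[i],
                          coh$radiocarbon$c14_age[i], 1)
    cd <- calibrate(d, coh$curve, grid_resolution = 1)
    expect_lt(abs(cd$median - coh$truth$true_date[i]), 5)
  }
})

test_that("cohort writes to disk and reads back equivalently", {
  dir <- withr::local_tempdir()
  sc <- synthetic_scenario(n_individuals = 8, n_sites = 120, seed = 8)
  coh <- generate_cohort(sc)
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_identical(back$genotypes$dosages, coh$genotypes$dosages)
  expect_equal(back$ibd$segments$length_cM, coh$ibd$segments$length_cM)
  expect_equal(back$meta$id, coh$meta$id)
  expect_equal(back$curve$grid$mu_c14, coh$curve$grid$mu_c14)
})
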