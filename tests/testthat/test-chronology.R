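test_that("marine_fraction: endmembers, midpoint and clipping", {
  em <- c(terrestrial = -21, marine = -12.5)
  expect_equal(marine_fraction(-21, em), 0)
  expect_equal(marine_fraction(-12.5, em), 1)
  expect_equal(marine_fraction((-21 - 12.5) / 2, em), 0.5)
  expect_equal(marine_fraction(-30, em), 0)
  expect_equal(marine_fraction(-5, em), 1)
  expect_error(marine_fraction(-20, c(-21, -21)), "distinct")
})

test_that("reservoir correction: flagging thresholds and error propagation", {
  # elevated both isotopes -> flagged
  d1 <- reservoir_correct(radiocarbon_date("a", 5000, 30,
                                           d13c = -17.5, d15n = 12.5))
  expect_true(d1$reservoir_flag)

  # typical terrestrial values -> identity
  d2 <- reservoir_correct(radiocarbon_date("b", 5000, 30,
                                           d13c = -20.0, d15n = 10.0))
  expect_false(d2$reservoir_flag)
  expect_equal(d2$c14_age, 5000)
  expect_equal(d2$sigma, 30)

  # one elevated isotope alone does not trigger (AND rule)
  d3 <- reservoir_correct(radiocarbon_date("c", 5000, 30,
                                           d13c = -17.0, d15n = 11.0))
  expect_false(d3$reservoir_flag)

  # flagged with f = 0.5 and offset 400 +/- 50: age - 200, quadrature sigma
  em <- c(terrestrial = -21, marine = -12.5)
  mid <- (-21 - 12.5) / 2   # -16.75, also above the -18 threshold
  d4 <- reservoir_correct(radiocarbon_date("d", 5000, 30,
                                           d13c = mid, d15n = 13),
                          endmembers = em, full_marine_offset = c(400, 50))
  expect_equal(d4$c14_age, 5000 - 200)
  expect_equal(d4$sigma, sqrt(30^2 + (0.5 * 50)^2))

  expect_error(reservoir_correct(radiocarbon_date("e", 5000, 30)),
               "missing collagen")
})

test_that("calibration against an identity curve matches the closed-form normal", {
  crv <- generate_calibration_curve("identity", window = c(8000, 3000),
                                    noise_sd = 0)
  cd <- calibrate(radiocarbon_date("x", 5000, 30), crv, grid_resolution = 1)
  expect_equal(sum(cd$density), 1, tolerance = 1e-9)
  expect_lt(abs(cd$mean - 5000), 1)
  expect_lt(abs(cd$sd - 30), 1)
  hpd <- cd$hpd[["95.4%"]]
  expect_equal(nrow(hpd), 1L)
  expect_lt(abs(hpd[1, "older"] - 5060), 2)
  expect_lt(abs(hpd[1, "younger"] - 4940), 2)

  # sigma -> 0 concentrates on one or two grid cells
  cd0 <- calibrate(radiocarbon_date("y", 5000, 1e-6), crv,
                   grid_resolution = 1)
  expect_gte(max(cd0$density), 0.5)
  expect_equal(cd0$median, 5000)

  expect_error(calibrate(radiocarbon_date("z", 20000, 30), crv), "span")
})

test_that("probability mass is conserved on wiggled curves (property)", {
  for (seed in 1:5) {
    crv <- generate_calibration_curve("wiggled", window = c(7000, 3500),
                                      noise_sd = 20, seed = seed)
    cd <- calibrate(radiocarbon_date("w", 5000 + 100 * seed, 40), crv,
                    grid_resolution = 5)
    expect_equal(sum(cd$density), 1, tolerance = 1e-9)
    # HPD accumulation overshoots the requested mass by at most one grid cell
    mass <- attr(cd$hpd[[1]], "mass")
    expect_gte(mass, 0.954)
    expect_lte(mass, 0.954 + max(cd$density) + 1e-9)
  }
})

test_that("two-crossing curve gives a bimodal density with two HPD intervals", {
  # piecewise-linear curve that dips below 5000 and comes back: crossings at
  # cal 5285.71 (down) and 4500 (up), computed by hand from the knots
  crv <- calibration_curve(data.frame(
    cal_bp = c(6000, 5000, 4000),
    mu_c14 = c(5500, 4800, 5200),
    sigma_curve = 0))
  cd <- calibrate(radiocarbon_date("bi", 5000, 20), crv, grid_resolution = 1)
  hpd <- cd$hpd[["95.4%"]]
  expect_equal(nrow(hpd), 2L)
  expect_gte(attr(hpd, "mass"), 0.954)
  expect_lte(attr(hpd, "mass"), 0.954 + max(cd$density) + 1e-9)
  # crossing points: 6000 - 500/0.7 = 5285.71; 4000 + 200/0.4 = 4500
  expect_lt(abs(mean(hpd[1, ]) - (6000 - 500 / 0.7)), 5)
  expect_lt(abs(mean(hpd[2, ]) - 4500), 5)
  # local posterior SD ~ sigma / |slope|: 20/0.7 = 28.6 and 20/0.4 = 50
  expect_lt(abs(diff(-hpd[1, ]) / 4 - 20 / 0.7), 6)
  expect_lt(abs(diff(-hpd[2, ]) / 4 - 20 / 0.4), 10)
})

test_that("combine_dates closed forms and chi-squared consistency test", {
  two <- combine_dates(list(radiocarbon_date("a", 5000, 30),
                            radiocarbon_date("a", 5000, 30)))
  expect_equal(two$c14_age, 5000)
  expect_equal(two$sigma, 30 / sqrt(2), tolerance = 1e-12)
  expect_equal(two$chi2_stat, 0)
  expect_true(two$passes)

  bad <- combine_dates(list(radiocarbon_date("a", 5000, 30),
                            radiocarbon_date("a", 5200, 30)))
  expect_equal(bad$chi2_stat, 200^2 / (2 * 30^2), tolerance = 1e-12)
  expect_false(bad$passes)                         # 22.2 > 3.84

  three <- combine_dates(replicate(3, radiocarbon_date("a", 5000, 30),
                                   simplify = FALSE))
  expect_equal(three$sigma, 30 / sqrt(3), tolerance = 1e-12)

  # one dominant precision: combination converges to the precise date
  dom <- combine_dates(list(radiocarbon_date("a", 5000, 10),
                            radiocarbon_date("a", 6000, 1e6)))
  expect_equal(dom$c14_age, 5000, tolerance = 1e-3)
  expect_equal(dom$sigma, 10, tolerance = 1e-6)

  expect_error(combine_dates(list(radiocarbon_date("a", 5000, 30))),
               "at least 2")
})

test_that("phase model: determinism, degenerate class, recovery and shrinkage", {
  crv <- generate_calibration_curve("identity", window = c(8000, 3000),
                                    noise_sd = 0)
  set.seed(41)
  dates <- simulate_phase_dates(12, sigma = 40, curve = crv)

  f1 <- fit_phase_model(dates, n_iter = 800, n_burn = 300, n_chains = 2,
                        seed = 5)
  f2 <- fit_phase_model(dates, n_iter = 800, n_burn = 300, n_chains = 2,
                        seed = 5)
  expect_identical(f1$draws, f2$draws)             # same seed, same draws
  expect_true(all(with(f1$draws,
    a_farmer >= b_farmer & b_farmer >= c_farmer & c_farmer >= d_farmer)))

  # tightly-dated farmer events at 5900 pin the onset near 5900
  tight <- c(lapply(1:6, function(i) quick_cal(5900, 0.5, "farmer", crv, 1)),
             lapply(1:6, function(i)
               quick_cal(4500 - 20 * i, 10, "steppe", crv, 1)))
  ft <- fit_phase_model(tight, n_iter = 1500, n_burn = 500, n_chains = 1,
                        seed = 3)
  onset_f <- (ft$draws$a_farmer + ft$draws$b_farmer) / 2
  expect_lt(abs(mean(onset_f) - 5900), 15)

  expect_error(fit_phase_model(dates[1:4], n_iter = 10, n_burn = 5),
               "at least 3 dates")
})
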