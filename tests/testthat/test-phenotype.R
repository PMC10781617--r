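toy_panel <- function() {
  beta <- data.frame(
    variant = rep(c("v1", "v2"), each = 2),
    effect_allele = "A",
    category = rep(c("blue", "intermediate"), 2),
    beta = c(1.0, 0.2, -0.5, 0.1))
  phenotype_panel(beta, c(blue = 0, intermediate = -1), "brown")
}

test_that("pigmentation probabilities follow the multinomial-logistic formulas", {
  p <- toy_panel()
  # all dosages zero -> softmax of intercepts alone
  pr0 <- pigmentation_probs(c(v1 = 0, v2 = 0), p)
  es <- exp(c(0, -1))
  expect_equal(unname(pr0[c("blue", "intermediate")]), es / (1 + sum(es)),
               tolerance = 1e-12)
  expect_equal(sum(pr0), 1, tolerance = 1e-12)

  # binary toy: one variant beta 1, intercept 0, dosage 2 -> e^2/(1+e^2)
  single <- phenotype_panel(
    data.frame(variant = "v", effect_allele = "A", category = "case",
               beta = 1.0),
    c(case = 0), "control")
  pr <- pigmentation_probs(c(v = 2), single)
  expect_equal(unname(pr["case"]), exp(2) / (1 + exp(2)), tolerance = 1e-12)
})

test_that("pigmentation: order invariance, normalization, missing handling", {
  p <- toy_panel()
  a <- pigmentation_probs(c(v1 = 2, v2 = 1), p)
  b <- pigmentation_probs(c(v2 = 1, v1 = 2), p)
  expect_equal(a, b)

  set.seed(3)
  for (i in 1:50) {
    pr <- pigmentation_probs(c(v1 = runif(1, 0, 2), v2 = runif(1, 0, 2)), p)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
  }

  m <- pigmentation_probs(c(v1 = 2, v2 = NA), p)
  expect_true(attr(m, "low_confidence"))
  expect_equal(attr(m, "n_dropped"), 1L)
  expect_equal(sum(m), 1, tolerance = 1e-12)
})

test_that("bundled synthetic panel fixture loads and predicts", {
  panel <- read_phenotype_panel(
    system.file("extdata", "synthetic_eye_panel.tsv",
                package = "paleoturnover"),
    system.file("extdata", "synthetic_eye_intercepts.json",
                package = "paleoturnover"))
  expect_length(unique(panel$beta$variant), 18L)
  dos <- setNames(rep(1, 18), unique(panel$beta$variant))
  pr <- pigmentation_probs(dos, panel)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  expect_setequal(names(pr), c("blue", "intermediate", "brown"))
})

test_that("height PGS arithmetic, rescaling and coverage guard", {
  panel <- data.frame(locus = c("l1", "l2"), effect_allele = "A",
                      beta = c(0.1, -0.2))
  class(panel) <- c("pgs_panel", "data.frame")
  expect_equal(height_pgs(c(l1 = 2, l2 = 1), panel)$raw, 0.0)
  expect_equal(height_pgs(c(l1 = 0, l2 = 0), panel)$raw, 0.0)

  # missing loci rescale by panel/non-missing
  p4 <- data.frame(locus = paste0("l", 1:4), effect_allele = "A",
                   beta = c(0.1, 0.1, 0.1, 0.1))
  r <- height_pgs(c(l1 = 2, l2 = 2, l3 = NA, l4 = NA), p4)
  expect_equal(r$raw, 0.4 * 4 / 2)
  expect_error(height_pgs(c(l1 = 2, l2 = NA, l3 = NA, l4 = NA), p4),
               "insufficient panel coverage")
})

test_that("standardized PGS over the reference population has mean 0 sd 1", {
  set.seed(11)
  panel <- data.frame(locus = sprintf("l%03d", 1:310), effect_allele = "A",
                      beta = rnorm(310, 0, 0.05))
  class(panel) <- c("pgs_panel", "data.frame")
  dos <- matrix(rbinom(310 * 40, 2, 0.5), 310, 40,
                dimnames = list(panel$locus, NULL))
  raws <- vapply(seq_len(40), function(i)
    height_pgs(dos[, i], panel)$raw, 0)
  std <- vapply(seq_len(40), function(i)
    height_pgs(dos[, i], panel, reference_scores = raws)$standardized, 0)
  expect_equal(mean(std), 0, tolerance = 1e-9)
  expect_equal(sd(std), 1, tolerance = 1e-9)

  # cm_per_sd scales delta linearly
  r <- height_pgs(dos[, 1], panel, reference_scores = raws, cm_per_sd = 6)
  expect_equal(r$delta, r$standardized * 6)
})

test_that("collagen QC window is closed [2.9, 3.6]", {
  r <- collagen_qc(c(3.2, 3.7, 2.9, 3.6, 2.8))
  expect_equal(r$pass, c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(r$reason[2], "C:N>3.6")
  expect_equal(r$reason[5], "C:N<2.9")
  expect_error(collagen_qc(NA_real_), "present")
})

test_that("diet classification and reservoir flag", {
  r <- diet_class(c(-20, -12.5, -17.5), c(10, 15, 12.5))
  expect_equal(r$class, c("terrestrial", "marine-dominated", "mixed"))
  expect_equal(r$reservoir_flag, c(FALSE, TRUE, TRUE))

  # marine fraction monotone non-decreasing in d13c
  f <- diet_class(seq(-25, -10, by = 0.5), rep(10, 31))$marine_fraction
  expect_true(all(diff(f) >= 0))
})

test_that("Sr outliers by scaled MAD with IQR fallback", {
  ids <- sprintf("s%d", 1:8)
  sr <- c(rep(0.7090, 7), 0.7140)
  expect_warning(r <- sr_outliers(ids, sr), "zero MAD")  # IQR fallback
  expect_equal(r$flagged, c(rep(FALSE, 7), TRUE))

  expect_warning(r2 <- sr_outliers(ids, rep(0.709, 8)), "zero MAD")
  expect_false(any(r2$flagged))

  set.seed(2)
  sr3 <- rnorm(10, 0.7095, 5e-4)
  r3 <- sr_outliers(sprintf("t%d", 1:10), sr3, k = Inf)
  expect_false(any(r3$flagged))

  # robust-z arithmetic against direct computation
  sr4 <- c(0.7090, 0.7091, 0.7092, 0.7093, 0.7094, 0.7200)
  r4 <- sr_outliers(sprintf("u%d", 1:6), sr4, k = 3)
  z_hand <- (sr4 - median(sr4)) / mad(sr4)
  expect_equal(r4$robust_z, z_hand)
  expect_equal(r4$flagged, abs(z_hand) > 3)
})
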