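test_that("nnls_mixture exact cases: identity and orthogonal half-half", {
  A <- c(1, 0, 0, 1) / 2
  B <- c(0, 1, 1, 0) / 2
  r1 <- nnls_mixture(A, cbind(A = A, B = B))
  expect_equal(unname(r1$weights), c(1, 0), tolerance = 1e-10)
  expect_lt(r1$residual_norm, 1e-10)

  y <- 0.5 * A + 0.5 * B
  r2 <- nnls_mixture(y, cbind(A = A, B = B))
  expect_equal(unname(r2$weights), c(0.5, 0.5), tolerance = 1e-10)
  expect_lt(r2$residual_norm, 1e-12)
})

test_that("active non-negativity matches a simplex grid-search oracle", {
  # y = A - 0.2 B clipped at 0, with B non-overlapping A
  A <- c(0.5, 0.5, 0, 0)
  B <- c(0, 0, 0.6, 0.4)
  y <- pmax(A - 0.2 * B, 0)
  fit <- nnls_mixture(y, cbind(A = A, B = B))
  expect_equal(unname(fit$weights["B"]), 0, tolerance = 1e-10)

  # brute-force over the simplex at 0.01 resolution (normalized features,
  # as nnls_mixture uses); scale-free in the mixture direction
  yn <- y / sum(y); An <- A / sum(A); Bn <- B / sum(B)
  grid <- seq(0, 1, by = 0.01)
  sse <- vapply(grid, function(w) {
    v <- w * An + (1 - w) * Bn
    # free total scale, as NNLS fits coefficients before renormalization
    s <- sum(v * yn) / sum(v * v)
    sum((s * v - yn)^2)
  }, 0)
  expect_equal(grid[which.min(sse)], 1)   # all weight on A
})

test_that("nnls_mixture validates inputs and flags collinearity", {
  A <- c(1, 0) / 1
  expect_error(nnls_mixture(c(0, 0), cbind(A, A)), "no sharing signal")
  expect_error(nnls_mixture(c(1, 0), matrix(A, ncol = 1)), "2 sources")
  expect_error(nnls_mixture(c(1, 0, 0), cbind(c(1, 0, 0), c(0, 1, 0),
                                              c(0, 0, 1), c(1, 1, 1))),
               "feature dimension")
  expect_warning(nnls_mixture(c(1, 1, 0), cbind(A = c(1, 1, 0),
                                                B = c(1, 1, 1e-12))),
                 "collinear")
})

test_that("3-source weights are recovered within 0.05 under feature noise (20 seeds)", {
  S <- cbind(a = c(0.6, 0.2, 0.1, 0.05, 0.05),
             b = c(0.1, 0.6, 0.2, 0.05, 0.05),
             c = c(0.05, 0.1, 0.15, 0.6, 0.1))
  for (seed in 1:20) {
    set.seed(seed)
    w_true <- c(0.5, 0.3, 0.2)
    y <- pmax(drop(S %*% w_true) + rnorm(5, 0, 0.01), 0)
    fit <- nnls_mixture(y, S)
    expect_lt(max(abs(fit$weights - w_true)), 0.05)
  }
})

test_that("d_statistic matches the pattern-count oracle on 4 haploid sequences", {
  # 4 sites: patterns BABA, BABA, BABA, ABBA with p in {0, 1}
  sites <- data.frame(chrom = rep("1", 4), pos = c(1L, 2L, 3L, 4L) * 10L,
                      ref = "A", alt = "C", info_score = 1)
  #        P1 P2 P3 P4  (haploid frequencies via pseudo-haploid dosage 0/2)
  pat <- rbind(c(1, 0, 1, 0),   # BABA
               c(1, 0, 1, 0),
               c(1, 0, 1, 0),
               c(0, 1, 1, 0))   # ABBA
  g <- genotype_table(sites, c("p1", "p2", "p3", "p4"),
                      matrix(as.integer(2 * pat), nrow = 4),
                      ploidy = "pseudohaploid")
  groups <- list(P1 = "p1", P2 = "p2", P3 = "p3", P4 = "p4")
  d <- d_statistic(g, groups, block_size = 10, weighted = FALSE)
  expect_equal(d$D, (1 - 3) / (1 + 3))            # (ABBA - BABA)/(ABBA + BABA)
  expect_equal(d$n_sites_used, 4L)

  # P1 <-> P2 swap negates D exactly; P3 <-> P4 swap too
  d12 <- d_statistic(g, groups[c(2, 1, 3, 4)], 10, weighted = FALSE)
  d34 <- d_statistic(g, groups[c(1, 2, 4, 3)], 10, weighted = FALSE)
  expect_equal(d12$D, -d$D)
  expect_equal(d34$D, -d$D)
})

test_that("D is zero for identical P1/P2 and invariant under allele relabeling", {
  set.seed(5)
  sites <- data.frame(chrom = "1", pos = seq_len(50) * 1000L,
                      ref = "A", alt = "C", info_score = 1)
  dos <- matrix(rbinom(50 * 8, 2, 0.4), 50, 8)
  g <- genotype_table(sites, paste0("s", 1:8), dos)
  same <- list(P1 = c("s1", "s2"), P2 = c("s1", "s2"),
               P3 = c("s5", "s6"), P4 = c("s7", "s8"))
  expect_equal(d_statistic(g, same, 5000)$D, 0)

  grp <- list(P1 = c("s1", "s2"), P2 = c("s3", "s4"),
              P3 = c("s5", "s6"), P4 = c("s7", "s8"))
  d0 <- d_statistic(g, grp, 5000)
  flip <- sample(50, 20)
  g2 <- g
  g2$dosages[flip, ] <- 2L - g2$dosages[flip, ]     # ref/alt relabel
  d1 <- d_statistic(g2, grp, 5000)
  expect_equal(d1$D, d0$D, tolerance = 1e-12)
  expect_equal(abs(d1$Z), abs(d0$Z), tolerance = 1e-8)
})

test_that("jackknife guards: empty group and too few blocks error", {
  g <- toy_genotypes()
  expect_error(
    d_statistic(g, list(P1 = "s1", P2 = "s2", P3 = "s3", P4 = "nope"),
                1e6), "unknown sample")
  expect_error(
    d_statistic(g, list(P1 = "s1", P2 = "s2", P3 = "s3", P4 = "s3"),
                1e9), "jackknife undefined")
})

test_that("lsq_project recovers reference coordinates and degrades gracefully", {
  set.seed(7)
  n <- 40; L <- 400
  p <- runif(L, 0.1, 0.9)
  pop <- rep(0:1, each = n / 2)
  dos <- t(vapply(seq_len(n), function(i)
    rbinom(L, 2, ifelse(pop[i] == 1, pmin(p + 0.25, 0.95), p)), numeric(L)))
  sites <- data.frame(chrom = "1", pos = seq_len(L), ref = "A", alt = "C")
  g <- genotype_table(sites, sprintf("r%02d", 1:n), t(dos))
  ref <- pca_reference(g, k = 2)

  # complete-data reference sample recovers its coordinates to 1e-8
  x <- g$dosages[, "r01"]
  expect_equal(lsq_project(ref, x), ref$coordinates["r01", ],
               tolerance = 1e-8)

  # masking: mean coordinate error shrinks as masking decreases (80/50/20%)
  err <- vapply(c(0.8, 0.5, 0.2), function(fr) {
    mean(vapply(1:5, function(rep) {
      set.seed(42 + rep)
      xm <- x
      xm[sample(length(x), round(fr * length(x)))] <- NA
      sqrt(sum((lsq_project(ref, xm) - ref$coordinates["r01", ])^2))
    }, 0))
  }, 0)
  expect_true(all(diff(err) < 0))

  # all-but-10 missing still returns finite coordinates
  xm <- x; xm[-(1:10)] <- NA
  expect_true(all(is.finite(lsq_project(ref, xm))))
  xm2 <- x; xm2[-(1:9)] <- NA
  expect_error(lsq_project(ref, xm2), "non-missing")
})

test_that("admixture dating recovers a 20-generation pulse within 20%", {
  set.seed(13)
  L <- 1500
  pos <- sort(runif(L, 0, 1.5))        # Morgans
  f1 <- runif(L, 0.05, 0.95)
  f2 <- pmin(pmax(f1 + sample(c(-1, 1), L, TRUE) * runif(L, 0.2, 0.4),
                  0.02), 0.98)
  sim <- simulate_admixed_haplotypes(200, pos, f1, f2, alpha = 0.5,
                                     generations = 20, seed = 99)
  fit <- admixture_date(sim$haplotypes, pos, f1, f2)
  expect_false(fit$no_date)
  expect_lt(abs(fit$generations - 20) / 20, 0.2)

  # years scale linearly with generation_time, generations fixed
  fit2 <- admixture_date(sim$haplotypes, pos, f1, f2, generation_time = 58)
  expect_equal(fit2$generations, fit$generations)
  expect_equal(fit2$years, 2 * fit$years)
})

test_that("unadmixed panel is flagged 'no date'", {
  set.seed(17)
  L <- 800
  pos <- sort(runif(L, 0, 1))
  f1 <- runif(L, 0.1, 0.9)
  f2 <- pmin(pmax(f1 + runif(L, -0.3, 0.3), 0.02), 0.98)
  H <- vapply(seq_len(L), function(s) rbinom(150, 1, f1[s]),
              integer(150))        # single-source, no admixture LD
  fit <- admixture_date(H, pos, f1, f2)
  expect_true(fit$no_date)
  expect_true(is.na(fit$generations))
})
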