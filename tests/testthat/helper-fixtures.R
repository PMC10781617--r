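# shared in-code fixtures and small oracles

# tiny genotype table built by hand
toy_genotypes <- function() {
  sites <- data.frame(
    chrom = c("1", "1", "2", "2", "3"),
    pos = c(100L, 200L, 100L, 300L, 50L),
    ref = c("A", "C", "G", "A", "C"),
    alt = c("C", "T", "A", "T", "G"),
    info_score = c(0.9, 0.4, 0.8, 0.95, 0.7))
  dos <- matrix(c(0L, 1L, 2L, NA, 1L,
                  2L, 0L, 1L, 2L, 0L,
                  1L, 2L, 0L, 0L, 2L), nrow = 5)
  genotype_table(sites, c("s1", "s2", "s3"), dos)
}

# block-structured IBD segment table: k blocks of `per` ids, every
# within-block pair gets one `within` cM segment, cross pairs get `between`
planted_blocks <- function(k = 3, per = 4, within = 60, between = 6) {
  ids <- sprintf("I%02d", seq_len(k * per))
  block <- rep(seq_len(k), each = per)
  rows <- list()
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in seq((i + 1), length(ids))) {
      len <- if (block[i] == block[j]) within else between
      if (len <= 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        sample1 = ids[i], sample2 = ids[j], chrom = 1L,
        start_cM = 10, end_cM = 10 + len, length_cM = len)
    }
  }
  list(segs = ibd_segments(do.call(rbind, rows)), ids = ids, block = block)
}

# adjusted Rand index oracle (direct contingency-table formula)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# Hudson-style FST from two population dosage matrices (sites x samples),
# ratio-of-averages with finite-sample correction
hudson_fst <- function(d1, d2) {
  n1 <- 2 * ncol(d1); n2 <- 2 * ncol(d2)
  p1 <- rowMeans(d1) / 2; p2 <- rowMeans(d2) / 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# identity-curve calibrated density factory for phase-model tests
quick_cal <- function(age, sigma, cls, curve, res = 5) {
  calibrate(radiocarbon_date(paste0(cls, "_", age), age, sigma,
                             ancestry_class = cls),
            curve, grid_resolution = res)
}

# simulate a two-phase dataset (uniform events in each phase) and calibrate
simulate_phase_dates <- function(n_per, farmer_range = c(5900, 4850),
                                 steppe_range = c(4850, 4000),
                                 sigma = 40, curve, res = 5) {
  mk <- function(n, rng, cls) lapply(seq_len(n), function(i) {
    t <- runif(1, rng[2], rng[1])
    quick_cal(round(t + rnorm(1, 0, sigma)), sigma, cls, curve, res)
  })
  c(mk(n_per, farmer_range, "farmer"), mk(n_per, steppe_range, "steppe"))
}
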