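#' Date an admixture pulse from weighted LD decay
#'
#' Simplified admixture-LD dating (single target panel, binned decay fit).
#' For SNP pairs at genetic distance `d`, the covariance of their alleles
#' across admixed haplotypes, weighted by the source allele-frequency
#' difference at each SNP, decays as `exp(-lambda d)` where `lambda` is the
#' admixture age in generations.  The statistic per distance bin is
#' \deqn{a(d) = \frac{\sum_{i<j} w_i w_j \,\mathrm{cov}(x_i, x_j)}
#'                   {\sum_{i<j} (w_i w_j)^2}},
#' with `w = f1 - f2` the source frequency difference; `A(d) = A0 exp(-lambda
#' d) + c` is then fitted by nonlinear least squares and `lambda` is read as
#' generations since admixture.
#'
#' @param haplotypes 0/1 matrix, haplotypes x sites.
#' @param positions site positions in Morgans (sorted increasing).
#' @param f1,f2 source allele frequencies per site.
#' @param bins breakpoints of the genetic-distance bins (Morgans); at least
#'   5 non-empty bins are required.
#' @param max_dist maximum pair distance used (Morgans).
#' @param generation_time years per generation (default 29).
#' @return object of class `admixture_date`: `generations`, `years`,
#'   `amplitude`, `offset`, `fit_rmse`, `no_date` flag (TRUE when the decay
#'   rate is not positive), `bin_mids`, `bin_stat`.
#' @export
admixture_date <- function(haplotypes, positions, f1, f2,
                           bins = seq(0.002, 0.2, by = 0.004),
                           max_dist = max(bins), generation_time = 29) {
  stopifnot(is.matrix(haplotypes), length(positions) == ncol(haplotypes),
            length(f1) == ncol(haplotypes), length(f2) == ncol(haplotypes),
            !is.unsorted(positions))
  w <- f1 - f2
  X <- sweep(haplotypes, 2, colMeans(haplotypes))
  n <- nrow(X)
  C <- crossprod(X) / (n - 1)            # allele covariance across haplotypes
  L <- ncol(X)
  pr <- which(upper.tri(C), arr.ind = TRUE)
  d <- positions[pr[, 2]] - positions[pr[, 1]]
  keep <- d > 0 & d <= max_dist
  pr <- pr[keep, , drop = FALSE]; d <- d[keep]
  ww <- w[pr[, 1]] * w[pr[, 2]]
  cv <- C[pr]
  bin <- cut(d, breaks = c(0, bins), labels = FALSE)
  ok <- !is.na(bin)
  num <- tapply(ww[ok] * cv[ok], bin[ok], sum)
  den <- tapply((ww[ok]^2), bin[ok], sum)
  stat <- num / den
  mids <- (c(0, bins[-length(bins)]) + bins)[as.integer(names(stat))] / 2
  nonempty <- is.finite(stat)
  if (sum(nonempty) < 5L) stop("need at least 5 non-empty distance bins")
  mids <- mids[nonempty]; stat <- as.numeric(stat[nonempty])
  fit <- fit_exp_decay(mids, stat)
  # "no date": decay absent (lambda <= 0), inverted (A0 <= 0), or the fitted
  # amplitude is indistinguishable from the bin noise floor
  no_date <- !is.finite(fit$lambda) || fit$lambda <= 0 ||
    !is.finite(fit$A0) || fit$A0 <= 0 || fit$A0 < 2 * fit$rmse
  structure(list(generations = if (no_date) NA_real_ else fit$lambda,
                 years = if (no_date) NA_real_ else fit$lambda * generation_time,
                 amplitude = fit$A0, offset = fit$c0, fit_rmse = fit$rmse,
                 no_date = no_date, generation_time = generation_time,
                 bin_mids = mids, bin_stat = stat),
            class = "admixture_date")
}

# A(d) = A0 exp(-lambda d) + c by Gauss-Newton via nls with a grid-started
# fallback to coarse profiling when nls fails to converge.
fit_exp_decay <- function(d, y) {
  best <- NULL
  for (lam0 in c(5, 10, 20, 50, 100)) {
    fit <- tryCatch(suppressWarnings(
      nls(y ~ A0 * exp(-lambda * d) + c0,
          start = list(A0 = max(y) - min(y) + 1e-9, lambda = lam0,
                       c0 = min(y)),
          control = list(maxiter = 200, warnOnly = TRUE))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(coef = coef(fit), rss = rss)
  }
  if (is.null(best)) {
    # profile lambda on a grid, linear solve for A0, c
    grid <- exp(seq(log(0.5), log(500), length.out = 200))
    rss <- vapply(grid, function(l) {
      Xd <- cbind(exp(-l * d), 1)
      sum(stats::lm.fit(Xd, y)$residuals^2)
    }, 0)
    l <- grid[which.min(rss)]
    cf <- stats::lm.fit(cbind(exp(-l * d), 1), y)$coefficients
    best <- list(coef = c(A0 = cf[1], lambda = l, c0 = cf[2]),
                 rss = min(rss))
  }
  list(lambda = unname(best$coef["lambda"]), A0 = unname(best$coef["A0"]),
       c0 = unname(best$coef["c0"]), rmse = sqrt(best$rss / length(d)))
}

#' @export
print.admixture_date <- function(x, ...) {
  if (x$no_date) cat("admixture date: no decaying signal (flagged 'no date')\n")
  else cat(sprintf("admixture date: %.1f generations = %.0f yr (gen time %g)\n",
                   x$generations, x$years, x$generation_time))
  invisible(x)
}
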