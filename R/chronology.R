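#' Construct a radiocarbon calibration curve
#'
#' @param grid data.frame with columns `cal_bp`, `mu_c14`, `sigma_curve`;
#'   `cal_bp` must be strictly monotone.
#' @return object of class `calibration_curve` (stored oldest-first).
#' @export
calibration_curve <- function(grid) {
  grid <- as.data.frame(grid)
  stopifnot(all(c("cal_bp", "mu_c14", "sigma_curve") %in% names(grid)),
            all(grid$sigma_curve >= 0))
  d <- diff(grid$cal_bp)
  if (!(all(d > 0) || all(d < 0))) stop("cal_bp must be strictly monotone")
  if (d[1] > 0) grid <- grid[rev(seq_len(nrow(grid))), ]  # store oldest first
  rownames(grid) <- NULL
  structure(list(grid = grid,
                 resolution = abs(stats::median(diff(grid$cal_bp)))),
            class = "calibration_curve")
}

# linear interpolation of the curve mean / error at arbitrary cal BP
curve_mu <- function(curve, t)
  approx(curve$grid$cal_bp, curve$grid$mu_c14, xout = t, rule = 1)$y
curve_sigma <- function(curve, t)
  approx(curve$grid$cal_bp, curve$grid$sigma_curve, xout = t, rule = 1)$y

#' Read/write calibration curves in IntCal-style ".14c" text
#'
#' Five comma/whitespace-separated columns (cal BP, 14C age, 1-sigma error,
#' Delta14C, error); only the first three are used.  Comment lines start
#' with `#`.
#'
#' @param path file path.
#' @return [calibration_curve()] (read) or `path` invisibly (write).
#' @export
read_calcurve <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  dt <- data.table::fread(text = lines, header = FALSE, data.table = FALSE)
  calibration_curve(data.frame(cal_bp = dt[[1]], mu_c14 = dt[[2]],
                               sigma_curve = dt[[3]]))
}

#' @rdname read_calcurve
#' @param curve a [calibration_curve()].
#' @export
write_calcurve <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  g <- curve$grid
  writeLines(c("# cal BP, 14C age BP, sigma, Delta14C, sigma",
               sprintf("%g,%g,%g,%g,%g", g$cal_bp, g$mu_c14, g$sigma_curve,
                       0, 0)), path)
  invisible(path)
}

#' Construct a radiocarbon determination
#'
#' @param lab_id laboratory identifier.
#' @param c14_age conventional 14C age BP.
#' @param sigma 1-sigma measurement error in 14C yr (> 0).
#' @param d13c,d15n collagen stable isotopes (permil, VPDB / AIR).
#' @param cn_atomic collagen atomic C:N ratio.
#' @param ancestry_class one of `"farmer"`, `"steppe"`, `"hg"`, `"other"`.
#' @return object of class `radiocarbon_date`.
#' @export
radiocarbon_date <- function(lab_id, c14_age, sigma, d13c = NA_real_,
                             d15n = NA_real_, cn_atomic = NA_real_,
                             ancestry_class = "other") {
  if (sigma <= 0) stop("sigma must be positive")
  structure(list(lab_id = lab_id, c14_age = c14_age, sigma = sigma,
                 d13c = d13c, d15n = d15n, cn_atomic = cn_atomic,
                 ancestry_class = ancestry_class,
                 reservoir_flag = FALSE, reservoir_age = 0,
                 reservoir_sigma = 0),
            class = "radiocarbon_date")
}

#' Marine diet fraction from collagen delta13C
#'
#' Two-endmember linear mixing: `f = (d13c - terrestrial) / (marine -
#' terrestrial)`, clipped to `[0, 1]`.
#'
#' @param d13c collagen delta13C (permil); vectorized.
#' @param endmembers length-2 `(terrestrial, marine)` endmember values,
#'   conventional defaults -21 and -12.5 permil.
#' @return marine protein fraction in `[0, 1]`.
#' @export
marine_fraction <- function(d13c, endmembers = c(terrestrial = -21.0,
                                                 marine = -12.5)) {
  endmembers <- unname(endmembers)
  if (endmembers[1] == endmembers[2]) stop("endmembers must be distinct")
  pmin(pmax((d13c - endmembers[1]) / (endmembers[2] - endmembers[1]), 0), 1)
}

#' Diet-based marine reservoir correction
#'
#' A date is flagged for reservoir correction when both collagen isotopes are
#' elevated: `d13c >= -18.00` AND `d15n >= +12.00` (the conjunction reflects
#' that marine protein raises both the carbon signal and the trophic level).
#' For a flagged date the reservoir age is the marine diet fraction times the
#' full-marine offset, its uncertainty is scaled likewise and combined in
#' quadrature with the measurement error, and the corrected age is
#' `c14_age - reservoir_age`.  Unflagged dates are returned unchanged.
#'
#' @param d a [radiocarbon_date()].
#' @param endmembers passed to [marine_fraction()].
#' @param full_marine_offset length-2 `(offset, sigma)` in 14C yr; the
#'   conventional 400 +/- 50 by default.
#' @param d13c_threshold,d15n_threshold flagging thresholds (permil).
#' @return the date with `reservoir_flag`, `reservoir_age`,
#'   `reservoir_sigma`, and (when flagged) updated `c14_age`/`sigma`; the
#'   uncorrected measurement is kept in `c14_age_raw`/`sigma_raw`.
#' @export
reservoir_correct <- function(d, endmembers = c(terrestrial = -21.0,
                                                marine = -12.5),
                              full_marine_offset = c(400, 50),
                              d13c_threshold = -18.00,
                              d15n_threshold = 12.00) {
  stopifnot(inherits(d, "radiocarbon_date"))
  if (is.na(d$d13c) || is.na(d$d15n))
    stop("missing collagen isotopes: cannot evaluate reservoir flag")
  d$c14_age_raw <- d$c14_age
  d$sigma_raw <- d$sigma
  d$reservoir_flag <- d$d13c >= d13c_threshold && d$d15n >= d15n_threshold
  if (d$reservoir_flag) {
    f <- marine_fraction(d$d13c, endmembers)
    d$reservoir_age <- f * full_marine_offset[1]
    d$reservoir_sigma <- f * full_marine_offset[2]
    d$c14_age <- d$c14_age - d$reservoir_age
    d$sigma <- sqrt(d$sigma^2 + d$reservoir_sigma^2)
  }
  d
}

#' Calibrate a radiocarbon date against a curve
#'
#' Numeric calibration: on a cal BP grid, the posterior is
#' `p(t) ~ N(age; mu(t), sigma^2 + sigma_curve(t)^2)`, normalized to unit
#' mass.  Highest-posterior-density regions are found by descending-density
#' accumulation and may be disjoint on wiggly curves.
#'
#' @param d a [radiocarbon_date()] (already reservoir-corrected if needed).
#' @param curve a [calibration_curve()].
#' @param grid_resolution output grid step in cal yr (default 1).
#' @param hpd_mass HPD masses to report (default 0.954 and 0.683).
#' @return object of class `calibrated_density`: `cal_bp` grid (oldest
#'   first), `density` (sums to 1), `hpd` (list of matrices `(older,
#'   younger)` per mass), `mean`, `sd`, `median`.
#' @export
calibrate <- function(d, curve, grid_resolution = 1,
                      hpd_mass = c(0.954, 0.683)) {
  stopifnot(inherits(d, "radiocarbon_date"), inherits(curve, "calibration_curve"))
  g <- curve$grid
  span_mu <- range(g$mu_c14)
  smax <- sqrt(max(g$sigma_curve)^2 + d$sigma^2)
  if (d$c14_age < span_mu[1] - 5 * smax || d$c14_age > span_mu[2] + 5 * smax)
    stop("14C age outside calibration curve span")
  cal_bp <- seq(max(g$cal_bp), min(g$cal_bp), by = -grid_resolution)
  mu <- curve_mu(curve, cal_bp)
  sg <- sqrt(curve_sigma(curve, cal_bp)^2 + d$sigma^2)
  dens <- dnorm(d$c14_age, mu, sg)
  tot <- sum(dens)
  if (tot == 0) stop("zero posterior mass: age incompatible with curve")
  dens <- dens / tot
  hpd <- lapply(hpd_mass, function(m) hpd_intervals(cal_bp, dens, m))
  names(hpd) <- sprintf("%.1f%%", 100 * hpd_mass)
  mu_post <- sum(cal_bp * dens)
  structure(list(lab_id = d$lab_id, cal_bp = cal_bp, density = dens,
                 hpd = hpd, mean = mu_post,
                 sd = sqrt(sum((cal_bp - mu_post)^2 * dens)),
                 median = cal_bp[which(cumsum(dens) >= 0.5)[1]],
                 ancestry_class = d$ancestry_class),
            class = "calibrated_density")
}

# HPD by accumulating grid cells in descending density order; contiguous runs
# of selected cells become intervals (older bound first).
hpd_intervals <- function(cal_bp, dens, mass) {
  ord <- order(dens, decreasing = TRUE)
  sel <- logical(length(dens))
  sel[ord[seq_len(which(cumsum(dens[ord]) >= mass)[1])]] <- TRUE
  r <- rle(sel)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- cbind(older = cal_bp[starts[runs]], younger = cal_bp[ends[runs]])
  attr(out, "mass") <- sum(dens[sel])
  out
}

#' @export
print.calibrated_density <- function(x, ...) {
  cat(sprintf("calibrated date %s: mean %.0f cal BP (sd %.0f)\n",
              x$lab_id %||% "", x$mean, x$sd))
  for (nm in names(x$hpd)) {
    iv <- x$hpd[[nm]]
    cat(" ", nm, "HPD:",
        paste(sprintf("%.0f-%.0f", iv[, 1], iv[, 2]), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Combine replicate radiocarbon determinations of one individual
#'
#' Inverse-variance weighted mean with the standard chi-squared consistency
#' test: `T = sum(((x_i - xbar) / sigma_i)^2)` compared with the 5% critical
#' value of a chi-squared distribution on `n - 1` degrees of freedom.
#'
#' @param dates list of [radiocarbon_date()]s (>= 2) for the same individual.
#' @return list: `c14_age`, `sigma`, `chi2_stat`, `chi2_crit`, `df`,
#'   `passes`.
#' @export
combine_dates <- function(dates) {
  if (length(dates) < 2L) stop("need at least 2 replicate dates")
  stopifnot(all(vapply(dates, inherits, logical(1), "radiocarbon_date")))
  x <- vapply(dates, `[[`, 0, "c14_age")
  s <- vapply(dates, `[[`, 0, "sigma")
  w <- 1 / s^2
  xbar <- sum(w * x) / sum(w)
  sig <- 1 / sqrt(sum(w))
  T <- sum(((x - xbar) / s)^2)
  crit <- qchisq(0.95, length(x) - 1L)
  list(c14_age = xbar, sigma = sig, chi2_stat = T, chi2_crit = crit,
       df = length(x) - 1L, passes = T <= crit)
}
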