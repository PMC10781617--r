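#' Collagen quality control on the atomic C:N ratio
#'
#' Collagen with atomic C:N inside the closed interval \[2.9, 3.6\] is
#' considered well preserved (low likelihood of diagenesis); values outside
#' fail.
#'
#' @param cn_atomic atomic C:N ratio(s).
#' @param bounds closed acceptance interval.
#' @return data.frame: `cn_atomic`, `pass`, `reason`.
#' @export
collagen_qc <- function(cn_atomic, bounds = c(2.9, 3.6)) {
  if (anyNA(cn_atomic)) stop("cn_atomic must be present")
  pass <- cn_atomic >= bounds[1] & cn_atomic <= bounds[2]
  reason <- ifelse(pass, "ok",
                   ifelse(cn_atomic < bounds[1],
                          sprintf("C:N<%g", bounds[1]),
                          sprintf("C:N>%g", bounds[2])))
  data.frame(cn_atomic = cn_atomic, pass = pass, reason = reason,
             stringsAsFactors = FALSE)
}

#' Classify diet from collagen isotopes
#'
#' Computes the marine protein fraction by two-endmember delta13C mixing
#' ([marine_fraction()]), classifies it (terrestrial < 0.2, mixed 0.2-0.5,
#' marine-dominated > 0.5) and evaluates the marine-reservoir flag
#' (delta13C >= -18.00 AND delta15N >= +12.00).
#'
#' @param d13c,d15n collagen isotopes (permil); vectorized.
#' @param endmembers passed to [marine_fraction()].
#' @param class_breaks marine-fraction breakpoints `(terrestrial|mixed,
#'   mixed|marine)`.
#' @param d13c_threshold,d15n_threshold reservoir-flag thresholds.
#' @return data.frame: `d13c`, `d15n`, `marine_fraction`, `class`,
#'   `reservoir_flag`.
#' @export
diet_class <- function(d13c, d15n,
                       endmembers = c(terrestrial = -21.0, marine = -12.5),
                       class_breaks = c(0.2, 0.5),
                       d13c_threshold = -18.00, d15n_threshold = 12.00) {
  if (anyNA(d13c) || anyNA(d15n)) stop("isotopes must be present")
  f <- marine_fraction(d13c, endmembers)
  cls <- ifelse(f < class_breaks[1], "terrestrial",
                ifelse(f <= class_breaks[2], "mixed", "marine-dominated"))
  flag <- d13c >= d13c_threshold & d15n >= d15n_threshold
  data.frame(d13c = d13c, d15n = d15n, marine_fraction = f, class = cls,
             reservoir_flag = flag, stringsAsFactors = FALSE)
}

#' Flag strontium-isotope mobility outliers
#'
#' Robust outlier rule relative to the assemblage itself (no geological
#' baseline): flag `|sr - median| > k x MAD` with the scaled MAD
#' (consistency constant 1.4826).  When the MAD is zero the rule falls back
#' to the IQR (flag outside `median +/- k x IQR / 1.349`), with a warning.
#'
#' @param ids sample ids.
#' @param sr_ratio 87Sr/86Sr ratios (>= 5 required).
#' @param k multiplier (default 3).
#' @return data.frame: `id`, `sr_ratio`, `robust_z`, `flagged`.
#' @export
sr_outliers <- function(ids, sr_ratio, k = 3) {
  ok <- !is.na(sr_ratio)
  if (sum(ok) < 5L) stop("need at least 5 Sr measurements")
  med <- median(sr_ratio[ok])
  s <- mad(sr_ratio[ok])           # scaled MAD, constant 1.4826
  if (s == 0) {
    warning("zero MAD: falling back to IQR rule")
    s <- IQR(sr_ratio[ok]) / 1.349
  }
  z <- if (s == 0) ifelse(sr_ratio == med, 0, Inf) else (sr_ratio - med) / s
  flagged <- ok & abs(z) > k
  data.frame(id = ids, sr_ratio = sr_ratio, robust_z = z,
             flagged = flagged, stringsAsFactors = FALSE)
}
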