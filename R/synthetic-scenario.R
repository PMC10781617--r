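#' Specify one ancestry stratum of a synthetic scenario
#'
#' A stratum is a source population occupying a contiguous slice of the
#' scenario's time window: its members carry allele frequencies drifted from a
#' shared ancestral pool (Balding-Nichols), share IBD at a within-stratum rate
#' that exceeds the between-stratum rate, and have collagen isotope and
#' strontium values drawn from stratum-specific distributions.
#'
#' @param name stratum label, e.g. `"hg"`, `"farmer"`, `"steppe"`.
#' @param isotope_means length-2 numeric: mean collagen (delta13C, delta15N)
#'   in permil.
#' @param isotope_sds length-2 numeric SDs in permil.
#' @param sr_mean_sd length-2 numeric: mean and SD of the 87Sr/86Sr ratio.
#' @param ibd_rate_within expected total cM shared per within-stratum pair.
#' @param ibd_rate_between expected total cM shared per between-stratum pair.
#' @param segment_mean_length mean IBD segment length in cM.
#' @return an object of class `stratum_spec`.
#' @export
stratum_spec <- function(name,
                         isotope_means = c(-20, 10),
                         isotope_sds = c(0.5, 0.8),
                         sr_mean_sd = c(0.7095, 5e-4),
                         ibd_rate_within = 30,
                         ibd_rate_between = 5,
                         segment_mean_length = 8) {
  stopifnot(is.character(name), length(name) == 1L,
            length(isotope_means) == 2L, length(isotope_sds) == 2L,
            all(isotope_sds >= 0), length(sr_mean_sd) == 2L,
            segment_mean_length > 0)
  if (!(ibd_rate_within > ibd_rate_between))
    stop("ibd_rate_within must exceed ibd_rate_between")
  if (ibd_rate_between < 0) stop("ibd_rate_between must be >= 0")
  structure(list(name = name,
                 isotope_means = as.numeric(isotope_means),
                 isotope_sds = as.numeric(isotope_sds),
                 sr_mean_sd = as.numeric(sr_mean_sd),
                 ibd_rate_within = ibd_rate_within,
                 ibd_rate_between = ibd_rate_between,
                 segment_mean_length = segment_mean_length),
            class = "stratum_spec")
}

default_strata <- function() {
  list(
    # Mesolithic foragers: marine-shifted collagen, hence reservoir-affected
    stratum_spec("hg", isotope_means = c(-15, 13.5), isotope_sds = c(1.5, 1.0),
                 sr_mean_sd = c(0.7101, 6e-4)),
    # Early farmers: terrestrial diet, d13C ~ -20, d15N ~ 10
    stratum_spec("farmer", isotope_means = c(-20, 10), isotope_sds = c(0.5, 0.8),
                 sr_mean_sd = c(0.7092, 5e-4)),
    stratum_spec("steppe", isotope_means = c(-19.8, 10.8), isotope_sds = c(0.6, 0.9),
                 sr_mean_sd = c(0.7098, 7e-4))
  )
}

#' Define a synthetic cohort scenario
#'
#' The scenario states the generative world: a time window (cal BP), abrupt
#' ancestry turnovers at the stated boundaries, one stratum per inter-boundary
#' interval (oldest first), a single continuous genetic map, and a
#' Balding-Nichols drift parameter controlling inter-stratum FST.
#'
#' Default turnovers (5,900 and 4,850 cal BP) mirror the first appearance of
#' farmer-related and steppe-related ancestry in the southern Scandinavian
#' record, giving an inter-onset duration of 1,050 years.
#'
#' @param n_individuals cohort size (>= 4).
#' @param time_window length-2 numeric `(oldest, youngest)` cal BP.
#' @param turnover_times strictly decreasing cal BP boundaries inside the
#'   window; `length(strata)` must equal `length(turnover_times) + 1`.
#' @param strata list of [stratum_spec()] objects, oldest first.
#' @param genome_map_length total genetic map length in cM.
#' @param n_sites number of biallelic sites (>= 100).
#' @param fst_divergence Balding-Nichols drift parameter in (0, 1); scalar or
#'   one value per stratum.
#' @param c14_sigma 1-sigma measurement noise on synthetic 14C ages, in 14C yr.
#' @param marine_offset full-marine reservoir offset applied to synthetic 14C
#'   ages in proportion to each individual's marine diet fraction, in 14C yr.
#' @param fraction_pseudohaploid fraction of samples emitted as pseudo-haploid
#'   (dosages 0/2 from one sampled allele).
#' @param seed master integer seed.
#' @return an object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_individuals = 60,
                               time_window = c(7000, 3500),
                               turnover_times = c(5900, 4850),
                               strata = default_strata(),
                               genome_map_length = 3500,
                               n_sites = 10000,
                               fst_divergence = 0.1,
                               c14_sigma = 30,
                               marine_offset = 400,
                               fraction_pseudohaploid = 0,
                               seed = 1L) {
  if (n_individuals < 4) stop("n_individuals < 4: degenerate downstream analyses")
  if (n_sites < 100) stop("n_sites < 100: degenerate downstream analyses")
  stopifnot(length(time_window) == 2L, time_window[1] > time_window[2])
  if (length(turnover_times) &&
      (any(diff(turnover_times) >= 0) ||
       any(turnover_times >= time_window[1]) ||
       any(turnover_times <= time_window[2])))
    stop("turnover_times must be strictly decreasing cal BP inside time_window")
  if (length(strata) != length(turnover_times) + 1L)
    stop("need exactly length(turnover_times) + 1 strata")
  if (!all(vapply(strata, inherits, logical(1), "stratum_spec")))
    stop("strata must be stratum_spec objects")
  fst <- rep_len(fst_divergence, length(strata))
  if (any(fst <= 0 | fst >= 1)) stop("fst_divergence must lie in (0, 1)")
  min_len <- min(vapply(strata, `[[`, numeric(1), "segment_mean_length"))
  structure(list(n_individuals = as.integer(n_individuals),
                 time_window = as.numeric(time_window),
                 turnover_times = as.numeric(turnover_times),
                 strata = strata,
                 genome_map_length = genome_map_length,
                 n_sites = as.integer(n_sites),
                 fst_divergence = fst,
                 c14_sigma = c14_sigma,
                 marine_offset = marine_offset,
                 fraction_pseudohaploid = fraction_pseudohaploid,
                 seed = as.integer(seed),
                 min_segment_mean = min_len),
            class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("Synthetic cohort scenario\n")
  cat(sprintf("  %d individuals, %d sites, map %.0f cM, seed %d\n",
              x$n_individuals, x$n_sites, x$genome_map_length, x$seed))
  cat(sprintf("  window %0.f-%0.f cal BP; turnovers at %s\n",
              x$time_window[1], x$time_window[2],
              paste(x$turnover_times, collapse = ", ")))
  cat("  strata:", paste(vapply(x$strata, `[[`, character(1), "name"),
                         collapse = " -> "), "\n")
  invisible(x)
}

# Occupancy interval (oldest, youngest) of stratum k, from window + turnovers.
stratum_intervals <- function(scenario) {
  bounds <- c(scenario$time_window[1], scenario$turnover_times,
              scenario$time_window[2])
  lapply(seq_along(scenario$strata),
         function(k) c(oldest = bounds[k], youngest = bounds[k + 1]))
}
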