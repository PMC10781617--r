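#' Filter sites on allele frequency, imputation quality and mutation class
#'
#' Retains exactly the sites with `maf > min_maf`, `info_score > min_info`
#' (strict inequalities, matching the ">1% minor allele frequency and
#' imputation info score > 0.5" convention for imputed ancient panels) and,
#' if requested, transversion allele pairs only (C<->T and G<->A transitions
#' are removed, since they are confounded by post-mortem deamination).
#' Sites with missing `maf` or `info_score` fail the corresponding predicate
#' only when a threshold above 0 is requested.
#'
#' @param g a [genotype_table()].
#' @param min_maf minor-allele-frequency threshold in `[0, 0.5]` (strict `>`).
#' @param min_info info-score threshold in `[0, 1]` (strict `>`); sites with
#'   NA info score are kept when `min_info = 0`.
#' @param transversions_only drop transition sites.
#' @return a new `genotype_table` with the retained sites, order preserved.
#' @export
filter_sites <- function(g, min_maf = 0.01, min_info = 0.5,
                         transversions_only = FALSE) {
  stopifnot(inherits(g, "genotype_table"),
            min_maf >= 0, min_maf <= 1, min_info >= 0, min_info <= 1)
  s <- g$sites
  keep_maf <- if (min_maf > 0) !is.na(s$maf) & s$maf > min_maf else TRUE
  keep_info <- if (min_info > 0) !is.na(s$info_score) & s$info_score > min_info
               else TRUE
  keep <- keep_maf & keep_info
  if (transversions_only) keep <- keep & s$is_transversion
  if (!any(keep)) warning("no sites retained")
  out <- g
  out$sites <- s[keep, , drop = FALSE]
  rownames(out$sites) <- NULL
  out$dosages <- g$dosages[keep, , drop = FALSE]
  out
}

#' Sample-level quality control with kin-pair resolution
#'
#' Excludes samples with coverage < 0.1x, mean genotype probability < 0.98,
#' or contamination > 5% (strict inequalities; boundary values are retained),
#' then resolves each remaining first/second-degree kin pair by removing the
#' lower-coverage member, iterating until no pair remains.  Coverage ties are
#' broken by removing the lexicographically larger id.
#'
#' @param meta data.frame with columns `id`, `coverage`, `mean_gp`,
#'   `contamination`.
#' @param kin_pairs optional data.frame `(id1, id2, degree)`; degrees 1 and 2
#'   trigger resolution.  Pairs are treated as unordered.
#' @param min_coverage,min_gp,max_contamination thresholds.
#' @return list with `retained` (character ids, input order) and `exclusions`
#'   (data.frame `id`, `reason`).
#' @export
qc_samples <- function(meta, kin_pairs = NULL,
                       min_coverage = 0.1, min_gp = 0.98,
                       max_contamination = 0.05) {
  stopifnot(all(c("id", "coverage", "mean_gp", "contamination") %in% names(meta)))
  excl <- list()
  drop <- function(id, reason) excl[[length(excl) + 1L]] <<-
    data.frame(id = id, reason = reason, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(meta))) {
    m <- meta[i, ]
    if (m$coverage < min_coverage) drop(m$id, sprintf("coverage<%g", min_coverage))
    else if (m$mean_gp < min_gp) drop(m$id, sprintf("mean_gp<%g", min_gp))
    else if (m$contamination > max_contamination)
      drop(m$id, sprintf("contamination>%g", max_contamination))
  }
  excl_ids <- vapply(excl, `[[`, character(1), "id")
  retained <- setdiff(meta$id, excl_ids)

  if (!is.null(kin_pairs) && nrow(kin_pairs)) {
    kp <- kin_pairs[kin_pairs$degree %in% c(1L, 2L), , drop = FALSE]
    cov <- setNames(meta$coverage, meta$id)
    repeat {
      live <- kp$id1 %in% retained & kp$id2 %in% retained
      if (!any(live)) break
      p <- kp[which(live)[1L], ]
      c1 <- cov[[p$id1]]; c2 <- cov[[p$id2]]
      victim <- if (c1 < c2) p$id1
        else if (c2 < c1) p$id2
        else max(p$id1, p$id2)   # tie: larger id removed, deterministic
      drop(victim, sprintf("kin_degree%d_lower_coverage_vs_%s", p$degree,
                           setdiff(c(p$id1, p$id2), victim)))
      retained <- setdiff(retained, victim)
    }
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(id = character(), reason = character(), stringsAsFactors = FALSE)
  list(retained = meta$id[meta$id %in% retained], exclusions = exclusions)
}
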