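#' ABBA-BABA D-statistic with block jackknife
#'
#' Four-population test of treeness on allele frequencies.  Per site,
#' with `p1..p4` the non-missing alternate-allele frequencies of the four
#' groups,
#' \deqn{D = \frac{\sum_s (p_2 - p_1)(p_3 - p_4)}
#'                {\sum_s (p_1 + p_2 - 2 p_1 p_2)(p_3 + p_4 - 2 p_3 p_4)}}
#' which for fixed haploid frequencies reduces to the classic pattern-count
#' form (ABBA - BABA) / (ABBA + BABA).  D > 0 indicates excess allele sharing
#' between P2 and P3 (or P1 and P4).  The Z score comes from a
#' leave-one-block-out jackknife over contiguous genomic blocks; with
#' `weighted = TRUE` blocks are weighted by their site counts (Busing-style
#' delete-m_j jackknife).
#'
#' Transversion filtering, when wanted, is done upstream with
#' [filter_sites()].
#'
#' @param g a [genotype_table()].
#' @param groups list of four character vectors of sample ids, in order
#'   (P1, P2, P3, P4); names are used for reporting when present.
#' @param block_size jackknife block span (bp of physical position; default
#'   5 Mb).
#' @param weighted use site-count block weights.
#' @return object of class `dstat_result`: `populations`, `D`, `Z`,
#'   `n_sites_used`, `n_blocks`, `block_size`.
#' @export
d_statistic <- function(g, groups, block_size = 5e6, weighted = TRUE) {
  stopifnot(inherits(g, "genotype_table"), length(groups) == 4L)
  pops <- names(groups) %||% paste0("P", 1:4)
  idx <- lapply(groups, function(ids) {
    j <- match(ids, g$samples)
    if (anyNA(j)) stop("unknown sample ids: ",
                       paste(ids[is.na(j)], collapse = ", "))
    j
  })
  freqs <- vapply(idx, function(j) {
    d <- g$dosages[, j, drop = FALSE]
    f <- rowMeans(d, na.rm = TRUE) / 2
    f[is.nan(f)] <- NA_real_
    f
  }, numeric(nrow(g$sites)))
  if (any(colSums(!is.na(freqs)) == 0))
    stop("a group has no non-missing calls at any site")
  ok <- rowSums(is.na(freqs)) == 0L
  p1 <- freqs[ok, 1]; p2 <- freqs[ok, 2]; p3 <- freqs[ok, 3]; p4 <- freqs[ok, 4]
  num_s <- (p2 - p1) * (p3 - p4)
  den_s <- (p1 + p2 - 2 * p1 * p2) * (p3 + p4 - 2 * p3 * p4)
  informative <- den_s != 0
  pos <- g$sites$pos[ok]
  chrom <- g$sites$chrom[ok]
  block <- paste0(chrom, ":", pos %/% block_size)
  ub <- unique(block)
  bnum <- vapply(split(num_s, block)[ub], sum, 0)
  bden <- vapply(split(den_s, block)[ub], sum, 0)
  bcnt <- vapply(split(informative, block)[ub], sum, 0)
  nonempty <- bcnt > 0
  if (sum(nonempty) < 3L) stop("jackknife undefined: fewer than 3 non-empty blocks")
  bnum <- bnum[nonempty]; bden <- bden[nonempty]; bcnt <- bcnt[nonempty]
  B <- length(bnum)
  D <- sum(bnum) / sum(bden)
  loo <- (sum(bnum) - bnum) / (sum(bden) - bden)   # delete-one-block estimates
  if (weighted) {
    # Busing et al. delete-m_j jackknife for unequal block sizes
    n_tot <- sum(bcnt)
    h <- n_tot / bcnt
    theta_j <- h * D - (h - 1) * loo
    theta_dot <- B * D - sum((1 - bcnt / n_tot) * loo)
    var_D <- sum((theta_j - theta_dot)^2 / (h - 1)) / B
  } else {
    var_D <- (B - 1) / B * sum((loo - mean(loo))^2)
  }
  Z <- if (var_D > 0) D / sqrt(var_D) else 0
  structure(list(populations = pops, D = D, Z = Z,
                 n_sites_used = sum(informative), n_blocks = B,
                 block_size = block_size),
            class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf("D(%s) = %.4f, Z = %.2f (%d sites, %d blocks)\n",
              paste(x$populations, collapse = ", "),
              x$D, x$Z, x$n_sites_used, x$n_blocks))
  invisible(x)
}
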