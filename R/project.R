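#' Build a PCA reference space from complete genotypes
#'
#' Standard genotype PCA on the reference panel: dosages are centered at
#' `2p` and scaled by `sqrt(2 p (1 - p))` per site (`p` = alt-allele
#' frequency in the reference), then decomposed by SVD.  The site loadings
#' and eigenvalues define the space low-coverage samples are projected onto.
#'
#' @param g a [genotype_table()] with complete (no-missing) dosages.
#' @param k number of components.
#' @return object of class `pca_reference`: `loadings` (sites x k, rownames =
#'   site ids), `eigenvalues`, `site_mean` (= 2p), `site_scale`,
#'   `coordinates` of the reference samples (samples x k).
#' @export
pca_reference <- function(g, k = 2L) {
  stopifnot(inherits(g, "genotype_table"))
  X <- t(g$dosages)                      # samples x sites
  if (anyNA(X)) stop("reference panel must be complete (no missing dosages)")
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  ctr <- 2 * p
  scl <- sqrt(2 * p * (1 - p))
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  if (k >= min(dim(Xs))) stop("k too large for panel dimensions")
  sv <- svd(Xs, nu = k, nv = k)
  loadings <- sv$v
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(k)))
  coords <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  dimnames(coords) <- list(rownames(X), paste0("PC", seq_len(k)))
  structure(list(loadings = loadings,
                 eigenvalues = sv$d^2 / (nrow(X) - 1),
                 site_mean = setNames(ctr, colnames(X)),
                 site_scale = setNames(scl, colnames(X)),
                 coordinates = coords),
            class = "pca_reference")
}

#' Least-squares projection of a (possibly incomplete) sample onto a PCA space
#'
#' Restricted to the sample's non-missing sites, solves the least-squares
#' problem `min || x_S - V_S c ||` for the coordinates `c`, where `x_S` is
#' the mean-centered, frequency-normalized dosage vector and `V_S` the site
#' loadings.  This is the "lsqproject" treatment of missing data: a complete
#' reference sample recovers its reference coordinates exactly, and
#' coordinates remain well-defined under heavy masking.
#'
#' @param ref a [pca_reference()].
#' @param dosages named numeric vector of alt dosages (site id -> 0/1/2, NA
#'   allowed) for one sample.
#' @param min_overlap minimum number of non-missing sites shared with the
#'   loadings (default 10).
#' @return named numeric vector of coordinates (length k).
#' @export
lsq_project <- function(ref, dosages, min_overlap = 10L) {
  stopifnot(inherits(ref, "pca_reference"))
  site_ids <- rownames(ref$loadings)
  x <- dosages[site_ids]
  ok <- !is.na(x)
  if (sum(ok) < min_overlap)
    stop("fewer than ", min_overlap, " non-missing sites overlap the loadings")
  xs <- (x[ok] - ref$site_mean[ok]) / ref$site_scale[ok]
  V <- ref$loadings[ok, , drop = FALSE]
  cf <- qr.coef(qr(V), xs)
  cf[is.na(cf)] <- 0
  setNames(as.numeric(cf), colnames(ref$loadings))
}
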