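#' PCA of the IBD-sharing covariance matrix
#'
#' Eigendecomposition of the covariance matrix of the rows of the pairwise
#' sharing-rate matrix.  The structural zero diagonal (no self-sharing) is
#' replaced by each row's off-diagonal mean before computing covariances, to
#' avoid self-sharing artifacts.  Coordinates are eigenvectors scaled by
#' sqrt(eigenvalue); the sign of each component is fixed so its
#' largest-magnitude loading is positive.
#'
#' @param m an [sharing_matrix()] result.
#' @param k number of components, `k < n`.
#' @return list: `coordinates` (n x k, rownames = ids), `eigenvalues`
#'   (non-increasing, length n), `diagonal` = "row-mean substituted".
#' @export
ibd_pca <- function(m, k = 2L) {
  stopifnot(inherits(m, "ibd_share_matrix"))
  n <- length(m$ids)
  if (k >= n) stop("k must be smaller than the number of individuals")
  R <- m$rate
  if (n > 1L)
    diag(R) <- (rowSums(R) - diag(R)) / (n - 1L)
  V <- cov(t(R))
  e <- eigen(V, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(k)]), k, k)
  for (j in seq_len(k)) {
    i <- which.max(abs(coords[, j]))
    if (length(i) && coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(m$ids, paste0("PC", seq_len(k)))
  list(coordinates = coords, eigenvalues = e$values,
       diagonal = "row-mean substituted")
}
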