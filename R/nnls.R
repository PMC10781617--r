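#' Lawson-Hanson non-negative least squares
#'
#' Solves `min ||Ax - b||^2` subject to `x >= 0` by the classic active-set
#' algorithm.  Small, dependency-free solver used by [nnls_mixture()].
#'
#' @param A numeric matrix (m x p).
#' @param b numeric vector (length m).
#' @param tol convergence tolerance on the dual (gradient) vector.
#' @return list: `x` (solution), `residual_norm`.
#' @export
nnls_solve <- function(A, b, tol = 1e-10) {
  A <- as.matrix(A); b <- as.numeric(b)
  p <- ncol(A)
  x <- rep(0, p)
  passive <- rep(FALSE, p)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0L
  while (any(!passive & w > tol) && iter < 30L * p) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- rep(0, p)
      Ap <- A[, passive, drop = FALSE]
      s[passive] <- drop(qr.coef(qr(Ap), b))
      s[passive][is.na(s[passive])] <- 0   # rank deficiency: drop to zero
      if (all(s[passive] > 0)) break
      neg <- passive & s <= 0
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    x <- s
    w <- drop(crossprod(A, b - A %*% x))
  }
  list(x = x, residual_norm = sqrt(sum((b - A %*% x)^2)))
}

#' Supervised ancestry mixture by NNLS on relative IBD-sharing vectors
#'
#' Expresses a target individual's IBD-sharing profile across reference
#' clusters as a non-negative mixture of source profiles in the same feature
#' space.  Every vector is first normalized to sum to one ("relative"
#' sharing rates), the NNLS problem is solved to tolerance `tol`, and the
#' weights are renormalized to sum to one; they are read as ancestry
#' proportions.
#'
#' @param target_vector non-negative sharing-rate vector over reference
#'   features.
#' @param source_vectors matrix with one column per source (features x
#'   sources) or a named list of vectors; same feature space as the target.
#' @param tol NNLS convergence tolerance.
#' @return object of class `mixture_result`: `weights` (named, sum to 1),
#'   `residual_norm`, `n_reference_features`, `condition_number`.
#' @export
nnls_mixture <- function(target_vector, source_vectors, tol = 1e-10) {
  if (is.list(source_vectors))
    source_vectors <- do.call(cbind, source_vectors)
  S <- as.matrix(source_vectors)
  y <- as.numeric(target_vector)
  if (ncol(S) < 2L) stop("need at least 2 sources")
  if (nrow(S) < ncol(S)) stop("feature dimension must be >= number of sources")
  if (length(y) != nrow(S)) stop("target and sources differ in feature space")
  if (any(y < 0) || any(S < 0)) stop("sharing vectors must be non-negative")
  if (sum(y) == 0) stop("no sharing signal: all-zero target")
  if (any(colSums(S) == 0)) stop("all-zero source vector")
  yn <- y / sum(y)
  Sn <- sweep(S, 2, colSums(S), "/")
  kappa <- kappa(Sn, exact = TRUE)
  if (kappa > 1e8)
    warning(sprintf("sources nearly collinear (condition number %.3g)", kappa))
  fit <- nnls_solve(Sn, yn, tol = tol)
  w <- fit$x
  if (sum(w) == 0) stop("degenerate NNLS solution: zero weights")
  w <- w / sum(w)
  names(w) <- colnames(S) %||% paste0("source", seq_len(ncol(S)))
  structure(list(weights = w, residual_norm = fit$residual_norm,
                 n_reference_features = nrow(S), condition_number = kappa),
            class = "mixture_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mixture_result <- function(x, ...) {
  cat("NNLS ancestry mixture (weights sum to 1):\n")
  print(round(x$weights, 4))
  cat(sprintf("residual norm %.4g over %d features\n",
              x$residual_norm, x$n_reference_features))
  invisible(x)
}

#' Relative sharing feature vectors for mixture modelling
#'
#' Builds the NNLS feature space from a sharing matrix and a cluster
#' assignment: the feature vector of an individual is its mean sharing rate
#' with the members of each reference cluster (excluding itself).
#'
#' @param m an [sharing_matrix()] result.
#' @param clusters named character vector (id -> cluster label) or a
#'   `cluster_assignment`; clusters listed in `reference_clusters` define the
#'   feature axes.
#' @param reference_clusters cluster labels used as features (default: all).
#' @return matrix individuals x reference clusters of mean sharing rates.
#' @export
sharing_features <- function(m, clusters, reference_clusters = NULL) {
  stopifnot(inherits(m, "ibd_share_matrix"))
  if (inherits(clusters, "cluster_assignment"))
    clusters <- setNames(clusters$assignment$level1, clusters$assignment$id)
  labs <- clusters[m$ids]
  if (anyNA(labs)) stop("cluster label missing for some ids")
  refs <- reference_clusters %||% sort(unique(labs))
  out <- matrix(0, length(m$ids), length(refs),
                dimnames = list(m$ids, refs))
  for (r in seq_along(refs)) {
    memb <- m$ids[labs == refs[r]]
    for (i in seq_along(m$ids)) {
      others <- setdiff(memb, m$ids[i])
      out[i, r] <- if (length(others)) mean(m$rate[m$ids[i], others]) else 0
    }
  }
  out
}
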