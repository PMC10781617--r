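#' Hierarchical community detection on an IBD-sharing network
#'
#' Deterministic greedy modularity agglomeration on the weighted sharing
#' network (edge weight = pairwise sharing rate): starting from singleton
#' communities, repeatedly merge the community pair with the largest
#' weighted-modularity gain, stopping when the best gain falls below
#' `gain_tol`; then recurse within every community of at least `min_size`
#' members to produce nested levels.  Ties in the merge gain are broken by
#' the lexicographically smallest (community-label) pair, so the partition is
#' invariant to the input order.
#'
#' @param m an [sharing_matrix()] result.
#' @param min_size smallest community that is recursed into.
#' @param gain_tol stop when the best modularity gain drops below this.
#' @param max_levels maximum nesting depth.
#' @return object of class `cluster_assignment`: data.frame `assignment` with
#'   `id` and `level1`, `level2`, ... labels (nested, dot-separated), and
#'   `modularity`, the global modularity of each level's partition.
#' @export
detect_communities <- function(m, min_size = 6L, gain_tol = 1e-12,
                               max_levels = 3L) {
  stopifnot(inherits(m, "ibd_share_matrix"))
  ids <- m$ids
  if (length(ids) < 2L) stop("need at least 2 individuals")
  A <- m$rate
  if (all(A == 0)) {
    warning("all-zero sharing matrix: returning a single community")
    assign <- data.frame(id = ids, level1 = "1", stringsAsFactors = FALSE)
    return(structure(list(assignment = assign, modularity = 0),
                     class = "cluster_assignment"))
  }
  labels <- rec_communities(A, ids, min_size, gain_tol, max_levels, prefix = "")
  depth <- max(lengths(strsplit(labels, ".", fixed = TRUE)))
  assign <- data.frame(id = ids, stringsAsFactors = FALSE)
  mods <- numeric(depth)
  for (lev in seq_len(depth)) {
    lv <- vapply(strsplit(labels, ".", fixed = TRUE), function(p)
      paste(p[seq_len(min(lev, length(p)))], collapse = "."), character(1))
    assign[[paste0("level", lev)]] <- lv
    mods[lev] <- modularity_q(A, lv)
  }
  structure(list(assignment = assign, modularity = mods),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  lv <- grep("^level", names(x$assignment), value = TRUE)
  for (l in seq_along(lv))
    cat(sprintf("level %d: %d communities, modularity %.4f\n",
                l, length(unique(x$assignment[[lv[l]]])), x$modularity[l]))
  invisible(x)
}

# recursive greedy agglomeration; returns dot-separated nested labels
rec_communities <- function(A, ids, min_size, gain_tol, levels_left, prefix) {
  part <- greedy_modularity(A, ids, gain_tol)
  comm <- sort(unique(part))
  labels <- paste0(prefix, match(part, comm))
  if (levels_left <= 1L || length(comm) == 0L) return(labels)
  for (ci in seq_along(comm)) {
    memb <- which(part == comm[ci])
    if (length(memb) >= min_size) {
      sub <- rec_communities(A[memb, memb, drop = FALSE], ids[memb],
                             min_size, gain_tol, levels_left - 1L,
                             prefix = paste0(prefix, ci, "."))
      # only keep the refinement if it actually split the community
      if (length(unique(sub)) > 1L) labels[memb] <- sub
    }
  }
  labels
}

# one level of deterministic greedy modularity agglomeration.
# Returns, per node, the community label = lexicographically smallest member id.
greedy_modularity <- function(A, ids, gain_tol) {
  n <- nrow(A)
  if (n == 1L) return(ids)
  two_m <- sum(A)
  if (two_m == 0) return(ids)          # no edges: singletons
  C <- A                                # between-community weight (ordered sums)
  K <- rowSums(A)                       # community total degree
  lab <- ids                            # community label = smallest member id
  alive <- rep(TRUE, n)
  members <- as.list(seq_len(n))
  repeat {
    idx <- which(alive)
    if (length(idx) < 2L) break
    # gain of merging a,b: 2*( C[a,b]/2m - K_a K_b/(2m)^2 )
    sub <- C[idx, idx, drop = FALSE]
    gain <- 2 * (sub / two_m - outer(K[idx], K[idx]) / two_m^2)
    diag(gain) <- -Inf
    best <- max(gain)
    if (best < gain_tol) break
    cand <- which(gain == best, arr.ind = TRUE)
    # lexicographic tie-break on the (sorted) community-label pair
    keys <- apply(cand, 1, function(rc) {
      l <- sort(c(lab[idx[rc[1]]], lab[idx[rc[2]]]))
      paste(l, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    a <- idx[pick[1L]]; b <- idx[pick[2L]]
    if (lab[b] < lab[a]) { tmp <- a; a <- b; b <- tmp }
    # merge b into a
    C[a, ] <- C[a, ] + C[b, ]
    C[, a] <- C[, a] + C[, b]
    C[a, a] <- C[a, a]                 # self weight accumulates via both axes
    K[a] <- K[a] + K[b]
    members[[a]] <- c(members[[a]], members[[b]])
    alive[b] <- FALSE
  }
  out <- character(n)
  for (a in which(alive)) out[members[[a]]] <- lab[a]
  out
}

# global weighted modularity of a labelled partition
modularity_q <- function(A, labels) {
  two_m <- sum(A)
  if (two_m == 0) return(0)
  K <- rowSums(A)
  q <- 0
  for (c in unique(labels)) {
    i <- labels == c
    q <- q + sum(A[i, i]) / two_m - (sum(K[i]) / two_m)^2
  }
  q
}
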