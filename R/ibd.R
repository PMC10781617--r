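#' Construct an IBD segment table
#'
#' Pairwise IBD segments as produced by a segment-detection tool: one row per
#' segment with genetic-map coordinates in cM.  Pair keys are canonicalized
#' (lexicographically smaller id first) and `length_cM` is validated against
#' the coordinates.
#'
#' @param segs data.frame with columns `sample1`, `sample2`, `chrom`,
#'   `start_cM`, `end_cM` and optionally `length_cM`.
#' @param min_length detection-time minimum segment length (cM), recorded as
#'   metadata.
#' @return object of class `ibd_segments`.
#' @export
ibd_segments <- function(segs, min_length = 0) {
  segs <- as.data.frame(segs, stringsAsFactors = FALSE)
  need <- c("sample1", "sample2", "chrom", "start_cM", "end_cM")
  stopifnot(all(need %in% names(segs)))
  if (is.null(segs$length_cM)) segs$length_cM <- segs$end_cM - segs$start_cM
  if (nrow(segs)) {
    if (any(segs$length_cM <= 0)) stop("segments must have positive length")
    if (any(abs(segs$end_cM - segs$start_cM - segs$length_cM) > 1e-6))
      stop("length_cM inconsistent with start/end")
    flip <- segs$sample1 > segs$sample2
    tmp <- segs$sample1[flip]
    segs$sample1[flip] <- segs$sample2[flip]
    segs$sample2[flip] <- tmp
  }
  structure(list(segments = segs, min_length = min_length),
            class = "ibd_segments")
}

#' Read/write IBD segments as TSV
#'
#' Columns: sample1, sample2, chrom, start_cM, end_cM, length_cM.
#' @param path TSV file.
#' @param min_length recorded detection threshold (cM).
#' @return [ibd_segments()] (read) or `path` invisibly (write).
#' @export
read_ibd_segments <- function(path, min_length = 0) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  ibd_segments(dt, min_length = min_length)
}

#' @rdname read_ibd_segments
#' @param segs an [ibd_segments()] object.
#' @export
write_ibd_segments <- function(segs, path) {
  stopifnot(inherits(segs, "ibd_segments"))
  data.table::fwrite(segs$segments, path, sep = "\t")
  invisible(path)
}

#' Total and relative pairwise IBD sharing
#'
#' Sums segment lengths per unordered pair (segments below `min_segment_cM`
#' are ignored: short segments are dominated by detection noise) and
#' normalizes by the analyzable map length to give a dimensionless sharing
#' rate, the edge weight of the sharing network.
#'
#' @param segs an [ibd_segments()] table.
#' @param ids sample ids defining matrix order; every segment id must appear.
#' @param map_length analyzable genetic map length in cM.
#' @param min_segment_cM minimum segment length retained.
#' @return object of class `ibd_share_matrix` with `ids`, symmetric
#'   `total_cM` and `rate` matrices (zero diagonal), `map_length`.
#' @export
sharing_matrix <- function(segs, ids, map_length, min_segment_cM = 1.0) {
  stopifnot(inherits(segs, "ibd_segments"), map_length > 0,
            !anyDuplicated(ids))
  s <- segs$segments
  unknown <- setdiff(unique(c(s$sample1, s$sample2)), ids)
  if (length(unknown))
    stop("segments reference unknown ids: ", paste(unknown, collapse = ", "))
  n <- length(ids)
  tot <- matrix(0, n, n, dimnames = list(ids, ids))
  s <- s[s$length_cM >= min_segment_cM, , drop = FALSE]
  if (nrow(s)) {
    key <- paste(s$sample1, s$sample2, sep = "\r")
    total <- rowsum(s$length_cM, key)
    pair <- strsplit(rownames(total), "\r", fixed = TRUE)
    i <- match(vapply(pair, `[`, "", 1), ids)
    j <- match(vapply(pair, `[`, "", 2), ids)
    tot[cbind(i, j)] <- total[, 1]
    tot[cbind(j, i)] <- total[, 1]
  }
  if (any(tot > 2 * map_length))
    stop("pair total exceeds 2 x map length: inconsistent input")
  structure(list(ids = ids, total_cM = tot, rate = tot / map_length,
                 map_length = map_length, min_segment_cM = min_segment_cM),
            class = "ibd_share_matrix")
}

#' @export
print.ibd_share_matrix <- function(x, ...) {
  cat(sprintf("ibd_share_matrix: %d individuals, map %.0f cM, mean rate %.4g\n",
              length(x$ids), x$map_length,
              mean(x$rate[upper.tri(x$rate)])))
  invisible(x)
}
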