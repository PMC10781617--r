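#' Run the end-to-end multiproxy pipeline
#'
#' Orchestrates qc -> IBD sharing -> clustering -> NNLS mixtures ->
#' calibration (+ optional two-phase model) -> phenotypes -> isotopes and
#' assembles the chronologically sorted multiproxy table (one row per
#' retained individual).  A failure or absent input for one proxy degrades
#' gracefully: the affected columns are set missing and the failure logged,
#' other columns are unchanged.
#'
#' @param cohort a `synthetic_cohort` (from [generate_cohort()] or
#'   [read_cohort()]) or a directory path accepted by [read_cohort()].
#' @param config list of parameters; recognized entries (all optional):
#'   `map_length` (cM, default 3500), `min_segment_cM` (1), `gain_tol`,
#'   `min_cluster_size`, `source_labels` (named vector id -> source group;
#'   default the metadata `group_label`), `weight_threshold` (0.25),
#'   `endmembers`, `full_marine_offset`, `run_phase_model` (FALSE),
#'   `phase_classes` (`c("farmer","steppe")`), `mcmc` (list n_iter, n_burn,
#'   n_chains), `pigmentation_panel` ([phenotype_panel()]),
#'   `pgs_panel` ([read_pgs_panel()] table), `pgs_reference` (numeric),
#'   `seed` (1).
#' @param out_dir optional output directory; when given, the multiproxy
#'   table, per-stage artifacts, a JSON summary, the echoed config and a log
#'   are written there.
#' @return list of class `pipeline_result`: `multiproxy` (data.frame),
#'   `qc`, `clusters`, `mixtures`, `phase_model` (or NULL), `turnovers`,
#'   `log` (character).
#' @export
run_pipeline <- function(cohort, config = list(), out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  cfg <- utils::modifyList(list(
    map_length = 3500, min_segment_cM = 1.0, gain_tol = 1e-12,
    min_cluster_size = 6L, source_labels = NULL, weight_threshold = 0.25,
    endmembers = c(terrestrial = -21.0, marine = -12.5),
    full_marine_offset = c(400, 50), run_phase_model = FALSE,
    phase_classes = c("farmer", "steppe"),
    mcmc = list(n_iter = 2000L, n_burn = 500L, n_chains = 2L),
    pigmentation_panel = NULL, pgs_panel = NULL, pgs_reference = NULL,
    cm_per_sd = 1.0, seed = 1L), config)
  logline <- character()
  say <- function(...) logline <<- c(logline, sprintf(...))
  say("pipeline start: seed %d", cfg$seed)

  # --- stage 1: sample QC
  qc <- qc_samples(cohort$meta, kin_pairs = cohort$kin_pairs)
  ids <- qc$retained
  say("qc: retained %d of %d samples", length(ids), nrow(cohort$meta))

  # --- stage 2-3: IBD sharing + clustering
  m <- sharing_matrix(subset_segments(cohort$ibd, ids), ids,
                      map_length = cfg$map_length,
                      min_segment_cM = cfg$min_segment_cM)
  clus <- detect_communities(m, min_size = cfg$min_cluster_size,
                             gain_tol = cfg$gain_tol)
  say("clustering: %d level-1 communities, modularity %.3f",
      length(unique(clus$assignment$level1)), clus$modularity[1])

  # --- stage 4: supervised NNLS mixtures
  src_lab <- cfg$source_labels %||%
    setNames(cohort$meta$group_label, cohort$meta$id)
  feats <- sharing_features(m, clus)
  src_names <- sort(unique(src_lab[ids]))
  S <- vapply(src_names, function(g) {
    memb <- ids[src_lab[ids] == g]
    colMeans(feats[memb, , drop = FALSE])
  }, numeric(ncol(feats)))
  mixtures <- matrix(NA_real_, length(ids), length(src_names),
                     dimnames = list(ids, src_names))
  for (i in ids) {
    res <- tryCatch(nnls_mixture(feats[i, ], S), error = function(e) NULL)
    if (!is.null(res)) mixtures[i, ] <- res$weights
    else say("mixture failed for %s", i)
  }

  # --- stage 5: chronology
  cal <- list()
  rc <- cohort$radiocarbon
  if (!is.null(rc) && nrow(rc)) {
    for (r in seq_len(nrow(rc))) {
      d <- radiocarbon_date(rc$lab_id[r], rc$c14_age[r], rc$sigma[r],
                            d13c = rc$d13c[r], d15n = rc$d15n[r],
                            cn_atomic = rc$cn_atomic[r],
                            ancestry_class = rc$ancestry_class[r])
      cal[[rc$lab_id[r]]] <- tryCatch({
        d <- reservoir_correct(d, endmembers = cfg$endmembers,
                               full_marine_offset = cfg$full_marine_offset)
        calibrate(d, cohort$curve, grid_resolution = 5)
      }, error = function(e) { say("calibration failed for %s: %s",
                                   rc$lab_id[r], conditionMessage(e)); NULL })
    }
  }
  phase <- NULL
  if (isTRUE(cfg$run_phase_model)) {
    usable <- Filter(Negate(is.null), cal)
    phase <- tryCatch(
      fit_phase_model(usable, classes = cfg$phase_classes,
                      n_iter = cfg$mcmc$n_iter, n_burn = cfg$mcmc$n_burn,
                      n_chains = cfg$mcmc$n_chains, seed = cfg$seed),
      error = function(e) { say("phase model failed: %s",
                                conditionMessage(e)); NULL })
  }

  # --- stage 6: phenotypes (graceful when no panel is configured)
  dos <- cohort$genotypes$dosages
  eye_cols <- NULL; pgs_col <- rep(NA_real_, length(ids))
  if (!is.null(cfg$pigmentation_panel)) {
    pp <- cfg$pigmentation_panel
    eye_cols <- t(vapply(ids, function(i) {
      pr <- tryCatch(pigmentation_probs(dos[, i], pp), error = function(e) NULL)
      if (is.null(pr)) rep(NA_real_, length(pp$categories)) else
        as.numeric(pr[pp$categories])
    }, numeric(length(pp$categories))))
    colnames(eye_cols) <- paste0("p_", pp$categories)
  } else say("pigmentation panel absent: columns skipped")
  if (!is.null(cfg$pgs_panel)) {
    pgs_col <- vapply(ids, function(i) {
      r <- tryCatch(height_pgs(dos[, i], cfg$pgs_panel,
                               reference_scores = cfg$pgs_reference,
                               cm_per_sd = cfg$cm_per_sd),
                    error = function(e) NULL)
      if (is.null(r)) NA_real_
      else if (!is.na(r$standardized)) r$standardized else r$raw
    }, 0)
  } else say("PGS panel absent: column skipped")

  # --- stage 7: isotopes
  iso <- cohort$isotopes
  iso <- iso[match(ids, iso$id), , drop = FALSE]
  diet <- tryCatch(diet_class(iso$d13c, iso$d15n, endmembers = cfg$endmembers),
                   error = function(e) NULL)
  cqc <- tryCatch(collagen_qc(iso$cn_atomic), error = function(e) NULL)
  srf <- tryCatch(sr_outliers(iso$id, iso$sr_ratio), error = function(e) NULL)

  # --- assemble multiproxy table, chronologically sorted (oldest first)
  date_mid <- vapply(ids, function(i) {
    if (!is.null(cal[[i]])) cal[[i]]$median
    else if ("date_mid" %in% names(cohort$meta))
      cohort$meta$date_mid[match(i, cohort$meta$id)]
    else NA_real_
  }, 0)
  lv <- clus$assignment
  tab <- data.frame(id = ids, date_mid = date_mid,
                    cluster = lv$level1[match(ids, lv$id)],
                    stringsAsFactors = FALSE)
  if ("level2" %in% names(lv))
    tab$subcluster <- lv$level2[match(ids, lv$id)]
  colnames(mixtures) <- paste0("w_", colnames(mixtures))
  tab <- cbind(tab, as.data.frame(mixtures))
  if (!is.null(eye_cols)) tab <- cbind(tab, as.data.frame(eye_cols))
  tab$height_pgs <- pgs_col
  tab$d13c <- iso$d13c; tab$d15n <- iso$d15n
  tab$marine_class <- if (!is.null(diet)) diet$class else NA_character_
  tab$reservoir_flag <- if (!is.null(diet)) diet$reservoir_flag else NA
  tab$collagen_pass <- if (!is.null(cqc)) cqc$pass else NA
  tab$sr_flag <- if (!is.null(srf)) srf$flagged[match(ids, srf$id)] else NA
  tab$qc_status <- "retained"
  tab <- tab[order(-tab$date_mid, tab$id), ]
  rownames(tab) <- NULL

  turn <- detect_turnovers(tab, weight_threshold = cfg$weight_threshold)
  say("pipeline done: %d rows", nrow(tab))

  out <- structure(list(multiproxy = tab, qc = qc, clusters = clus,
                        mixtures = mixtures, phase_model = phase,
                        turnovers = turn, sharing = m, log = logline,
                        config = cfg),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(tab, file.path(out_dir, "multiproxy.csv"), row.names = FALSE)
    write.csv(qc$exclusions, file.path(out_dir, "qc_exclusions.csv"),
              row.names = FALSE)
    write.csv(clus$assignment, file.path(out_dir, "clusters.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(turnovers = turn,
           config = cfg[vapply(cfg, function(x)
             is.atomic(x) || is.list(x) && all(vapply(x, is.atomic, TRUE)),
             TRUE)]),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
    writeLines(logline, file.path(out_dir, "pipeline.log"))
  }
  out
}

# keep only segments among retained ids
subset_segments <- function(segs, ids) {
  s <- segs$segments
  keep <- s$sample1 %in% ids & s$sample2 %in% ids
  ibd_segments(s[keep, , drop = FALSE], min_length = segs$min_length)
}

#' First chronological appearance of each ancestry
#'
#' For each ancestry weight column (`w_*`) of a multiproxy table, returns
#' the chronologically earliest (oldest) individual whose weight is at least
#' `weight_threshold`; ties in date are broken by the smaller id (logged via
#' a `tie` flag).  Ancestries with no qualifying individual are omitted.
#'
#' @param table multiproxy data.frame with `id`, `date_mid` and `w_*`
#'   columns.
#' @param weight_threshold minimum mixture weight counting as "present".
#' @return data.frame: `ancestry`, `first_id`, `date`, `weight`, `tie`.
#' @export
detect_turnovers <- function(table, weight_threshold = 0.25) {
  wcols <- grep("^w_", names(table), value = TRUE)
  if (!length(wcols)) stop("no ancestry weight columns (w_*) present")
  rows <- list()
  for (wc in wcols) {
    ok <- which(!is.na(table[[wc]]) & table[[wc]] >= weight_threshold)
    if (!length(ok)) next
    dmax <- max(table$date_mid[ok], na.rm = TRUE)
    cand <- ok[table$date_mid[ok] == dmax]
    pick <- cand[order(table$id[cand])][1L]
    rows[[wc]] <- data.frame(ancestry = sub("^w_", "", wc),
                             first_id = table$id[pick],
                             date = table$date_mid[pick],
                             weight = table[[wc]][pick],
                             tie = length(cand) > 1L,
                             stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(ancestry = character(), first_id = character(),
                      date = numeric(), weight = numeric(), tie = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline result: %d individuals, %d level-1 clusters\n",
              nrow(x$multiproxy),
              length(unique(x$multiproxy$cluster))))
  if (nrow(x$turnovers)) {
    cat("first appearances:\n")
    print(x$turnovers)
  }
  invisible(x)
}
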