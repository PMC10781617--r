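#' Load a pigmentation prediction panel
#'
#' Panel format for HIrisPlex-style multinomial-logistic pigmentation models:
#' a TSV with columns `variant`, `effect_allele`, `category`, `beta` (one row
#' per variant x non-reference category) and a JSON file of per-category
#' intercepts plus the reference category.  The bundled
#' `synthetic_pigmentation_panel` fixture is a synthetic stand-in with the
#' structure (18 variants; eye: blue/intermediate/brown; hair:
#' blond/brown/black/red) but not the published coefficients; real panels
#' drop in via the same files.
#'
#' @param beta_path TSV of coefficients.
#' @param intercept_path JSON: `{"reference": "...", "intercepts": {cat: x}}`.
#' @return object of class `phenotype_panel`.
#' @export
read_phenotype_panel <- function(beta_path, intercept_path) {
  beta <- read.table(beta_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  stopifnot(all(c("variant", "effect_allele", "category", "beta") %in%
                  names(beta)))
  ij <- jsonlite::read_json(intercept_path, simplifyVector = TRUE)
  phenotype_panel(beta, unlist(ij$intercepts), ij$reference)
}

#' @rdname read_phenotype_panel
#' @param beta data.frame of coefficients (see above).
#' @param intercepts named numeric, one per non-reference category.
#' @param reference reference category name (receives residual probability).
#' @export
phenotype_panel <- function(beta, intercepts, reference) {
  cats <- sort(unique(beta$category))
  if (!setequal(cats, names(intercepts)))
    stop("intercepts must cover exactly the non-reference categories")
  cnt <- table(beta$variant)
  if (any(cnt != length(cats)))
    stop("every variant needs a coefficient for every non-reference category")
  structure(list(beta = beta, intercepts = intercepts[cats],
                 reference = reference, categories = c(cats, reference)),
            class = "phenotype_panel")
}

#' Pigmentation category probabilities from effect-allele dosages
#'
#' Multinomial logistic prediction: for each non-reference category `c`,
#' `score_c = intercept_c + sum_v beta_{c,v} dosage_v` and
#' `p_c = exp(score_c) / (1 + sum_{c'} exp(score_{c'}))`; the reference
#' category takes the residual mass.  Variants with missing dosage are
#' dropped and the prediction is flagged low-confidence with the dropped
#' count.
#'
#' @param dosages named numeric vector, effect-allele dosage in `[0, 2]` per
#'   panel variant (NA = missing).
#' @param panel a [phenotype_panel()].
#' @return named probability vector (sums to 1) with attributes
#'   `n_dropped` and `low_confidence`.
#' @export
pigmentation_probs <- function(dosages, panel) {
  stopifnot(inherits(panel, "phenotype_panel"))
  vars <- unique(panel$beta$variant)
  d <- dosages[vars]
  names(d) <- vars
  dropped <- vars[is.na(d)]
  use <- setdiff(vars, dropped)
  cats <- setdiff(panel$categories, panel$reference)
  scores <- vapply(cats, function(ct) {
    b <- panel$beta[panel$beta$category == ct, ]
    b <- b[b$variant %in% use, ]
    panel$intercepts[[ct]] + sum(b$beta * d[b$variant])
  }, 0)
  es <- exp(scores)
  p <- es / (1 + sum(es))
  p <- c(p, setNames(1 - sum(p), panel$reference))
  attr(p, "n_dropped") <- length(dropped)
  attr(p, "low_confidence") <- length(dropped) > 0L
  p
}

#' Load a polygenic score panel
#'
#' TSV with columns `locus`, `effect_allele`, `beta` (trait units per
#' effect allele); loci must be unique and betas finite.
#'
#' @param path TSV file.
#' @return data.frame of class `pgs_panel`.
#' @export
read_pgs_panel <- function(path) {
  p <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("locus", "effect_allele", "beta") %in% names(p)))
  if (anyDuplicated(p$locus)) stop("duplicate loci in PGS panel")
  if (!all(is.finite(p$beta))) stop("non-finite betas in PGS panel")
  class(p) <- c("pgs_panel", "data.frame")
  p
}

#' Polygenic score from imputed dosages
#'
#' Raw score = sum of allelic effects times effect-allele dosage over
#' non-missing loci, rescaled by (panel size / non-missing count) so scores
#' with different missingness stay comparable; at least 50% of the panel must
#' be non-missing.  Standardization is against a reference population of raw
#' scores; `delta = standardized x cm_per_sd` converts to trait units when a
#' per-SD scale is configured (default 1: report SD units).
#'
#' @param dosages named numeric vector (locus -> dosage in `[0, 2]`, NA
#'   missing).
#' @param panel a [read_pgs_panel()] data.frame (columns `locus`, `beta`).
#' @param reference_scores numeric vector of raw scores in the reference
#'   population (optional; required for standardization).
#' @param cm_per_sd trait units per reference SD.
#' @return list: `raw`, `standardized`, `delta`, `n_used`, `n_panel`.
#' @export
height_pgs <- function(dosages, panel, reference_scores = NULL,
                       cm_per_sd = 1.0) {
  d <- dosages[panel$locus]
  ok <- !is.na(d)
  if (sum(ok) < 0.5 * nrow(panel))
    stop("insufficient panel coverage: fewer than 50% of loci non-missing")
  raw <- sum(panel$beta[ok] * d[ok]) * nrow(panel) / sum(ok)
  std <- delta <- NA_real_
  if (!is.null(reference_scores) && length(reference_scores) > 1L) {
    std <- (raw - mean(reference_scores)) / sd(reference_scores)
    delta <- std * cm_per_sd
  }
  list(raw = raw, standardized = std, delta = delta,
       n_used = sum(ok), n_panel = nrow(panel))
}
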