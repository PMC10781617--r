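#' Write a synthetic cohort to a directory of standard files
#'
#' Emits the cohort in the formats the pipeline consumes: EIGENSTRAT triplet
#' (`genotypes.{geno,snp,ind}`) and minimal VCF (`genotypes.vcf`); IBD
#' segments TSV; metadata / isotope / radiocarbon CSVs; the calibration
#' curve as IntCal-style `.14c` text; and the truth table CSV.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_genotypes(cohort$genotypes, p("genotypes"), "eigenstrat")
  write_genotypes(cohort$genotypes, p("genotypes.vcf"), "vcf")
  write_ibd_segments(cohort$ibd, p("ibd_segments.tsv"))
  write.csv(cohort$meta, p("metadata.csv"), row.names = FALSE)
  write.csv(cohort$isotopes, p("isotopes.csv"), row.names = FALSE)
  write.csv(cohort$radiocarbon, p("radiocarbon.csv"), row.names = FALSE)
  write.csv(cohort$truth, p("truth.csv"), row.names = FALSE)
  write_calcurve(cohort$curve, p("curve.14c"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory path.
#' @return list with the same data elements as a [generate_cohort()] result
#'   (minus the scenario; `truth` only if present).
#' @export
read_cohort <- function(dir) {
  p <- function(...) file.path(dir, ...)
  out <- list(
    genotypes = read_genotypes(p("genotypes"), "eigenstrat"),
    ibd = read_ibd_segments(p("ibd_segments.tsv")),
    meta = read.csv(p("metadata.csv"), stringsAsFactors = FALSE),
    isotopes = read.csv(p("isotopes.csv"), stringsAsFactors = FALSE),
    radiocarbon = read.csv(p("radiocarbon.csv"), stringsAsFactors = FALSE),
    curve = read_calcurve(p("curve.14c")))
  if (file.exists(p("truth.csv")))
    out$truth <- read.csv(p("truth.csv"), stringsAsFactors = FALSE)
  class(out) <- "synthetic_cohort"
  out
}
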