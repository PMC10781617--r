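#' Construct a genotype table
#'
#' Container for biallelic dosages over samples: alt-allele counts in
#' \{0, 1, 2, NA\} for diploid samples, \{0, 2, NA\} for pseudo-haploid ones.
#' `maf` is computed from non-missing dosages when not supplied;
#' `is_transversion` is derived from the allele pair (transitions are
#' C<->T and G<->A, either order).
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `maf`, `info_score`, `id`.
#' @param samples character vector of sample ids.
#' @param dosages integer matrix, sites x samples.
#' @param ploidy `"diploid"` or `"pseudohaploid"` per sample (recycled).
#' @return object of class `genotype_table`.
#' @export
genotype_table <- function(sites, samples, dosages, ploidy = "diploid") {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
            nrow(dosages) == nrow(sites), ncol(dosages) == length(samples))
  ploidy <- rep_len(ploidy, length(samples))
  bad <- dosages[, ploidy == "pseudohaploid", drop = FALSE] == 1L
  if (any(bad, na.rm = TRUE))
    stop("pseudo-haploid samples must not carry dosage 1")
  if (!all(dosages %in% c(0L, 1L, 2L, NA)))
    stop("dosages must be 0, 1, 2 or NA")
  if (is.null(sites$id))
    sites$id <- paste0(sites$chrom, "_", sites$pos)
  sites$is_transversion <- is_transversion(sites$ref, sites$alt)
  if (is.null(sites$maf)) sites$maf <- site_maf(dosages)
  if (is.null(sites$info_score)) sites$info_score <- NA_real_
  dimnames(dosages) <- list(sites$id, samples)
  structure(list(sites = sites, samples = samples,
                 dosages = dosages, ploidy = ploidy),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d sites x %d samples (%d pseudo-haploid)\n",
              nrow(x$sites), length(x$samples),
              sum(x$ploidy == "pseudohaploid")))
  invisible(x)
}

is_transversion <- function(ref, alt) {
  a <- pmin(toupper(ref), toupper(alt))
  b <- pmax(toupper(ref), toupper(alt))
  !((a == "C" & b == "T") | (a == "A" & b == "G"))
}

# minor allele frequency from non-missing dosages (no imputation)
site_maf <- function(dosages) {
  f <- rowMeans(dosages, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA_real_
  pmin(f, 1 - f)
}

#' Read genotypes from EIGENSTRAT triplet or VCF
#'
#' EIGENSTRAT: `path` is the prefix of a `.geno`/`.snp`/`.ind` triplet; geno
#' characters count copies of the reference allele (column 5 of `.snp`), `9`
#' means missing; dosages returned are alt-allele counts (2 - geno).
#' VCF: GT field only (`./.` is missing); `MAF=`/`IS=` INFO tags, when
#' present, populate `maf` and `info_score`.  VCF parsing is delegated to the
#' VariantAnnotation package.
#'
#' @param path file path (VCF) or triplet prefix (EIGENSTRAT).
#' @param format `"eigenstrat"` or `"vcf"`.
#' @return a [genotype_table()].
#' @export
read_genotypes <- function(path, format = c("eigenstrat", "vcf")) {
  format <- match.arg(format)
  if (format == "eigenstrat") read_eigenstrat(path) else read_vcf_gt(path)
}

read_eigenstrat <- function(prefix) {
  geno_f <- paste0(prefix, ".geno")
  snp_f <- paste0(prefix, ".snp")
  ind_f <- paste0(prefix, ".ind")
  for (f in c(geno_f, snp_f, ind_f))
    if (!file.exists(f)) stop("missing EIGENSTRAT file: ", f)
  snp <- read.table(snp_f, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("id", "chrom", "genpos", "pos", "ref", "alt"))
  ind <- read.table(ind_f, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("id", "sex", "group"))
  lines <- readLines(geno_f)
  if (length(lines) != nrow(snp))
    stop("geno has ", length(lines), " rows but snp has ", nrow(snp))
  nc <- nchar(lines)
  bad <- which(nc != nrow(ind))
  if (length(bad))
    stop("malformed geno row(s) at line ", paste(head(bad, 5), collapse = ", "),
         ": expected ", nrow(ind), " characters")
  m <- matrix(utf8ToInt("0"), length(lines), nrow(ind))
  for (i in seq_along(lines)) m[i, ] <- utf8ToInt(lines[i])
  dig <- m - utf8ToInt("0")
  if (!all(dig %in% c(0L, 1L, 2L, 9L)))
    stop("geno characters must be 0/1/2/9 (line ",
         which(apply(!matrix(dig %in% c(0L, 1L, 2L, 9L), nrow(m)), 1, all))[1], ")")
  dos <- 2L - dig
  dos[dig == 9L] <- NA_integer_
  sites <- data.frame(id = snp$id, chrom = as.character(snp$chrom),
                      pos = snp$pos, ref = snp$ref, alt = snp$alt,
                      stringsAsFactors = FALSE)
  ploidy <- ifelse(apply(dos, 2, function(x) !any(x == 1L, na.rm = TRUE)) &
                     grepl("^PH:", ind$group), "pseudohaploid", "diploid")
  genotype_table(sites, ind$id, dos, ploidy = ploidy)
}

read_vcf_gt <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VCF reading requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- as.character(unlist(rr$ALT))
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean %in% c("0/0", "0")] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean %in% c("1/1", "1")] <- 2L
  info <- VariantAnnotation::info(vcf)
  sites <- data.frame(id = rownames(gt),
                      chrom = as.character(GenomicRanges::seqnames(rr)),
                      pos = GenomicRanges::start(rr),
                      ref = as.character(rr$REF), alt = alt,
                      stringsAsFactors = FALSE)
  if (!is.null(info$MAF)) sites$maf <- as.numeric(info$MAF)
  if (!is.null(info$IS)) sites$info_score <- as.numeric(info$IS)
  ploidy <- ifelse(apply(dos, 2, function(x) !any(x == 1L, na.rm = TRUE)) &
                     apply(nchar(gt), 2, function(x) all(x == 1L)),
                   "pseudohaploid", "diploid")
  genotype_table(sites, colnames(gt), dos, ploidy = ploidy)
}

#' Write genotypes to EIGENSTRAT triplet or minimal VCF
#'
#' The EIGENSTRAT triplet cannot carry `maf`/`info_score`; a round trip
#' through it recomputes `maf` from the dosages and leaves `info_score` NA.
#' The VCF route writes `MAF=`/`IS=` INFO tags and GT calls (haploid-style
#' single-allele GT for pseudo-haploid samples), and round-trips both fields.
#'
#' @param g a [genotype_table()].
#' @param path output path (VCF) or triplet prefix (EIGENSTRAT).
#' @param format `"eigenstrat"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("eigenstrat", "vcf")) {
  format <- match.arg(format)
  stopifnot(inherits(g, "genotype_table"))
  if (format == "eigenstrat") {
    dig <- 2L - g$dosages
    dig[is.na(dig)] <- 9L
    writeLines(apply(dig, 1, paste0, collapse = ""), paste0(path, ".geno"))
    snp <- data.frame(g$sites$id, g$sites$chrom, 0, g$sites$pos,
                      g$sites$ref, g$sites$alt)
    write.table(snp, paste0(path, ".snp"), quote = FALSE, sep = "\t",
                row.names = FALSE, col.names = FALSE)
    grp <- ifelse(g$ploidy == "pseudohaploid", "PH:Case", "Case")
    write.table(data.frame(g$samples, "U", grp), paste0(path, ".ind"),
                quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
                 "##INFO=<ID=IS,Number=1,Type=Float,Description=\"Imputation info score\">",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                         "INFO", "FORMAT", g$samples), collapse = "\t")), con)
    gt_str <- function(d, ph) {
      if (ph == "pseudohaploid")
        ifelse(is.na(d), ".", ifelse(d == 2L, "1", "0"))
      else
        ifelse(is.na(d), "./.", c("0/0", "0/1", "1/1")[d + 1L])
    }
    gts <- vapply(seq_along(g$samples),
                  function(j) gt_str(g$dosages[, j], g$ploidy[j]),
                  character(nrow(g$sites)))
    if (nrow(g$sites) == 1L) gts <- matrix(gts, nrow = 1L)
    info <- sprintf("MAF=%s;IS=%s",
                    ifelse(is.na(g$sites$maf), ".",
                           formatC(g$sites$maf, format = "g", digits = 8)),
                    ifelse(is.na(g$sites$info_score), ".",
                           formatC(g$sites$info_score, format = "g", digits = 8)))
    rows <- paste(g$sites$chrom, g$sites$pos, g$sites$id, g$sites$ref,
                  g$sites$alt, ".", "PASS", info, "GT",
                  apply(gts, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(rows, con)
  }
  invisible(path)
}
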