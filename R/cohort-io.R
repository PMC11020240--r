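#' Write a synthetic cohort to disk
#'
#' Emits a plain-text VCF 4.2 with GT and AD FORMAT fields, a phenotype and
#' covariate TSV (one sample per row, `NA` for missing), and truth tables.
#' The round trip through [read_cohort_vcf()] reproduces the in-memory
#' dosage matrix exactly.
#'
#' @param cohort a `synthetic_cohort` from [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf_path <- file.path(dir, "cohort.vcf")
  write_vcf(cohort$genotypes, vcf_path, read_counts = cohort$read_counts)
  paths <- c(vcf = vcf_path)
  if (!is.null(cohort$traits)) {
    ph_path <- file.path(dir, "phenotypes.tsv")
    utils::write.table(cohort$traits, ph_path,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    paths <- c(paths, phenotypes = ph_path)
  }
  truth_dir <- file.path(dir, "truth")
  dir.create(truth_dir, showWarnings = FALSE)
  af <- data.frame(
    id = cohort$genotypes$variant_meta$id,
    realized_af = cohort$truth$realized_af
  )
  utils::write.table(af, file.path(truth_dir, "allele_freq.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(cohort$truth$kinship, file.path(truth_dir, "kinship.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  writeLines(
    as.character(cohort$truth$biased_variants),
    file.path(truth_dir, "biased_variants.txt")
  )
  invisible(c(paths, truth = truth_dir))
}

#' Write a genotype matrix as VCF 4.2
#'
#' Minimal, standards-conforming writer: CHROM/POS/ID/REF/ALT plus GT
#' (unphased) and, when read counts are supplied, AD and DP per call.
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output `.vcf` path.
#' @param read_counts optional list with `ref_reads` and `alt_reads`
#'   matrices aligned to the dosage matrix.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(genotypes, path, read_counts = NULL) {
  meta <- genotypes$variant_meta
  dos <- genotypes$dosages
  gt_codes <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  has_ad <- !is.null(read_counts)
  if (has_ad) {
    header <- c(
      header,
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'
    )
  }
  header <- c(header, paste(
    c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
      genotypes$sample_ids),
    collapse = "\t"
  ))
  gt <- matrix(".", nrow(dos), ncol(dos))
  ok <- !is.na(dos)
  gt[ok] <- gt_codes[dos[ok] + 1L]
  gt[!ok] <- "./."
  if (has_ad) {
    ad <- matrix(".", nrow(dos), ncol(dos))
    got <- !is.na(read_counts$ref_reads)
    ad[got] <- paste0(
      read_counts$ref_reads[got], ",", read_counts$alt_reads[got]
    )
    dp <- matrix(".", nrow(dos), ncol(dos))
    dp[got] <- read_counts$ref_reads[got] + read_counts$alt_reads[got]
    cells <- matrix(paste(gt, ad, dp, sep = ":"), nrow(dos), ncol(dos))
    fmt <- "GT:AD:DP"
  } else {
    cells <- gt
    fmt <- "GT"
  }
  body <- paste(
    meta$chrom, meta$pos, meta$id, meta$ref, meta$alt, ".", "PASS", ".", fmt,
    apply(cells, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a cohort VCF back into a genotype matrix
#'
#' Parses GT and (when present) AD fields via the vcfR package.
#'
#' @param path a VCF file (plain text or gzipped).
#' @return list with `genotypes` (a [genotype_matrix()]) and, when the VCF
#'   carries AD, `read_counts` (list of `ref_reads`, `alt_reads`).
#' @export
read_cohort_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  meta <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    id = fix[, "ID"], stringsAsFactors = FALSE
  )
  gt <- vcfR::extract.gt(v, element = "GT") # variants x samples
  count_alt <- function(g) {
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0", "0|0")] <- 0L
    out[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    out[g %in% c("1/1", "1|1")] <- 2L
    out
  }
  dos <- t(matrix(count_alt(gt), nrow = nrow(gt))) # samples x variants
  dimnames(dos) <- list(colnames(gt), rownames(gt))
  gm <- genotype_matrix(dos, meta, sample_ids = colnames(gt))
  out <- list(genotypes = gm)
  if (any(grepl("AD", v@gt[, "FORMAT"]))) {
    ad <- vcfR::extract.gt(v, element = "AD")
    parts <- strsplit(as.vector(ad), ",", fixed = TRUE)
    pick <- function(i) {
      vapply(parts, function(p) {
        if (length(p) < 2) NA_integer_ else as.integer(p[i])
      }, integer(1))
    }
    ref <- t(matrix(pick(1L), nrow = nrow(ad)))
    alt <- t(matrix(pick(2L), nrow = nrow(ad)))
    dimnames(ref) <- dimnames(alt) <- dimnames(dos)
    out$read_counts <- list(ref_reads = ref, alt_reads = alt)
  }
  out
}
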