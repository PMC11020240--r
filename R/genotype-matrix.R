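#' Genotype matrix container
#'
#' A samples-by-variants dosage matrix (alternate-allele counts 0/1/2, `NA`
#' for missing calls) with per-variant metadata. This is the backbone object
#' every downstream stage (QC, profiling, association, phenomics) consumes.
#'
#' @param dosages integer or numeric matrix, samples in rows, variants in
#'   columns; values must be 0, 1, 2 or `NA`.
#' @param variant_meta data.frame with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt`, and optionally `id`; one row per variant.
#' @param sample_ids character vector of sample labels, one per row of
#'   `dosages`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `variant_meta`, `sample_ids`.
#' @examples
#' gm <- genotype_matrix(
#'   matrix(c(0L, 1L, 2L, 0L), nrow = 2),
#'   data.frame(chrom = "1", pos = c(100L, 200L), ref = "A", alt = "G"),
#'   c("s1", "s2")
#' )
#' n_variants(gm)
#' @export
genotype_matrix <- function(dosages, variant_meta, sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(sample_ids)) {
    sample_ids <- paste0("sample", seq_len(nrow(dosages)))
  }
  stopifnot(
    nrow(variant_meta) == ncol(dosages),
    length(sample_ids) == nrow(dosages),
    all(c("chrom", "pos", "ref", "alt") %in% names(variant_meta))
  )
  bad <- !(dosages %in% c(0, 1, 2)) & !is.na(dosages)
  if (any(bad)) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  if (any(variant_meta$pos < 1)) {
    stop("variant positions must be 1-based (>= 1)")
  }
  if (is.null(variant_meta$id)) {
    variant_meta$id <- variant_key(variant_meta)
  }
  if (anyDuplicated(variant_key(variant_meta))) {
    stop("duplicate (chrom, pos, ref, alt) variant keys")
  }
  storage.mode(dosages) <- "integer"
  dimnames(dosages) <- list(sample_ids, variant_meta$id)
  structure(
    list(dosages = dosages, variant_meta = variant_meta, sample_ids = sample_ids),
    class = "genotype_matrix"
  )
}

#' Canonical variant key
#'
#' @param variant_meta data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @return character vector `chrom:pos:ref:alt`.
#' @export
variant_key <- function(variant_meta) {
  paste(variant_meta$chrom, variant_meta$pos, variant_meta$ref, variant_meta$alt,
    sep = ":"
  )
}

#' @rdname genotype_matrix
#' @param x a `genotype_matrix`.
#' @export
n_samples <- function(x) nrow(x$dosages)

#' @rdname genotype_matrix
#' @export
n_variants <- function(x) ncol(x$dosages)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(
    "genotype_matrix:", n_samples(x), "samples x", n_variants(x), "variants;",
    sprintf("%.2f%% missing\n", 100 * mean(is.na(x$dosages)))
  )
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param samples sample index (logical, integer, or labels); default all.
#' @param variants variant index (logical, integer, or variant ids); default all.
#' @return a `genotype_matrix` restricted to the selection.
#' @export
subset_genotypes <- function(x, samples = NULL, variants = NULL) {
  if (is.null(samples)) samples <- seq_len(n_samples(x))
  if (is.null(variants)) variants <- seq_len(n_variants(x))
  if (is.character(samples)) samples <- match(samples, x$sample_ids)
  if (is.character(variants)) variants <- match(variants, x$variant_meta$id)
  d <- x$dosages[samples, variants, drop = FALSE]
  genotype_matrix(d, x$variant_meta[variants, , drop = FALSE],
    sample_ids = x$sample_ids[samples]
  )
}

#' Alternate-allele frequency per variant
#'
#' AF is the alternate-allele count divided by the number of non-missing
#' alleles (2 per genotyped sample).
#'
#' @param x a `genotype_matrix`.
#' @return numeric vector of alternate-allele frequencies (NaN when every
#'   call is missing).
#' @export
allele_freq <- function(x) {
  colMeans(x$dosages, na.rm = TRUE) / 2
}

#' Minor-allele frequency per variant
#'
#' @param x a `genotype_matrix`.
#' @return numeric vector in \[0, 0.5\].
#' @export
minor_allele_freq <- function(x) {
  af <- allele_freq(x)
  pmin(af, 1 - af)
}

#' Per-variant missing-call rate
#'
#' @param x a `genotype_matrix`.
#' @return numeric vector in \[0, 1\].
#' @export
variant_missing_rate <- function(x) {
  colMeans(is.na(x$dosages))
}
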