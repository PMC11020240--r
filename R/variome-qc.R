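#' Per-variant allele balance at heterozygous calls
#'
#' Allele balance (AB) at a call is the alternate read count divided by the
#' total read count at the locus. It is summarized at heterozygous calls
#' only, where both alleles are expected and AB should center on 0.5; the
#' genome-wide mean and SD over variants with a defined per-variant mean
#' drive the batch-effect filter.
#'
#' @param genotypes a [genotype_matrix()].
#' @param read_counts list with `ref_reads` and `alt_reads` matrices aligned
#'   to the dosages.
#' @return an `allele_balance_stats` list: `per_variant_mean_ab` (NA where a
#'   variant has no heterozygous call with reads), `n_het_per_variant`,
#'   `genomewide_mean`, `genomewide_sd`.
#' @export
compute_allele_balance <- function(genotypes, read_counts) {
  dos <- genotypes$dosages
  tot <- read_counts$ref_reads + read_counts$alt_reads
  het <- !is.na(dos) & dos == 1L & !is.na(tot) & tot > 0
  ab <- read_counts$alt_reads / tot
  ab[!het] <- NA_real_
  n_het <- colSums(het)
  mean_ab <- colMeans(ab, na.rm = TRUE)
  mean_ab[n_het == 0] <- NA_real_
  defined <- !is.na(mean_ab)
  structure(
    list(
      per_variant_mean_ab = mean_ab,
      n_het_per_variant = n_het,
      genomewide_mean = mean(mean_ab[defined]),
      genomewide_sd = stats::sd(mean_ab[defined])
    ),
    class = "allele_balance_stats"
  )
}

#' Allele-balance batch-effect filter
#'
#' Excludes variants whose mean heterozygous allele balance lies outside the
#' closed interval mean +/- 1 SD of the genome-wide allele-balance
#' distribution. Variants with an undefined mean (no heterozygous calls)
#' carry no allele-balance evidence and are kept.
#'
#' @param stats an `allele_balance_stats` object from
#'   [compute_allele_balance()].
#' @param n_sd width of the exclusion band in genome-wide SD units.
#' @return logical keep mask per variant (`TRUE` = kept).
#' @export
filter_batch_effect <- function(stats, n_sd = 1) {
  mu <- stats$genomewide_mean
  sdv <- stats$genomewide_sd
  m <- stats$per_variant_mean_ab
  if (!is.na(sdv) && sdv == 0) {
    warning("genome-wide allele-balance SD is 0; no variant excluded")
    return(rep(TRUE, length(m)))
  }
  keep <- is.na(m) | (m >= mu - n_sd * sdv & m <= mu + n_sd * sdv)
  keep
}

#' Per-sample QC: missingness and het/hom ratio
#'
#' Flags samples with missing genotype rate above `max_missing` and samples
#' whose heterozygous-to-(non-reference-)homozygous call ratio falls outside
#' the cohort mean +/- `het_hom_sd` SD. Samples with zero non-reference
#' homozygous calls have an undefined ratio and are flagged for review.
#'
#' @param genotypes a [genotype_matrix()].
#' @param max_missing missing-rate threshold (exclusive), default 0.10.
#' @param het_hom_sd SD band for the het/hom ratio, default 3.
#' @return data.frame (one row per sample): `sample_id`, `missing_rate`,
#'   `het_hom_ratio`, `high_missing`, `het_hom_outlier`, `ratio_undefined`,
#'   `kept`.
#' @export
sample_qc <- function(genotypes, max_missing = 0.10, het_hom_sd = 3) {
  dos <- genotypes$dosages
  stopifnot(nrow(dos) >= 2)
  miss <- rowMeans(is.na(dos))
  n_het <- rowSums(dos == 1L, na.rm = TRUE)
  n_hom <- rowSums(dos == 2L, na.rm = TRUE)
  ratio <- ifelse(n_hom > 0, n_het / n_hom, NA_real_)
  mu <- mean(ratio, na.rm = TRUE)
  sdv <- stats::sd(ratio, na.rm = TRUE)
  outlier <- if (is.na(sdv) || sdv == 0) {
    rep(FALSE, length(ratio))
  } else {
    !is.na(ratio) & abs(ratio - mu) > het_hom_sd * sdv
  }
  undefined <- is.na(ratio)
  high_missing <- miss > max_missing
  data.frame(
    sample_id = genotypes$sample_ids,
    missing_rate = miss,
    het_hom_ratio = ratio,
    high_missing = high_missing,
    het_hom_outlier = outlier,
    ratio_undefined = undefined,
    kept = !high_missing & !outlier & !undefined,
    stringsAsFactors = FALSE
  )
}

#' Variant QC report
#'
#' Per-variant genotyping rate, MAF, exact HWE P, and the allele-balance
#' exclusion flag; `kept` applies the genotyping-rate threshold (variants
#' with rate below `min_rate` dropped) and the allele-balance mask.
#'
#' @param genotypes a [genotype_matrix()].
#' @param ab_keep optional logical mask from [filter_batch_effect()].
#' @param min_rate minimum genotyping rate, default 0.9.
#' @return data.frame: `id`, `genotyping_rate`, `maf`, `hwe_p`,
#'   `ab_excluded`, `kept`.
#' @export
variant_qc <- function(genotypes, ab_keep = NULL, min_rate = 0.9) {
  dos <- genotypes$dosages
  rate <- 1 - colMeans(is.na(dos))
  maf <- minor_allele_freq(genotypes)
  n0 <- colSums(dos == 0L, na.rm = TRUE)
  n1 <- colSums(dos == 1L, na.rm = TRUE)
  n2 <- colSums(dos == 2L, na.rm = TRUE)
  hwe <- vapply(
    seq_along(n0), function(i) hwe_exact_test(n0[i], n1[i], n2[i]),
    numeric(1)
  )
  if (is.null(ab_keep)) ab_keep <- rep(TRUE, ncol(dos))
  data.frame(
    id = genotypes$variant_meta$id,
    genotyping_rate = rate,
    maf = maf,
    hwe_p = hwe,
    ab_excluded = !ab_keep,
    kept = rate >= min_rate & ab_keep,
    stringsAsFactors = FALSE
  )
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on genotype counts: conditioning on the observed
#' allele counts, sums the probabilities of all heterozygote counts whose
#' hypergeometric-form probability does not exceed the observed one (no
#' mid-p correction). Monomorphic variants return P = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return exact P in (0, 1\].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("no genotyped samples")
  n_a <- n_Aa + 2L * n_aa # minor-ish allele count (use rarer allele)
  n_A <- n_Aa + 2L * n_AA
  rare <- min(n_a, n_A)
  if (rare == 0) return(1)
  # possible heterozygote counts share the parity of the rare allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # log probability up to a constant: P(n_Aa = h | allele counts)
  #   = C * 2^h / (h! * ((rare-h)/2)! * ((2n-rare-h)/2)!)
  logp <- hets * log(2) - lfactorial(hets) -
    lfactorial((rare - hets) / 2) - lfactorial((2 * n - rare - hets) / 2)
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  obs <- which(hets == n_Aa)
  if (!length(obs)) stop("observed heterozygote count inconsistent with allele counts")
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Method-of-moments IBD estimation (PLINK-style)
#'
#' For each sample pair, compares the observed identity-by-state (IBS)
#' distribution over variants with its expectation under IBD states 0/1/2
#' given cohort allele frequencies, solves for the IBD-state proportions,
#' truncates them to \[0, 1\], renormalizes, and reports
#' PI_HAT = P(IBD=1)/2 + P(IBD=2). Use common, LD-pruned variants.
#'
#' @param genotypes a [genotype_matrix()].
#' @param af optional per-variant alternate-allele frequencies; estimated
#'   from the cohort when `NULL`.
#' @param pairs optional 2-column matrix of sample indices to evaluate;
#'   default all pairs.
#' @param min_variants refuse estimation below this many usable variants.
#' @return data.frame: `sample_i`, `sample_j`, `ibd0`, `ibd1`, `ibd2`,
#'   `pi_hat`, `n_variants`.
#' @export
estimate_ibd <- function(genotypes, af = NULL, pairs = NULL, min_variants = 100) {
  dos <- genotypes$dosages
  external_af <- !is.null(af)
  if (!external_af) af <- allele_freq(genotypes)
  # variants informative for IBS expectations: polymorphic, defined AF
  use <- !is.na(af) & af > 0 & af < 1
  if (sum(use) < min_variants) {
    stop("fewer than ", min_variants, " usable variants for IBD estimation")
  }
  dos <- dos[, use, drop = FALSE]
  p <- af[use]
  q <- 1 - p
  if (external_af) {
    # reference frequencies: infinite-population expectations
    e_ibs0_ibd0 <- 2 * p^2 * q^2
    e_ibs2_ibd0 <- p^4 + q^4 + 4 * p^2 * q^2
    e_ibs2_ibd1 <- p^3 + q^3 + p^2 * q + p * q^2
  } else {
    # cohort-estimated frequencies: unbiased without-replacement
    # expectations from the observed allele pool (finite-sample correction;
    # uncorrected formulas bias PI_HAT upward in small cohorts)
    nA <- colSums(dos, na.rm = TRUE)
    t_all <- 2 * colSums(!is.na(dos))
    nB <- t_all - nA
    d4 <- t_all * (t_all - 1) * (t_all - 2) * (t_all - 3)
    d3 <- t_all * (t_all - 1) * (t_all - 2)
    e_ibs0_ibd0 <- 2 * nA * (nA - 1) * nB * (nB - 1) / d4
    e_ibs2_ibd0 <- (nA * (nA - 1) * (nA - 2) * (nA - 3) +
      nB * (nB - 1) * (nB - 2) * (nB - 3) +
      4 * nA * (nA - 1) * nB * (nB - 1)) / d4
    e_ibs2_ibd1 <- (nA * (nA - 1) * (nA - 2) + nB * (nB - 1) * (nB - 2) +
      nA * nB * (nB - 1) + nB * nA * (nA - 1)) / d3
  }
  e_ibs1_ibd0 <- 1 - e_ibs0_ibd0 - e_ibs2_ibd0
  e_ibs1_ibd1 <- 1 - e_ibs2_ibd1
  n <- nrow(dos)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(n, 2))
  }
  out <- matrix(NA_real_, nrow(pairs), 5)
  for (r in seq_len(nrow(pairs))) {
    gi <- dos[pairs[r, 1], ]
    gj <- dos[pairs[r, 2], ]
    ok <- !is.na(gi) & !is.na(gj)
    d <- abs(gi[ok] - gj[ok])
    m <- sum(ok)
    obs0 <- sum(d == 2)
    obs1 <- sum(d == 1)
    obs2 <- sum(d == 0)
    E0_0 <- sum(e_ibs0_ibd0[ok])
    E1_0 <- sum(e_ibs1_ibd0[ok])
    E2_0 <- sum(e_ibs2_ibd0[ok])
    E1_1 <- sum(e_ibs1_ibd1[ok])
    E2_1 <- sum(e_ibs2_ibd1[ok])
    p0 <- obs0 / E0_0
    p1 <- (obs1 - p0 * E1_0) / E1_1
    p2 <- (obs2 - p0 * E2_0 - p1 * E2_1) / m
    ibd <- pmin(pmax(c(p0, p1, p2), 0), 1)
    ibd <- ibd / sum(ibd)
    out[r, ] <- c(ibd, ibd[2] / 2 + ibd[3], m)
  }
  data.frame(
    sample_i = genotypes$sample_ids[pairs[, 1]],
    sample_j = genotypes$sample_ids[pairs[, 2]],
    ibd0 = out[, 1], ibd1 = out[, 2], ibd2 = out[, 3],
    pi_hat = out[, 4], n_variants = out[, 5],
    stringsAsFactors = FALSE
  )
}

#' Select a maximal unrelated sample set
#'
#' Greedy removal: while any pair exceeds the PI_HAT threshold, drop the
#' sample participating in the most such pairs (ties broken by sample label
#' order), then return the kept set.
#'
#' @param pairs data.frame from [estimate_ibd()] (needs `sample_i`,
#'   `sample_j`, `pi_hat`).
#' @param sample_ids all sample labels under consideration.
#' @param threshold PI_HAT above which a pair counts as related,
#'   default 0.05.
#' @return character vector of kept sample ids (original order).
#' @export
select_unrelated <- function(pairs, sample_ids, threshold = 0.05) {
  rel <- pairs[pairs$pi_hat > threshold, c("sample_i", "sample_j")]
  kept <- sample_ids
  while (nrow(rel) > 0) {
    counts <- table(c(rel$sample_i, rel$sample_j))
    top <- max(counts)
    drop <- sort(names(counts)[counts == top])[1]
    kept <- setdiff(kept, drop)
    rel <- rel[rel$sample_i != drop & rel$sample_j != drop, , drop = FALSE]
  }
  kept
}

#' Sliding-window LD pruning
#'
#' PLINK-style `--indep`-like pruning on squared dosage correlation: within
#' each window of `window` variants, repeatedly remove one variant of any
#' pair with r-squared above `r2` (the later variant of the pair is
#' removed), then advance by `step` variants. Missing dosages are
#' mean-imputed for the correlation only.
#'
#' @param genotypes a [genotype_matrix()].
#' @param window window size in variants, default 200.
#' @param step window shift in variants, default 4.
#' @param r2 squared-correlation threshold, default 0.1.
#' @return integer vector of kept variant indices.
#' @export
ld_prune <- function(genotypes, window = 200, step = 4, r2 = 0.1) {
  dos <- impute_mean(genotypes$dosages)
  M <- ncol(dos)
  keep <- rep(TRUE, M)
  start <- 1L
  repeat {
    end <- min(start + window - 1L, M)
    idx <- which(keep[start:end]) + start - 1L
    if (length(idx) > 1) {
      cc <- suppressWarnings(stats::cor(dos[, idx, drop = FALSE]))
      cc[is.na(cc)] <- 0
      for (a in seq_along(idx)) {
        if (!keep[idx[a]]) next
        for (b in seq_along(idx)) {
          if (b <= a || !keep[idx[b]]) next
          if (cc[a, b]^2 > r2) keep[idx[b]] <- FALSE
        }
      }
    }
    if (end == M) break
    start <- start + step
  }
  which(keep)
}

# mean-impute missing dosages (PCA / LD use only, never association)
impute_mean <- function(dos) {
  mu <- colMeans(dos, na.rm = TRUE)
  idx <- which(is.na(dos), arr.ind = TRUE)
  if (nrow(idx)) dos[idx] <- mu[idx[, 2]]
  dos[is.na(dos)] <- 0 # all-missing columns
  dos
}

#' Principal component analysis of standardized genotypes
#'
#' Eigen-decomposition of the covariance of standardized (mean 0, unit
#' variance) dosages, with mean imputation of missing calls before
#' standardization. Scores are reproducible up to sign.
#'
#' @param genotypes a [genotype_matrix()] (apply MAF/missingness/LD filters
#'   first).
#' @param n_components number of components to return.
#' @return list with `scores` (samples x components), `eigenvalues`, and
#'   `explained` (fraction of total variance per component).
#' @export
pca_genotypes <- function(genotypes, n_components = 10) {
  dos <- impute_mean(genotypes$dosages)
  n <- nrow(dos)
  if (n_components > n - 1) stop("more components than samples - 1")
  Z <- scale(dos)
  Z[, attr(Z, "scaled:scale") == 0 | is.na(attr(Z, "scaled:scale"))] <- 0
  Z[is.na(Z)] <- 0
  G <- tcrossprod(Z) / ncol(Z)
  ev <- eigen(G, symmetric = TRUE)
  scores <- ev$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(pmax(ev$values[seq_len(n_components)], 0)), n_components)
  rownames(scores) <- genotypes$sample_ids
  colnames(scores) <- paste0("PC", seq_len(n_components))
  list(
    scores = scores,
    eigenvalues = ev$values[seq_len(n_components)],
    explained = pmax(ev$values, 0)[seq_len(n_components)] / sum(pmax(ev$values, 0))
  )
}

#' Flag PCA outliers relative to a target-population centroid
#'
#' Samples farther than `k` robust SDs from the target centroid on the
#' first two components are flagged (e.g., non-target genetic background
#' after joint projection with reference populations).
#'
#' @param scores PCA score matrix (needs PC1, PC2).
#' @param target logical or index vector: which rows define the target
#'   population; default all.
#' @param k SD multiplier, default 6.
#' @return logical outlier flag per row of `scores`.
#' @export
pca_outliers <- function(scores, target = NULL, k = 6) {
  s <- scores[, 1:2, drop = FALSE]
  if (is.null(target)) target <- seq_len(nrow(s))
  ctr <- colMeans(s[target, , drop = FALSE])
  sds <- apply(s[target, , drop = FALSE], 2, stats::sd)
  sds[sds == 0] <- Inf
  abs(s[, 1] - ctr[1]) > k * sds[1] | abs(s[, 2] - ctr[2]) > k * sds[2]
}
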