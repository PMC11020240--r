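test_that("allele balance is the mean alternate-read fraction at het calls", {
  gm <- toy_genotypes(matrix(c(1L, 1L, 0L, 2L), nrow = 2))
  rc <- list(
    ref_reads = matrix(c(3L, 5L, 10L, 0L), nrow = 2),
    alt_reads = matrix(c(7L, 5L, 0L, 10L), nrow = 2)
  )
  ab <- compute_allele_balance(gm, rc)
  # het calls (3,7) and (5,5): mean of {0.7, 0.5} = 0.6
  expect_equal(ab$per_variant_mean_ab[1], 0.6)
  # no het call at variant 2: undefined, not silently 0
  expect_true(is.na(ab$per_variant_mean_ab[2]))
  # equal ref/alt reads everywhere -> 0.5
  rc2 <- list(
    ref_reads = matrix(5L, 2, 2), alt_reads = matrix(5L, 2, 2)
  )
  ab2 <- compute_allele_balance(toy_genotypes(matrix(1L, 2, 2)), rc2)
  expect_equal(unname(ab2$per_variant_mean_ab), c(0.5, 0.5))
})

test_that("batch-effect filter excludes outside the closed 1-SD band", {
  st <- structure(
    list(
      per_variant_mean_ab = c(0.45, 0.47, 0.5, 0.53, 0.56, NA),
      genomewide_mean = 0.5, genomewide_sd = 0.03,
      n_het_per_variant = c(10, 10, 10, 10, 10, 0)
    ),
    class = "allele_balance_stats"
  )
  keep <- filter_batch_effect(st)
  # 0.45 and 0.56 are outside; the boundary values 0.47 and 0.53 are kept
  expect_identical(keep, c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE))
  st$genomewide_sd <- 0
  expect_warning(keep0 <- filter_batch_effect(st), "SD")
  expect_true(all(keep0))
})

test_that("unbiased synthetic cohort centers allele balance on 0.5 and the
           filter recovers injected batch-biased variants", {
  cfg <- cohort_config(
    n_samples = 500, n_variants = 3000, batch_biased_fraction = 0.05,
    bias_ab = 0.65, mean_depth = 30, seed = 71
  )
  g <- simulate_genotypes(cfg)
  rc <- simulate_read_counts(g$genotypes, cfg, batch = g$truth$batch)
  ab <- compute_allele_balance(g$genotypes, rc)
  unb <- setdiff(seq_len(3000), rc$biased_variants)
  expect_lt(abs(mean(ab$per_variant_mean_ab[unb], na.rm = TRUE) - 0.5), 0.01)
  keep <- filter_batch_effect(ab)
  recall <- mean(!keep[rc$biased_variants])
  expect_gte(recall, 0.90)
  # order invariance of the exclusion set
  perm_s <- sample.int(n_samples(g$genotypes))
  perm_v <- sample.int(n_variants(g$genotypes))
  g2 <- subset_genotypes(g$genotypes, samples = perm_s, variants = perm_v)
  rc2 <- list(
    ref_reads = rc$ref_reads[perm_s, perm_v],
    alt_reads = rc$alt_reads[perm_s, perm_v]
  )
  keep2 <- filter_batch_effect(compute_allele_balance(g2, rc2))
  expect_identical(unname(keep2), unname(keep[perm_v]))
})

test_that("sample QC flags high missingness and het/hom outliers", {
  set.seed(1)
  n <- 200
  m <- 400
  dos <- matrix(rbinom(n * m, 2, 0.3), n, m)
  # sample 1: 11% missing
  dos[1, seq_len(ceiling(0.11 * m))] <- NA
  # sample 2: strongly inflated het rate (but with some hom calls so the
  # ratio stays defined)
  dos[2, ] <- sample(c(0L, 1L, 2L), m, replace = TRUE, prob = c(0.1, 0.85, 0.05))
  gm <- toy_genotypes(dos)
  qc <- sample_qc(gm)
  expect_true(qc$high_missing[1])
  expect_true(qc$het_hom_outlier[2])
  expect_false(any(qc$high_missing[-1]))
  expect_true(qc$kept[3])
  # identical samples: SD = 0 handled as no outlier flag
  gm2 <- toy_genotypes(matrix(rep(c(0L, 1L, 2L, 1L), each = 4), 4, 4))
  qc2 <- sample_qc(gm2)
  expect_false(any(qc2$het_hom_outlier))
})

test_that("HWE exact test matches the enumeration oracle and edge cases", {
  # maximally HWE-consistent table
  expect_gte(hwe_exact_test(25, 50, 25), 0.5)
  # monomorphic
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  # full agreement with enumeration on every table with total <= 50
  worst <- 0
  for (n in c(5, 10, 17, 25, 50)) {
    for (nAA in 0:n) {
      for (nAa in 0:(n - nAA)) {
        naa <- n - nAA - nAa
        diff <- abs(hwe_exact_test(nAA, nAa, naa) - hwe_oracle(nAA, nAa, naa))
        worst <- max(worst, diff)
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("IBD estimation separates duplicates, relatives, and unrelated", {
  cfg <- cohort_config(
    n_samples = 120, n_variants = 5000, fst = 0, missing_rate = 0,
    related_pairs = c("parent-offspring" = 10), seed = 31
  )
  g <- simulate_genotypes(cfg)
  kin <- g$truth$kinship
  po_pairs <- cbind(
    match(kin$sample_i, g$genotypes$sample_ids),
    match(kin$sample_j, g$genotypes$sample_ids)
  )
  unrel_pairs <- t(utils::combn(seq(21, 60), 2))
  ibd <- estimate_ibd(g$genotypes, pairs = rbind(po_pairs, unrel_pairs))
  po <- ibd$pi_hat[seq_len(nrow(po_pairs))]
  un <- ibd$pi_hat[-seq_len(nrow(po_pairs))]
  expect_gte(mean(po >= 0.45 & po <= 0.55), 0.95)
  # unrelated pairs sit far below the parent-offspring band
  expect_lt(stats::median(un), 0.03)
  expect_gte(mean(un < 0.1), 0.95)
  # duplicate sample
  g2 <- g$genotypes
  g2$dosages[2, ] <- g2$dosages[1, ]
  dup <- estimate_ibd(g2, pairs = cbind(1, 2))
  expect_gte(dup$pi_hat, 0.95)
  # IBD proportions are a normalized distribution
  expect_true(all(abs(ibd$ibd0 + ibd$ibd1 + ibd$ibd2 - 1) < 1e-9))
  expect_error(
    estimate_ibd(subset_genotypes(g$genotypes, variants = 1:50)),
    "usable variants"
  )
})

test_that("unrelated selection is greedy, deterministic, and complete", {
  ids <- c("a", "b", "c", "d", "e")
  # no related pair: all kept
  none <- data.frame(sample_i = "a", sample_j = "b", pi_hat = 0.01)
  expect_identical(select_unrelated(none, ids), ids)
  # one parent-offspring pair: exactly one removed (tie-break: drop "a")
  one <- data.frame(sample_i = "a", sample_j = "b", pi_hat = 0.5)
  expect_identical(select_unrelated(one, ids), c("b", "c", "d", "e"))
  # star family: parent p related to 3 offspring, offspring mutually related
  fam <- data.frame(
    sample_i = c("p", "p", "p", "o1", "o1", "o2"),
    sample_j = c("o1", "o2", "o3", "o2", "o3", "o3"),
    pi_hat = c(0.5, 0.5, 0.5, 0.25, 0.25, 0.25)
  )
  all_ids <- c("p", "o1", "o2", "o3", "x")
  kept <- select_unrelated(fam, all_ids)
  # brute force: smallest removal set leaving no related pair
  best <- NULL
  for (k in 0:4) {
    for (rm in utils::combn(c("p", "o1", "o2", "o3"), k, simplify = FALSE)) {
      left <- fam[!(fam$sample_i %in% rm) & !(fam$sample_j %in% rm), ]
      if (nrow(left) == 0) {
        best <- rm
        break
      }
    }
    if (!is.null(best)) break
  }
  # greedy removal is minimum-size on this instance (vertex cover of K4)
  expect_identical(length(setdiff(all_ids, kept)), length(best))
  # returned set never contains a residual related pair
  resid <- fam[fam$sample_i %in% kept & fam$sample_j %in% kept, ]
  expect_identical(nrow(resid), 0L)
})

test_that("LD pruning removes duplicates, keeps independents, matches a
           brute-force check on a toy r2 structure", {
  set.seed(5)
  n <- 1000
  base <- rbinom(n, 2, 0.4)
  # toy: v1, v2 correlated r2 ~ 0.5 with v1, v3 nearly independent
  v2 <- ifelse(runif(n) < 0.75, base, rbinom(n, 2, 0.4))
  v3 <- rbinom(n, 2, 0.4)
  gm <- toy_genotypes(cbind(base, v2, v3))
  cc <- cor(cbind(base, v2, v3))^2
  kept <- ld_prune(gm, window = 10, step = 2, r2 = 0.1)
  # oracle: scan pairs in order, drop the later variant of any pair > 0.1
  keep_oracle <- rep(TRUE, 3)
  for (a in 1:2) {
    for (b in (a + 1):3) {
      if (keep_oracle[a] && keep_oracle[b] && cc[a, b] > 0.1) {
        keep_oracle[b] <- FALSE
      }
    }
  }
  expect_identical(kept, which(keep_oracle))
  # duplicated column: exactly one survives
  gm2 <- toy_genotypes(cbind(base, base))
  expect_identical(ld_prune(gm2), 1L)
  # independent variants: none removed (false-removal < 5%)
  indep <- matrix(rbinom(n * 40, 2, 0.4), n, 40)
  gm3 <- toy_genotypes(indep)
  expect_gte(length(ld_prune(gm3)), 38)
})

test_that("PCA separates subpopulations and gives orthogonal scores", {
  cfg <- cohort_config(
    n_samples = 300, n_variants = 2000, n_subpops = 2, fst = 0.1,
    missing_rate = 0, seed = 41
  )
  g <- simulate_genotypes(cfg)
  pc <- pca_genotypes(g$genotypes, n_components = 5)
  sp <- g$truth$subpop
  side <- pc$scores[, 1] > 0
  acc <- max(mean(side == (sp == 1)), mean(side == (sp == 2)))
  expect_gte(acc, 0.99)
  expect_lt(abs(cor(pc$scores[, 1], pc$scores[, 2])), 1e-8)
  # homogeneous population: no component splits random halves well
  cfg0 <- cohort_config(
    n_samples = 200, n_variants = 1000, fst = 0, missing_rate = 0, seed = 42
  )
  g0 <- simulate_genotypes(cfg0)
  pc0 <- pca_genotypes(g0$genotypes, n_components = 2)
  set.seed(1)
  half <- sample(c(TRUE, FALSE), 200, replace = TRUE)
  side0 <- pc0$scores[, 1] > median(pc0$scores[, 1])
  acc0 <- max(mean(side0 == half), mean(side0 == !half))
  expect_lt(acc0, 0.6)
  expect_error(pca_genotypes(g0$genotypes, n_components = 500), "components")
})

test_that("variant QC applies genotyping-rate and allele-balance masks", {
  set.seed(2)
  dos <- matrix(rbinom(300, 2, 0.4), 30, 10)
  dos[1:4, 1] <- NA # variant 1: 13% missing -> rate < 0.9
  gm <- toy_genotypes(dos)
  ab_keep <- rep(TRUE, 10)
  ab_keep[2] <- FALSE
  vq <- variant_qc(gm, ab_keep = ab_keep, min_rate = 0.9)
  expect_false(vq$kept[1])
  expect_false(vq$kept[2])
  expect_true(vq$ab_excluded[2])
  expect_true(all(vq$kept[3:10]))
})
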