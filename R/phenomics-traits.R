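#' Filter a clinical trait table
#'
#' Keeps the most recent record per sample when multiple time points exist,
#' then drops quantitative traits missing from more than `max_missing_frac`
#' of participants and binary traits whose minority class is rarer than 1:4.
#'
#' @param traits data.frame with `sample_id`, optionally a `date` column,
#'   and trait columns.
#' @param trait_cols trait columns to screen; default every column other
#'   than `sample_id`, `date`, and the standard covariates.
#' @param max_missing_frac maximum missing fraction, default 0.90.
#' @param max_imbalance maximum minority:majority ratio for binary traits,
#'   default 1/4.
#' @return data.frame restricted to one row per sample and the kept traits
#'   (covariate and id columns retained).
#' @export
filter_traits <- function(traits, trait_cols = NULL, max_missing_frac = 0.90,
                          max_imbalance = 1 / 4) {
  meta_cols <- c("sample_id", "date", "sex", "age", "age2", "bmi")
  if (is.null(trait_cols)) trait_cols <- setdiff(names(traits), meta_cols)
  if ("date" %in% names(traits)) {
    ord <- order(traits$sample_id, traits$date, decreasing = TRUE)
    traits <- traits[ord, , drop = FALSE]
    traits <- traits[!duplicated(traits$sample_id), , drop = FALSE]
    traits <- traits[order(traits$sample_id), , drop = FALSE]
  }
  kept <- screen_traits(traits,
    trait_cols = trait_cols,
    min_obs_frac = 1 - max_missing_frac, max_imbalance = max_imbalance
  )
  traits[, c(intersect(meta_cols, names(traits)), kept), drop = FALSE]
}

#' Pairwise phenotypic correlation with Fisher-z intervals and BH FDR
#'
#' Pairwise-complete Pearson correlation for every trait pair, 95%
#' confidence intervals by the Fisher z-transform, BH FDR across all pairs.
#' A pair is `significant` iff its FDR is below `fdr_threshold` and the CI
#' excludes zero. Pairs with fewer than `min_pairs` complete observations,
#' or a constant trait, are reported as NA.
#'
#' @param traits data.frame of quantitative traits (columns = traits).
#' @param trait_cols which columns to correlate; default all numeric.
#' @param min_pairs minimum complete observations per pair, default 10.
#' @param fdr_threshold default 0.05.
#' @return data.frame: `trait_i`, `trait_j`, `n`, `r`, `ci_lo`, `ci_hi`,
#'   `p`, `fdr`, `significant`.
#' @export
phenotypic_correlation <- function(traits, trait_cols = NULL, min_pairs = 10,
                                   fdr_threshold = 0.05) {
  if (is.null(trait_cols)) {
    trait_cols <- names(traits)[vapply(traits, is.numeric, logical(1))]
    trait_cols <- setdiff(trait_cols, c("sex", "age", "age2", "bmi"))
  }
  K <- length(trait_cols)
  rows <- list()
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      x <- traits[[trait_cols[i]]]
      y <- traits[[trait_cols[j]]]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      if (n < min_pairs || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          trait_i = trait_cols[i], trait_j = trait_cols[j], n = n,
          r = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_
        )
        next
      }
      r <- stats::cor(x[ok], y[ok])
      z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
      se_z <- 1 / sqrt(n - 3)
      ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se_z)
      p <- 2 * stats::pnorm(abs(z) / se_z, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        trait_i = trait_cols[i], trait_j = trait_cols[j], n = n,
        r = r, ci_lo = ci[1], ci_hi = ci[2], p = p
      )
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out$significant <- !is.na(out$fdr) & out$fdr < fdr_threshold &
    (out$ci_lo > 0 | out$ci_hi < 0)
  out
}

#' Variant-Sharing Index of two suggestive-variant sets
#'
#' The VSI of traits i and j is the Jaccard index of their suggestive
#' association variant sets on the percentage scale:
#' 100 * |intersection| / |union|, with union = s_i + s_j - shared, rounded
#' to one decimal.
#'
#' @param s_i,s_j sizes of the suggestive-variant sets of the two traits.
#' @param shared size of their intersection (must not exceed min(s_i, s_j)).
#' @return list: `s_i`, `s_j`, `shared`, `total` (union size), `vsi`.
#' @export
compute_vsi <- function(s_i, s_j, shared) {
  stopifnot(shared <= min(s_i, s_j), s_i >= 0, s_j >= 0, shared >= 0)
  total <- s_i + s_j - shared
  if (total == 0) stop("both variant sets empty: VSI undefined")
  list(
    s_i = s_i, s_j = s_j, shared = shared, total = total,
    vsi = round(100 * shared / total, 1)
  )
}

#' Detect pleiotropic variants and score trait-pair sharing
#'
#' A variant is pleiotropic when its association P is below `p_threshold`
#' for at least two traits. Every trait pair with a non-empty intersection
#' of suggestive sets receives a VSI record.
#'
#' @param stats_by_trait named list of `summary_stats` data.frames from
#'   [run_gwas()].
#' @param p_threshold suggestive threshold, default 1e-5.
#' @return list with `pleiotropic` (variant ids suggestive for >= 2
#'   traits), `suggestive_sets` (per-trait id vectors), and `vsi`
#'   (data.frame: trait_i, trait_j, s_i, s_j, shared, total, vsi).
#' @export
detect_pleiotropy <- function(stats_by_trait, p_threshold = 1e-5) {
  stopifnot(length(stats_by_trait) >= 2)
  sets <- lapply(stats_by_trait, function(s) s$id[!is.na(s$p) & s$p < p_threshold])
  counts <- table(unlist(sets))
  pleio <- names(counts)[counts >= 2]
  tn <- names(stats_by_trait)
  rows <- list()
  for (i in seq_len(length(tn) - 1)) {
    for (j in (i + 1):length(tn)) {
      shared <- length(intersect(sets[[i]], sets[[j]]))
      if (shared == 0) next
      v <- compute_vsi(length(sets[[i]]), length(sets[[j]]), shared)
      rows[[length(rows) + 1L]] <- data.frame(
        trait_i = tn[i], trait_j = tn[j],
        s_i = v$s_i, s_j = v$s_j, shared = v$shared,
        total = v$total, vsi = v$vsi, stringsAsFactors = FALSE
      )
    }
  }
  vsi <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trait_i = character(0), trait_j = character(0),
      s_i = integer(0), s_j = integer(0), shared = integer(0),
      total = integer(0), vsi = numeric(0))
  list(pleiotropic = pleio, suggestive_sets = sets, vsi = vsi)
}
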