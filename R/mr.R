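#' Select MR instruments from exposure association results
#'
#' Takes variants with suggestive exposure association (P < `p_threshold`)
#' and keeps one per LD block: clumping at the given r-squared and window,
#' retaining the smallest-P variant of each block.
#'
#' @param exposure_stats `summary_stats` for the exposure trait.
#' @param genotypes a [genotype_matrix()] sharing variant keys.
#' @param p_threshold suggestive threshold, default 1e-5.
#' @param r2 clumping r-squared, default 0.1.
#' @param window_kb clumping window, default 250.
#' @return character vector of instrument variant ids (may be empty).
#' @export
select_instruments <- function(exposure_stats, genotypes, p_threshold = 1e-5,
                               r2 = 0.1, window_kb = 250) {
  sugg <- exposure_stats[!is.na(exposure_stats$p) &
    exposure_stats$p < p_threshold, , drop = FALSE]
  if (nrow(sugg) == 0) return(character(0))
  cl <- ld_clump(sugg, genotypes, r2 = r2, window_kb = window_kb)
  cl$index
}

#' Inverse-variance-weighted MR estimate
#'
#' Weighted least-squares slope of outcome effects on exposure effects
#' through the origin, weights 1 / se_y^2. With a single instrument this
#' reduces to the Wald ratio beta_y / beta_x.
#'
#' @param beta_x,se_x instrument effects (and SEs) on the exposure.
#' @param beta_y,se_y instrument effects (and SEs) on the outcome.
#' @return list: `estimate`, `se`, `p`, `n_instruments`, `method`.
#' @export
mr_ivw <- function(beta_x, se_x, beta_y, se_y) {
  stopifnot(length(beta_x) >= 1)
  if (all(beta_x == 0)) stop("all exposure effects are zero: IVW undefined")
  w <- 1 / se_y^2
  est <- sum(w * beta_x * beta_y) / sum(w * beta_x^2)
  if (length(beta_x) == 1) {
    se <- abs(se_y / beta_x)
  } else {
    # multiplicative random-effects: residual scale floored at 1
    resid <- beta_y - est * beta_x
    sigma2 <- max(1, sum(w * resid^2) / (length(beta_x) - 1))
    se <- sqrt(sigma2 / sum(w * beta_x^2))
  }
  z <- est / se
  list(
    estimate = est, se = se,
    p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
    n_instruments = length(beta_x), method = "ivw"
  )
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with an
#' intercept; exposure effects are sign-oriented positive first (the
#' estimate is invariant, the intercept testable). The slope is the causal
#' estimate; the intercept tests directional pleiotropy. Requires >= 3
#' instruments.
#'
#' @inheritParams mr_ivw
#' @return list: `estimate`, `se`, `p`, `intercept`, `intercept_se`,
#'   `intercept_p`, `n_instruments`, `method`.
#' @export
mr_egger <- function(beta_x, se_x, beta_y, se_y) {
  k <- length(beta_x)
  if (k < 3) stop("MR-Egger requires at least 3 instruments")
  flip <- sign(beta_x)
  flip[flip == 0] <- 1
  bx <- beta_x * flip
  by <- beta_y * flip
  w <- 1 / se_y^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  # scale residual variance as in random-effects Egger (floored at 1)
  phi <- max(1, sm$sigma^2)
  co <- sm$coefficients
  se_slope <- co["bx", "Std. Error"] / sm$sigma * sqrt(phi)
  se_int <- co["(Intercept)", "Std. Error"] / sm$sigma * sqrt(phi)
  t_slope <- co["bx", "Estimate"] / se_slope
  t_int <- co["(Intercept)", "Estimate"] / se_int
  dfres <- k - 2
  list(
    estimate = co["bx", "Estimate"], se = se_slope,
    p = 2 * stats::pt(abs(t_slope), dfres, lower.tail = FALSE),
    intercept = co["(Intercept)", "Estimate"], intercept_se = se_int,
    intercept_p = 2 * stats::pt(abs(t_int), dfres, lower.tail = FALSE),
    n_instruments = k, method = "egger"
  )
}

#' MR-PRESSO global test and outlier removal
#'
#' Parametric-resampling residual-sum-of-squares test: the observed RSS of
#' the leave-one-out IVW fit is compared against `nb_distribution`
#' simulations of instrument effects drawn from the fitted model and the
#' reported SEs. Instruments whose observed squared residual is extreme
#' relative to its simulated distribution (Bonferroni-adjusted) are
#' removed and IVW re-run.
#'
#' @inheritParams mr_ivw
#' @param nb_distribution number of parametric resamples, default 10000.
#' @param signif significance threshold for the global and outlier tests,
#'   default 0.05.
#' @param seed random seed for the resampling.
#' @return list: `global_p`, `outliers` (indices), `estimate`, `se`, `p`
#'   (IVW after outlier removal), `n_instruments` (after removal),
#'   `method`.
#' @export
mr_presso <- function(beta_x, se_x, beta_y, se_y, nb_distribution = 10000,
                      signif = 0.05, seed = 1) {
  k <- length(beta_x)
  if (k < 4) stop("MR-PRESSO requires at least 4 instruments")
  set.seed(seed)
  w <- 1 / se_y^2
  # leave-one-out IVW slopes, vectorized: drop instrument i from the sums
  loo_all <- function(bx, by) {
    sxy <- sum(w * bx * by)
    sxx <- sum(w * bx^2)
    (sxy - w * bx * by) / (sxx - w * bx^2)
  }
  slope_loo <- loo_all(beta_x, beta_y)
  obs_res2 <- (beta_y - slope_loo * beta_x)^2
  rss_obs <- sum(w * obs_res2)
  # parametric null: redraw effects about the leave-one-out fitted values
  BX <- matrix(stats::rnorm(nb_distribution * k, rep(beta_x, each = nb_distribution),
    rep(se_x, each = nb_distribution)), nb_distribution, k)
  BY <- matrix(stats::rnorm(nb_distribution * k,
    rep(slope_loo * beta_x, each = nb_distribution),
    rep(se_y, each = nb_distribution)), nb_distribution, k)
  W <- matrix(w, nb_distribution, k, byrow = TRUE)
  sxy <- rowSums(W * BX * BY)
  sxx <- rowSums(W * BX^2)
  slope_sim <- (sxy - W * BX * BY) / (sxx - W * BX^2)
  sim_res2 <- (BY - slope_sim * BX)^2
  rss_sim <- rowSums(W * sim_res2)
  global_p <- (sum(rss_sim >= rss_obs) + 1) / (nb_distribution + 1)
  outliers <- integer(0)
  if (global_p < signif) {
    out_p <- vapply(seq_len(k), function(i) {
      (sum(sim_res2[, i] >= obs_res2[i]) + 1) / (nb_distribution + 1)
    }, numeric(1))
    outliers <- which(out_p * k < signif) # Bonferroni
  }
  keep <- setdiff(seq_len(k), outliers)
  if (length(keep) < 2) {
    return(list(
      global_p = global_p, outliers = outliers,
      estimate = NA_real_, se = NA_real_, p = NA_real_,
      n_instruments = length(keep), method = "presso",
      skipped = "too few instruments after outlier removal"
    ))
  }
  ivw <- mr_ivw(beta_x[keep], se_x[keep], beta_y[keep], se_y[keep])
  list(
    global_p = global_p, outliers = outliers,
    estimate = ivw$estimate, se = ivw$se, p = ivw$p,
    n_instruments = length(keep), method = "presso"
  )
}

#' Run all three MR estimators for one exposure-outcome pair
#'
#' Joins exposure and outcome summary statistics on the instrument set and
#' applies IVW, MR-Egger, and MR-PRESSO. Pairs with fewer than 3
#' instruments skip Egger; fewer than 4 skip PRESSO.
#'
#' @param exposure_stats,outcome_stats `summary_stats` data.frames.
#' @param instruments instrument variant ids from [select_instruments()].
#' @param nb_distribution,signif,seed passed to [mr_presso()].
#' @return a `mr_result` list with `exposure`, `outcome`, `n_instruments`,
#'   and per-method results (`ivw`, `egger`, `presso`; NULL when skipped
#'   with `skip_reason`).
#' @export
mr_pair <- function(exposure_stats, outcome_stats, instruments,
                    nb_distribution = 10000, signif = 0.05, seed = 1) {
  ex <- exposure_stats[match(instruments, exposure_stats$id), , drop = FALSE]
  ou <- outcome_stats[match(instruments, outcome_stats$id), , drop = FALSE]
  ok <- !is.na(ex$beta) & !is.na(ou$beta)
  ex <- ex[ok, , drop = FALSE]
  ou <- ou[ok, , drop = FALSE]
  k <- nrow(ex)
  res <- list(
    exposure = attr(exposure_stats, "trait"),
    outcome = attr(outcome_stats, "trait"),
    n_instruments = k, instruments = ex$id,
    ivw = NULL, egger = NULL, presso = NULL, skip_reason = NULL
  )
  if (k < 1) {
    res$skip_reason <- "no usable instruments"
    class(res) <- "mr_result"
    return(res)
  }
  res$ivw <- mr_ivw(ex$beta, ex$se, ou$beta, ou$se)
  if (k >= 3) res$egger <- mr_egger(ex$beta, ex$se, ou$beta, ou$se)
  if (k >= 4) {
    res$presso <- mr_presso(ex$beta, ex$se, ou$beta, ou$se,
      nb_distribution = nb_distribution, signif = signif, seed = seed
    )
  }
  class(res) <- "mr_result"
  res
}

#' @export
print.mr_result <- function(x, ...) {
  cat("MR", x$exposure, "->", x$outcome, "with", x$n_instruments,
      "instruments\n")
  for (m in c("ivw", "egger", "presso")) {
    r <- x[[m]]
    if (!is.null(r)) {
      cat(sprintf("  %-7s estimate %.4f (SE %.4f), P = %.3g\n",
        m, r$estimate, r$se, r$p))
    }
  }
  invisible(x)
}

#' Consensus across MR methods with per-method FDR
#'
#' Applies BH FDR within each method across all tested exposure-outcome
#' pairs; a pair is consensus-significant when at least 2 of the 3 methods
#' reach FDR below `fdr_threshold`. Directionality labels compare the two
#' orientations of each unordered trait pair: unidirectional when exactly
#' one orientation is consensus-significant, bidirectional when both are.
#'
#' @param results list of `mr_result` objects (both orientations of pairs
#'   may be present).
#' @param fdr_threshold default 0.05.
#' @return data.frame: `exposure`, `outcome`, per-method estimate/p/fdr,
#'   `n_significant_methods`, `consensus_significant`, `direction`.
#' @export
consensus_mr <- function(results, fdr_threshold = 0.05) {
  grab <- function(r, m, f) {
    v <- r[[m]][[f]]
    if (is.null(v)) NA_real_ else v
  }
  df <- data.frame(
    exposure = vapply(results, function(r) r$exposure, character(1)),
    outcome = vapply(results, function(r) r$outcome, character(1)),
    n_instruments = vapply(results, function(r) r$n_instruments, numeric(1)),
    ivw_estimate = vapply(results, grab, numeric(1), m = "ivw", f = "estimate"),
    ivw_p = vapply(results, grab, numeric(1), m = "ivw", f = "p"),
    egger_estimate = vapply(results, grab, numeric(1), m = "egger", f = "estimate"),
    egger_p = vapply(results, grab, numeric(1), m = "egger", f = "p"),
    presso_estimate = vapply(results, grab, numeric(1), m = "presso", f = "estimate"),
    presso_p = vapply(results, grab, numeric(1), m = "presso", f = "p"),
    stringsAsFactors = FALSE
  )
  for (m in c("ivw", "egger", "presso")) {
    df[[paste0(m, "_fdr")]] <- bh_fdr(df[[paste0(m, "_p")]])
  }
  sig <- cbind(
    df$ivw_fdr < fdr_threshold,
    df$egger_fdr < fdr_threshold,
    df$presso_fdr < fdr_threshold
  )
  sig[is.na(sig)] <- FALSE
  df$n_significant_methods <- rowSums(sig)
  df$consensus_significant <- df$n_significant_methods >= 2
  # directionality: compare the two orientations of each unordered pair
  keypair <- apply(cbind(df$exposure, df$outcome), 1, function(r) {
    paste(sort(r), collapse = "|")
  })
  df$direction <- NA_character_
  for (kp in unique(keypair)) {
    idx <- which(keypair == kp)
    n_sig <- sum(df$consensus_significant[idx])
    lab <- if (n_sig == 0) {
      "none"
    } else if (n_sig == length(idx) && length(idx) > 1) {
      "bidirectional"
    } else {
      "unidirectional"
    }
    df$direction[idx] <- lab
  }
  df
}
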