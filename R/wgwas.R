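#' Association-analysis variant prefilter
#'
#' Keeps variants with MAF >= `maf_min`, exact HWE P >= `hwe_min`, and
#' missing genotype rate <= `max_missing`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param maf_min minor-allele-frequency floor, default 0.01.
#' @param hwe_min HWE exact-test P floor, default 1e-6.
#' @param max_missing missing-rate ceiling, default 0.01.
#' @return logical keep mask per variant.
#' @export
prefilter_variants <- function(genotypes, maf_min = 0.01, hwe_min = 1e-6,
                               max_missing = 0.01) {
  maf <- minor_allele_freq(genotypes)
  miss <- variant_missing_rate(genotypes)
  dos <- genotypes$dosages
  n0 <- colSums(dos == 0L, na.rm = TRUE)
  n1 <- colSums(dos == 1L, na.rm = TRUE)
  n2 <- colSums(dos == 2L, na.rm = TRUE)
  hwe <- vapply(seq_along(n0), function(i) hwe_exact_test(n0[i], n1[i], n2[i]),
    numeric(1))
  unname(!is.na(maf) & maf >= maf_min & hwe >= hwe_min & miss <= max_missing)
}

#' Covariate specification for association models
#'
#' @param columns covariate column names in the trait table (e.g. sex, age,
#'   age2, bmi) plus any principal-component columns.
#' @param bmi_excluded_traits traits for which `bmi` is dropped from the
#'   covariates (a trait derived from BMI must never be adjusted for BMI).
#' @return a `covariate_spec` list.
#' @export
covariate_spec <- function(columns = c("sex", "age", "age2", "bmi"),
                           bmi_excluded_traits = c("bmi", "degree_of_obesity")) {
  structure(list(columns = columns, bmi_excluded_traits = bmi_excluded_traits),
    class = "covariate_spec"
  )
}

# resolve the covariate matrix for a trait, honoring the BMI exclusion rule
covariate_matrix <- function(traits, trait_name, spec) {
  cols <- spec$columns
  if (tolower(trait_name) %in% tolower(spec$bmi_excluded_traits)) {
    cols <- setdiff(cols, "bmi")
  }
  missing_cols <- setdiff(cols, names(traits))
  if (length(missing_cols)) {
    stop("missing covariate columns: ", paste(missing_cols, collapse = ", "))
  }
  X <- as.matrix(traits[, cols, drop = FALSE])
  storage.mode(X) <- "double"
  X
}

#' Per-variant association scan (additive model)
#'
#' Linear (least squares) or logistic (IRLS maximum likelihood) regression
#' of a trait on alternate-allele dosage plus covariates. Samples missing
#' the trait or any covariate are dropped trait-wide; samples missing a
#' genotype are dropped per variant (complete-case, never imputed). P is
#' two-sided from the dosage coefficient's t (linear) or Wald z (logistic).
#'
#' @param genotypes a [genotype_matrix()] (prefiltered, see
#'   [prefilter_variants()]).
#' @param traits data.frame with `sample_id`, the trait, and covariates.
#' @param trait name of the trait column.
#' @param covariates a [covariate_spec()], or NULL for no adjustment.
#' @param model `"linear"` or `"logistic"`.
#' @return a `summary_stats` data.frame: `id`, `beta`, `se`, `stat`, `p`,
#'   `n`; attributes `trait` and `model`. Monomorphic variants in the
#'   analyzed subsample give an NA row.
#' @export
run_gwas <- function(genotypes, traits, trait, covariates = covariate_spec(),
                     model = c("linear", "logistic")) {
  model <- match.arg(model)
  stopifnot(trait %in% names(traits))
  m <- match(genotypes$sample_ids, traits$sample_id)
  if (anyNA(m)) stop("trait table is missing samples present in the genotypes")
  traits <- traits[m, , drop = FALSE]
  y_all <- traits[[trait]]
  X_cov <- if (is.null(covariates)) {
    matrix(numeric(0), nrow(traits), 0)
  } else {
    covariate_matrix(traits, trait, covariates)
  }
  use <- !is.na(y_all) & stats::complete.cases(X_cov)
  if (sum(use) < ncol(X_cov) + 10) {
    stop("fewer than covariates + 10 samples with complete trait data")
  }
  y <- y_all[use]
  X_cov <- X_cov[use, , drop = FALSE]
  if (ncol(X_cov)) {
    CX <- cbind(`(Intercept)` = 1, X_cov)
    qrX <- qr(CX)
    if (qrX$rank < ncol(CX)) {
      bad <- colnames(CX)[qrX$pivot[(qrX$rank + 1):ncol(CX)]]
      stop("collinear covariates: ", paste(bad, collapse = ", "))
    }
  }
  dos <- genotypes$dosages[use, , drop = FALSE]
  M <- ncol(dos)
  out <- matrix(NA_real_, M, 5)
  colnames(out) <- c("beta", "se", "stat", "p", "n")

  if (model == "linear") {
    # fast path via Frisch-Waugh: residualize y and complete-dosage columns
    C <- cbind(`(Intercept)` = 1, X_cov)
    Q <- qr.Q(qr(C))
    y_res <- y - Q %*% crossprod(Q, y)
    complete <- !colAnyNA(dos)
    if (any(complete)) {
      D <- dos[, complete, drop = FALSE]
      D_res <- D - Q %*% crossprod(Q, D)
      dd <- colSums(D_res^2)
      dfres <- length(y) - ncol(C) - 1
      ok <- dd > 1e-12
      beta <- ifelse(ok, as.vector(crossprod(D_res, y_res)) / dd, NA_real_)
      fitted <- sweep(D_res, 2, ifelse(ok, beta, 0), "*")
      rss <- colSums((matrix(y_res, nrow(D_res), ncol(D_res)) - fitted)^2)
      se <- ifelse(ok, sqrt(rss / dfres / dd), NA_real_)
      stat <- beta / se
      p <- 2 * stats::pt(abs(stat), dfres, lower.tail = FALSE)
      out[complete, ] <- cbind(beta, se, stat, p, length(y))
    }
    for (j in which(!complete)) {
      g <- dos[, j]
      okr <- !is.na(g)
      if (sum(okr) < ncol(C) + 2 || stats::var(g[okr]) == 0) {
        out[j, "n"] <- sum(okr)
        next
      }
      Xf <- cbind(g = g[okr], C[okr, , drop = FALSE])
      fit <- stats::lm.fit(Xf, y[okr])
      dfres <- sum(okr) - fit$rank
      cov_unscaled <- chol2inv(qr.R(fit$qr))
      pos <- which(fit$qr$pivot == 1L) # position of the dosage column
      s2 <- sum(fit$residuals^2) / dfres
      se <- sqrt(s2 * cov_unscaled[pos, pos])
      stat <- fit$coefficients["g"] / se
      out[j, ] <- c(
        fit$coefficients["g"], se, stat,
        2 * stats::pt(abs(stat), dfres, lower.tail = FALSE), sum(okr)
      )
    }
  } else {
    if (!all(y %in% c(0, 1))) stop("logistic model requires a 0/1 trait")
    C <- cbind(`(Intercept)` = 1, X_cov)
    for (j in seq_len(M)) {
      g <- dos[, j]
      okr <- !is.na(g)
      if (sum(okr) < ncol(C) + 2 || stats::var(g[okr]) == 0) {
        out[j, "n"] <- sum(okr)
        next
      }
      Xf <- cbind(g = g[okr], C[okr, , drop = FALSE])
      fit <- suppressWarnings(stats::glm.fit(Xf, y[okr],
        family = stats::binomial(),
        control = list(maxit = 25)
      ))
      if (!fit$converged || any(abs(fit$coefficients) > 15)) {
        # separation or non-convergence: no stable Wald statistic
        out[j, "n"] <- sum(okr)
        next
      }
      cov_b <- chol2inv(qr.R(fit$qr))
      pos <- which(fit$qr$pivot == 1L)
      se <- sqrt(cov_b[pos, pos])
      z <- fit$coefficients["g"] / se
      out[j, ] <- c(
        fit$coefficients["g"], se, z,
        2 * stats::pnorm(abs(z), lower.tail = FALSE), sum(okr)
      )
    }
  }
  res <- data.frame(id = genotypes$variant_meta$id, out,
    stringsAsFactors = FALSE
  )
  attr(res, "trait") <- trait
  attr(res, "model") <- model
  class(res) <- c("summary_stats", "data.frame")
  res
}

colAnyNA <- function(m) colSums(is.na(m)) > 0

#' Genomic inflation factor (lambda from the median test statistic)
#'
#' Converts two-sided P values to 1-df chi-square quantiles and divides the
#' median by 0.4549364, the null median of the chi-square(1) distribution.
#'
#' @param stats a `summary_stats` data.frame from [run_gwas()], or a
#'   numeric vector of P values.
#' @return list with `lambda_median` and `n_tests`.
#' @export
genomic_lambda <- function(stats) {
  p <- if (is.data.frame(stats)) stats$p else stats
  p <- p[!is.na(p)]
  chi2 <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  list(
    lambda_median = stats::median(chi2) / 0.4549364,
    n_tests = length(p)
  )
}

#' Greedy LD clumping of association results
#'
#' PLINK-style index-first clumping: variants sorted by ascending P; the
#' best remaining variant becomes a clump index and absorbs every
#' unassigned variant on the same chromosome within `window_kb` whose
#' squared dosage correlation with the index exceeds `r2`. P-value gates
#' `p1` (index) and `p2` (members) default to 1 so every variant is
#' assigned to exactly one clump.
#'
#' @param stats a `summary_stats` data.frame (needs `id`, `p`).
#' @param genotypes a [genotype_matrix()] sharing variant keys.
#' @param r2 squared-correlation threshold, default 0.1.
#' @param window_kb window half-width in kb around the index, default 250.
#' @param p1 maximum index P, default 1.
#' @param p2 maximum member P, default 1.
#' @return data.frame: `index` (variant id), `members`
#'   (comma-separated ids including the index), `n_members`, `index_p`.
#' @export
ld_clump <- function(stats, genotypes, r2 = 0.1, window_kb = 250, p1 = 1, p2 = 1) {
  key <- genotypes$variant_meta$id
  m <- match(stats$id, key)
  if (anyNA(m)) stop("stats contain variants absent from the genotypes")
  p <- stats$p
  chrom <- genotypes$variant_meta$chrom[m]
  pos <- genotypes$variant_meta$pos[m]
  dos <- impute_mean(genotypes$dosages)[, m, drop = FALSE]
  ordv <- order(p, stats$id) # deterministic tie-break by variant id
  assigned <- rep(FALSE, length(p))
  assigned[is.na(p)] <- TRUE
  clumps <- list()
  for (i in ordv) {
    if (assigned[i] || is.na(p[i]) || p[i] > p1) next
    cand <- which(!assigned & chrom == chrom[i] &
      abs(pos - pos[i]) <= window_kb * 1000 & p <= p2)
    cand <- setdiff(cand, i)
    members <- i
    if (length(cand)) {
      cc <- suppressWarnings(
        stats::cor(dos[, i], dos[, cand, drop = FALSE])
      )
      cc[is.na(cc)] <- 0
      members <- c(i, cand[cc^2 > r2])
    }
    assigned[members] <- TRUE
    clumps[[length(clumps) + 1L]] <- data.frame(
      index = stats$id[i],
      members = paste(stats$id[members], collapse = ","),
      n_members = length(members),
      index_p = p[i],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, clumps)
}

#' Benjamini-Hochberg q-values
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")` so every stage shares
#' one FDR entry point.
#'
#' @param p numeric vector of P values in (0, 1\].
#' @return q-values, same length as `p`.
#' @export
bh_fdr <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Trait pre-screen for association analysis
#'
#' Drops traits observed in fewer than `min_obs_frac` of samples and binary
#' traits whose minority class is rarer than `max_imbalance` (1:4 by
#' default, i.e. minority < 20%).
#'
#' @param traits trait data.frame (`sample_id` plus trait columns).
#' @param trait_cols which columns to screen; default all non-covariate
#'   columns.
#' @param min_obs_frac minimum fraction of non-missing values, default 0.10.
#' @param max_imbalance maximum minority:majority imbalance for binary
#'   traits, default 1/4.
#' @return character vector of kept trait names.
#' @export
screen_traits <- function(traits,
                          trait_cols = setdiff(
                            names(traits),
                            c("sample_id", "sex", "age", "age2", "bmi")
                          ),
                          min_obs_frac = 0.10, max_imbalance = 1 / 4) {
  keep <- character(0)
  for (tc in trait_cols) {
    v <- traits[[tc]]
    obs <- mean(!is.na(v))
    if (obs < min_obs_frac) next
    vv <- v[!is.na(v)]
    if (all(vv %in% c(0, 1))) {
      tab <- table(factor(vv, levels = c(0, 1)))
      if (min(tab) / max(tab) < max_imbalance) next
    }
    keep <- c(keep, tc)
  }
  keep
}
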