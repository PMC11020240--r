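#' Genetic relationship matrix (GCTA-style)
#'
#' A_jk = (1/M) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))
#' over autosomal variants with MAF >= `maf_min`. Missing dosages are
#' skipped per variant and the per-pair M is adjusted to the number of
#' variants observed in both samples. Monomorphic variants are excluded.
#'
#' @param genotypes a [genotype_matrix()].
#' @param maf_min minor-allele-frequency floor, default 0.01.
#' @return a `grm` list: `A` (samples x samples), `M` (variants used),
#'   `af` (frequencies of the variants used), `sample_ids`.
#' @export
build_grm <- function(genotypes, maf_min = 0.01) {
  af <- allele_freq(genotypes)
  use <- !is.na(af) & af > 0 & af < 1 & pmin(af, 1 - af) >= maf_min
  X <- genotypes$dosages[, use, drop = FALSE]
  p <- af[use]
  W <- sweep(X, 2, 2 * p, "-")
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  obs <- !is.na(W)
  W[!obs] <- 0
  Np <- tcrossprod(obs * 1) # per-pair count of jointly observed variants
  A <- tcrossprod(W) / pmax(Np, 1)
  dimnames(A) <- list(genotypes$sample_ids, genotypes$sample_ids)
  structure(
    list(A = A, M = sum(use), af = p, sample_ids = genotypes$sample_ids),
    class = "grm"
  )
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", nrow(x$A), "samples,", x$M, "variants; mean diagonal",
      sprintf("%.3f\n", mean(diag(x$A))))
  invisible(x)
}

# residualize y against covariates X (with intercept) and return pieces
design_matrix <- function(n, covariates = NULL) {
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    X <- cbind(X, covariates)
  }
  X
}

# REML log-likelihood of the univariate two-component model after rotating
# by the GRM eigenvectors; d = eigenvalues, yt/Xt = rotated data
reml_loglik_uni <- function(sg, se, d, yt, Xt) {
  v <- sg * d + se
  if (any(v <= 0)) return(-Inf)
  w <- 1 / v
  T <- crossprod(Xt, Xt * w)
  u <- crossprod(Xt, yt * w)
  Tc <- tryCatch(chol(T), error = function(e) NULL)
  if (is.null(Tc)) return(-Inf)
  quad <- sum(yt^2 * w) - sum(backsolve(Tc, u, transpose = TRUE)^2)
  -0.5 * (sum(log(v)) + 2 * sum(log(diag(Tc))) + quad)
}

#' REML heritability from a GRM (GREML)
#'
#' Restricted maximum likelihood fit of y = Xb + g + e with
#' g ~ N(0, A sigma_g^2), e ~ N(0, I sigma_e^2), on the eigendecomposition
#' of the GRM (so each likelihood evaluation is O(n)). Variance components
#' are constrained nonnegative by box bounds; the h2 standard error comes
#' from the inverse observed information with a delta-method transform, and
#' is flagged when a component sits at the boundary.
#'
#' @param grm a `grm` from [build_grm()] (or a plain symmetric matrix).
#' @param trait numeric trait vector aligned to the GRM samples (NA
#'   dropped, with the GRM subset accordingly).
#' @param covariates optional numeric matrix of covariates.
#' @param eig optional precomputed `eigen()` of the (complete-case) GRM to
#'   reuse across traits.
#' @param max_iter optimizer iteration cap, default 200.
#' @param tol relative log-likelihood convergence tolerance, default 1e-8.
#' @return a `heritability_estimate` list: `h2`, `se`, `ci95`,
#'   `significant` (CI lower bound > 0), `sigma_g2`, `sigma_e2`,
#'   `loglik`, `converged`, `boundary`, `n`.
#' @export
reml_h2 <- function(grm, trait, covariates = NULL, eig = NULL,
                    max_iter = 200, tol = 1e-8) {
  A <- if (inherits(grm, "grm")) grm$A else as.matrix(grm)
  ok <- !is.na(trait)
  if (!is.null(covariates)) ok <- ok & stats::complete.cases(covariates)
  y <- trait[ok]
  n <- length(y)
  X <- design_matrix(n, if (is.null(covariates)) NULL else
    as.matrix(covariates)[ok, , drop = FALSE])
  if (is.null(eig)) {
    eig <- eigen(A[ok, ok], symmetric = TRUE)
  }
  d <- pmax(eig$values, 0)
  yt <- as.vector(crossprod(eig$vectors, y))
  Xt <- crossprod(eig$vectors, X)
  vy <- stats::var(y)
  fn <- function(par) -reml_loglik_uni(par[1], par[2], d, yt, Xt)
  start <- c(vy / 2, vy / 2)
  lower <- c(0, vy * 1e-8)
  opt <- stats::optim(start, fn,
    method = "L-BFGS-B", lower = lower, upper = c(vy * 10, vy * 10),
    control = list(maxit = max_iter, factr = tol / .Machine$double.eps)
  )
  sg <- opt$par[1]
  se_comp <- opt$par[2]
  h2 <- sg / (sg + se_comp)
  boundary <- sg <= lower[1] + 1e-12 || se_comp <= lower[2] * (1 + 1e-8)
  H <- tryCatch(stats::optimHess(opt$par, fn), error = function(e) NULL)
  se_h2 <- NA_real_
  if (!is.null(H)) {
    Vc <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vc)) {
      gr <- c(se_comp, -sg) / (sg + se_comp)^2
      v <- drop(t(gr) %*% Vc %*% gr)
      if (is.finite(v) && v >= 0) se_h2 <- sqrt(v)
    }
  }
  ci <- pmin(pmax(h2 + c(-1, 1) * 1.96 * se_h2, 0), 1)
  structure(
    list(
      h2 = h2, se = se_h2, ci95 = ci,
      significant = !is.na(ci[1]) && ci[1] > 0,
      sigma_g2 = sg, sigma_e2 = se_comp,
      loglik = -opt$value, converged = opt$convergence == 0,
      boundary = boundary, n = n
    ),
    class = "heritability_estimate"
  )
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf(
    "GREML h2 = %.3f (SE %.3f, 95%% CI %.3f-%.3f), n = %d%s\n",
    x$h2, x$se, x$ci95[1], x$ci95[2], x$n,
    if (x$boundary) " [boundary]" else ""
  ))
  invisible(x)
}

# bivariate REML log-likelihood; th = (sg1, sg2, rg, se1, se2, re)
reml_loglik_biv <- function(th, d, y1t, y2t, Xt) {
  sg1 <- th[1]; sg2 <- th[2]; rg <- th[3]
  se1 <- th[4]; se2 <- th[5]; re <- th[6]
  sg12 <- rg * sqrt(sg1 * sg2)
  se12 <- re * sqrt(se1 * se2)
  a <- sg1 * d + se1
  b <- sg2 * d + se2
  cc <- sg12 * d + se12
  det <- a * b - cc^2
  if (any(det <= 0) || any(a <= 0) || any(b <= 0)) return(-Inf)
  w11 <- b / det; w22 <- a / det; w12 <- -cc / det
  quad <- sum(w11 * y1t^2 + 2 * w12 * y1t * y2t + w22 * y2t^2)
  T11 <- crossprod(Xt, Xt * w11)
  T22 <- crossprod(Xt, Xt * w22)
  T12 <- crossprod(Xt, Xt * w12)
  T <- rbind(cbind(T11, T12), cbind(T12, T22))
  u <- c(
    crossprod(Xt, w11 * y1t + w12 * y2t),
    crossprod(Xt, w12 * y1t + w22 * y2t)
  )
  Tc <- tryCatch(chol(T), error = function(e) NULL)
  if (is.null(Tc)) return(-Inf)
  quad <- quad - sum(backsolve(Tc, u, transpose = TRUE)^2)
  -0.5 * (sum(log(det)) + 2 * sum(log(diag(Tc))) + quad)
}

#' Bivariate GREML genetic correlation
#'
#' REML fit of the bivariate two-component model with genetic covariance
#' sigma_g12; rG = sigma_g12 / sqrt(sigma_g1^2 sigma_g2^2). Tested against
#' rG = 0 by a likelihood-ratio test (1 df). Non-convergence is reported
#' explicitly, never as a silent NA.
#'
#' @param grm a `grm` or symmetric matrix.
#' @param trait1,trait2 numeric trait vectors aligned to the GRM samples;
#'   only samples complete for both traits (and covariates) are used.
#' @param covariates optional numeric covariate matrix.
#' @param eig optional precomputed eigendecomposition of the complete-case
#'   GRM.
#' @return a `genetic_correlation` list: `rg`, `p_lrt`, per-trait variance
#'   components, `loglik`, `converged`, `excluded` (TRUE with `reason`
#'   when the fit failed), `n`.
#' @export
bivariate_rg <- function(grm, trait1, trait2, covariates = NULL, eig = NULL) {
  A <- if (inherits(grm, "grm")) grm$A else as.matrix(grm)
  ok <- !is.na(trait1) & !is.na(trait2)
  if (!is.null(covariates)) ok <- ok & stats::complete.cases(covariates)
  y1 <- trait1[ok]; y2 <- trait2[ok]
  n <- length(y1)
  X <- design_matrix(n, if (is.null(covariates)) NULL else
    as.matrix(covariates)[ok, , drop = FALSE])
  if (is.null(eig)) eig <- eigen(A[ok, ok], symmetric = TRUE)
  d <- pmax(eig$values, 0)
  y1t <- as.vector(crossprod(eig$vectors, y1))
  y2t <- as.vector(crossprod(eig$vectors, y2))
  Xt <- crossprod(eig$vectors, X)
  v1 <- stats::var(y1); v2 <- stats::var(y2)
  r0 <- stats::cor(y1, y2)
  fn <- function(th) -reml_loglik_biv(th, d, y1t, y2t, Xt)
  start <- c(v1 / 2, v2 / 2, r0 * 0.5, v1 / 2, v2 / 2, r0 * 0.5)
  lower <- c(v1 * 1e-6, v2 * 1e-6, -0.999, v1 * 1e-6, v2 * 1e-6, -0.999)
  upper <- c(v1 * 10, v2 * 10, 0.999, v1 * 10, v2 * 10, 0.999)
  opt <- tryCatch(
    stats::optim(start, fn, method = "L-BFGS-B", lower = lower, upper = upper,
      control = list(maxit = 400)),
    error = function(e) NULL
  )
  if (is.null(opt) || !is.finite(opt$value)) {
    return(structure(
      list(rg = NA_real_, p_lrt = NA_real_, excluded = TRUE,
           reason = "log-likelihood did not converge", n = n),
      class = "genetic_correlation"
    ))
  }
  # null fit: genetic covariance fixed at zero
  fn0 <- function(th5) fn(c(th5[1], th5[2], 0, th5[3], th5[4], th5[5]))
  opt0 <- stats::optim(start[-3], fn0, method = "L-BFGS-B",
    lower = lower[-3], upper = upper[-3], control = list(maxit = 400))
  lrt <- max(0, 2 * (opt0$value - opt$value))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  th <- opt$par
  structure(
    list(
      rg = max(-1, min(1, th[3])),
      p_lrt = p, lrt = lrt,
      sigma_g1 = th[1], sigma_g2 = th[2],
      sigma_e1 = th[4], sigma_e2 = th[5], re = th[6],
      h2_1 = th[1] / (th[1] + th[4]), h2_2 = th[2] / (th[2] + th[5]),
      loglik = -opt$value, converged = opt$convergence == 0,
      excluded = FALSE, reason = NA_character_, n = n
    ),
    class = "genetic_correlation"
  )
}

#' @export
print.genetic_correlation <- function(x, ...) {
  if (x$excluded) {
    cat("bivariate GREML: excluded (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("bivariate GREML rG = %.3f (LRT P = %.3g), n = %d\n",
      x$rg, x$p_lrt, x$n))
  }
  invisible(x)
}

#' Analytic GREML detection power
#'
#' Power to declare h2 > 0 given the sampling variance of a GREML estimate:
#' SE(h2) = sqrt(2 / (n^2 var_A)) where var_A is the variance of the GRM
#' off-diagonal elements (about 2e-5 for a homogeneous unrelated cohort);
#' power = Phi(h2 / SE - z_{1 - alpha/2}).
#'
#' @param n sample size.
#' @param h2 assumed heritability in (0, 1\].
#' @param var_a variance of GRM off-diagonals, default 2e-5.
#' @param alpha two-sided significance level, default 0.05.
#' @return power in (0, 1).
#' @export
greml_power <- function(n, h2, var_a = 2e-5, alpha = 0.05) {
  stopifnot(n > 0, h2 >= 0, h2 <= 1, var_a > 0, alpha > 0, alpha < 1)
  se <- sqrt(2 / (n^2 * var_a))
  stats::pnorm(h2 / se - stats::qnorm(1 - alpha / 2))
}
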