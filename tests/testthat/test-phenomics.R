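# the 14 published trait-pair sharing records used as a worked fixture:
# (set sizes, intersection) -> (union, VSI%)
vsi_reference <- data.frame(
  s_i    = c(638, 294, 348, 221, 74, 177, 153, 542, 202, 123, 173, 163, 294, 627),
  s_j    = c(632, 230, 398, 264, 238, 100, 221, 125, 466, 100, 123, 230, 163, 294),
  shared = c(569, 147, 191, 74, 38, 31, 35, 23, 15, 5, 2, 1, 1, 1),
  total  = c(701, 377, 555, 411, 274, 246, 339, 644, 653, 218, 294, 392, 456, 920),
  vsi    = c(81.2, 39.0, 34.4, 18.0, 13.9, 12.6, 10.3, 3.6, 2.3, 2.3, 0.7, 0.3, 0.2, 0.1)
)

test_that("VSI reproduces every reference trait-pair row exactly", {
  for (r in seq_len(nrow(vsi_reference))) {
    v <- compute_vsi(vsi_reference$s_i[r], vsi_reference$s_j[r],
      vsi_reference$shared[r])
    expect_identical(v$total, vsi_reference$total[r])
    expect_identical(v$vsi, vsi_reference$vsi[r])
  }
  # identical sets share everything
  expect_equal(compute_vsi(5, 5, 5)$vsi, 100)
  expect_error(compute_vsi(0, 0, 0), "undefined")
  expect_error(compute_vsi(3, 5, 4), "shared")
})

test_that("pleiotropy detection builds suggestive sets and VSI records", {
  mk_stats <- function(trait, ids, p) {
    s <- data.frame(id = ids, beta = 0.1, se = 0.02, stat = 5, p = p, n = 100)
    attr(s, "trait") <- trait
    class(s) <- c("summary_stats", "data.frame")
    s
  }
  ids <- paste0("v", 1:10)
  pa <- rep(1, 10); pa[1:4] <- 1e-7   # trait A suggestive: v1-v4
  pb <- rep(1, 10); pb[3:6] <- 1e-7   # trait B suggestive: v3-v6
  pc_ <- rep(1, 10); pc_[8] <- 1e-7   # trait C suggestive: v8 (disjoint)
  res <- detect_pleiotropy(
    list(A = mk_stats("A", ids, pa), B = mk_stats("B", ids, pb),
      C = mk_stats("C", ids, pc_)),
    p_threshold = 1e-5
  )
  expect_setequal(res$pleiotropic, c("v3", "v4"))
  expect_identical(nrow(res$vsi), 1L) # only A-B intersect
  expect_identical(res$vsi$shared, 2L)
  expect_identical(res$vsi$total, 6L)
  expect_equal(res$vsi$vsi, round(100 * 2 / 6, 1))
  # identical sets give VSI 100
  res2 <- detect_pleiotropy(
    list(A = mk_stats("A", ids, pa), A2 = mk_stats("A2", ids, pa))
  )
  expect_equal(res2$vsi$vsi, 100)
})

test_that("phenotypic correlation matches the direct formula with Fisher CIs", {
  # 5-point worked fixture
  x <- c(1.2, 3.4, 2.2, 5.6, 4.4)
  y <- c(2.0, 3.1, 2.4, 6.3, 4.0)
  tr <- data.frame(t1 = x, t2 = y)
  out <- phenotypic_correlation(tr, min_pairs = 5)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_hand, tolerance = 1e-10)
  # null simulation: few significant pairs among independent traits
  set.seed(51)
  nt <- 20
  tr2 <- as.data.frame(matrix(rnorm(500 * nt), 500, nt))
  out2 <- phenotypic_correlation(tr2)
  expect_lt(mean(out2$significant), 0.05)
  # constant trait reported NA, trait vs itself r = 1
  tr3 <- data.frame(a = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1), b = rnorm(10))
  out3 <- phenotypic_correlation(tr3, min_pairs = 5)
  expect_true(is.na(out3$r))
  tr4 <- data.frame(a = rnorm(12))
  tr4$b <- tr4$a
  expect_equal(phenotypic_correlation(tr4, min_pairs = 5)$r, 1)
})

test_that("trait filtering keeps most-recent records and screens traits", {
  set.seed(52)
  base <- data.frame(
    sample_id = rep(paste0("s", 1:50), each = 2),
    date = rep(c("2018-01-01", "2019-06-01"), 50)
  )
  base$q1 <- rnorm(100)
  base$sparse <- NA_real_
  base$sparse[1:8] <- rnorm(8)
  base$bin_ok <- rbinom(100, 1, 0.5)
  base$bin_bad <- rbinom(100, 1, 0.1)
  while (mean(base$bin_bad) >= 0.2) base$bin_bad <- rbinom(100, 1, 0.1)
  out <- filter_traits(base)
  expect_identical(nrow(out), 50L)
  # the 2019 record wins for every sample
  expect_true(all(out$date == "2019-06-01"))
  expect_true(all(c("q1", "bin_ok") %in% names(out)))
  expect_false(any(c("sparse", "bin_bad") %in% names(out)))
})

test_that("GRM matches the direct formula and behaves on known relationships", {
  # 3-sample, 4-variant toy against a hand computation
  dos <- rbind(
    c(0L, 1L, 2L, 1L),
    c(1L, 1L, 0L, 2L),
    c(2L, 0L, 1L, 0L)
  )
  gm <- toy_genotypes(dos)
  grm <- build_grm(gm, maf_min = 0)
  p <- colMeans(dos) / 2
  A_hand <- matrix(0, 3, 3)
  for (j in 1:3) {
    for (k in 1:3) {
      A_hand[j, k] <- mean(
        (dos[j, ] - 2 * p) * (dos[k, ] - 2 * p) / (2 * p * (1 - p))
      )
    }
  }
  expect_equal(unname(grm$A), A_hand, tolerance = 1e-12)
  # duplicates and unrelated pairs at scale
  cfg <- cohort_config(
    n_samples = 80, n_variants = 10000, missing_rate = 0, seed = 53
  )
  g <- simulate_genotypes(cfg)
  g$genotypes$dosages[2, ] <- g$genotypes$dosages[1, ]
  big <- build_grm(g$genotypes)
  expect_lt(abs(big$A[1, 2] - big$A[1, 1]), 0.02)
  off <- big$A[upper.tri(big$A)][-1]
  expect_gte(mean(abs(off) < 0.05), 0.95)
  # diagonal close to 1 under HWE
  expect_lt(abs(mean(diag(big$A)) - 1), 0.05)
})

test_that("GREML recovers simulated heritability and covers the null", {
  # null sampling SD of the h2 estimate is sqrt(2 / (n^2 var_A)) with
  # var_A ~ 1/M; M = 2000 at n = 1000 gives SD ~ 0.06, so a null estimate
  # below 0.1 is the expected behavior rather than a coin flip
  cfg <- cohort_config(
    n_samples = 1000, n_variants = 2000, missing_rate = 0, seed = 54
  )
  g <- simulate_genotypes(cfg)
  grm <- build_grm(g$genotypes)
  eig <- eigen(grm$A, symmetric = TRUE)
  # h2 = 0.5 recovery across replicate trait draws
  est <- se <- numeric(5)
  for (r in 1:5) {
    tr <- simulate_traits(g$genotypes,
      trait_model(n_traits = 1, h2 = 0.5, n_causal = 300), seed = 100 + r)
    h <- reml_h2(grm, tr$traits$trait1, eig = eig)
    est[r] <- h$h2
    se[r] <- h$se
    expect_true(h$converged)
  }
  expect_lt(abs(mean(est) - 0.5), 0.1)
  # null traits: the analytic sampling SD of the h2 estimate is
  # SE0 = sqrt(2 / (n^2 var_A)); null estimates should be small on that
  # scale (boundary truncation at 0 makes the distribution half-normal-ish)
  # and the 95% CI should reach 0 at close to its nominal rate
  var_A <- stats::var(grm$A[upper.tri(grm$A)])
  se0 <- sqrt(2 / (1000^2 * var_A))
  est0 <- ci_lo <- numeric(30)
  for (r in 1:30) {
    set.seed(200 + r)
    y <- rnorm(1000)
    h0 <- reml_h2(grm, y, eig = eig)
    est0[r] <- h0$h2
    ci_lo[r] <- h0$ci95[1]
  }
  expect_lt(mean(est0), se0)
  expect_gte(mean(est0 < 2.5 * se0), 0.9)
  expect_gte(mean(ci_lo <= 1e-12), 0.85)
})

test_that("bivariate GREML recovers genetic correlation and its null", {
  cfg <- cohort_config(
    n_samples = 1500, n_variants = 3000, missing_rate = 0, seed = 55
  )
  g <- simulate_genotypes(cfg)
  grm <- build_grm(g$genotypes)
  eig <- eigen(grm$A, symmetric = TRUE)
  rgs <- numeric(4)
  for (r in 1:4) {
    tr <- simulate_traits(g$genotypes,
      trait_model(n_traits = 2, h2 = 0.5, rg = matrix(c(1, .8, .8, 1), 2),
        n_causal = 300),
      seed = 300 + r
    )
    b <- bivariate_rg(grm, tr$traits$trait1, tr$traits$trait2, eig = eig)
    expect_false(b$excluded)
    rgs[r] <- b$rg
    expect_lt(b$p_lrt, 0.05)
  }
  expect_lt(abs(mean(rgs) - 0.8), 0.15)
  # near-duplicate trait: rg close to 1
  tr <- simulate_traits(g$genotypes,
    trait_model(n_traits = 1, h2 = 0.6, n_causal = 300), seed = 400)
  y1 <- tr$traits$trait1
  set.seed(401)
  y2 <- y1 + rnorm(length(y1), 0, 0.1 * sd(y1))
  b2 <- bivariate_rg(grm, y1, y2, eig = eig)
  expect_gt(b2$rg, 0.9)
  # genetically independent traits: LRT P typically non-significant
  tr2 <- simulate_traits(g$genotypes,
    trait_model(n_traits = 2, h2 = 0.5, n_causal = 300), seed = 402)
  b3 <- bivariate_rg(grm, tr2$traits$trait1, tr2$traits$trait2, eig = eig)
  expect_lt(abs(b3$rg), 0.35)
})

test_that("analytic GREML power matches published operating points and is
           monotone", {
  expect_equal(round(greml_power(2685, 0.3), 2), 0.72)
  expect_equal(round(greml_power(4000, 0.3), 2), 0.97)
  # null limit: as h2 -> 0 the power tends to the alpha/2 tail
  expect_equal(greml_power(2685, 0), pnorm(-qnorm(0.975)), tolerance = 1e-12)
  grid_n <- seq(500, 6000, by = 500)
  grid_h <- seq(0.05, 0.8, by = 0.05)
  pw_n <- greml_power(grid_n, 0.3)
  pw_h <- vapply(grid_h, function(h) greml_power(2685, h), numeric(1))
  expect_true(all(diff(pw_n) > 0))
  expect_true(all(diff(pw_h) > 0))
})

test_that("IVW equals the closed-form weighted slope and the Wald ratio", {
  bx <- c(0.12, -0.08, 0.25, 0.05, -0.17)
  sx <- rep(0.02, 5)
  by <- c(0.06, -0.05, 0.11, 0.03, -0.09)
  sy <- c(0.02, 0.03, 0.02, 0.04, 0.03)
  fit <- mr_ivw(bx, sx, by, sy)
  w <- 1 / sy^2
  expect_equal(fit$estimate, sum(w * bx * by) / sum(w * bx^2), tolerance = 1e-12)
  # single instrument: Wald ratio
  one <- mr_ivw(0.2, 0.02, 0.09, 0.03)
  expect_equal(one$estimate, 0.45, tolerance = 1e-12)
  # exact proportionality: slope recovered exactly
  prop <- mr_ivw(bx, sx, 2 * bx, sy)
  expect_equal(prop$estimate, 2, tolerance = 1e-12)
  expect_error(mr_ivw(rep(0, 3), sx[1:3], by[1:3], sy[1:3]), "zero")
})

test_that("Egger regression separates slope from directional pleiotropy", {
  set.seed(61)
  k <- 30
  bx <- runif(k, 0.05, 0.3) * sample(c(-1, 1), k, TRUE)
  sy <- rep(0.02, k)
  # exact proportionality: slope gamma, zero intercept
  ex <- mr_egger(bx, rep(0.01, k), 0.6 * bx, sy)
  expect_equal(ex$estimate, 0.6, tolerance = 1e-10)
  expect_equal(ex$intercept, 0, tolerance = 1e-10)
  expect_error(mr_egger(bx[1:2], rep(0.01, 2), bx[1:2], sy[1:2]), "3")
  # constant directional pleiotropy lands in the intercept
  recov <- replicate(20, {
    bxs <- runif(k, 0.05, 0.3)
    bys <- 0.5 * bxs + 0.04 + rnorm(k, 0, 0.02)
    f <- mr_egger(bxs, rep(0.01, k), bys, sy)
    c(f$estimate, f$intercept)
  })
  expect_lt(abs(mean(recov[1, ]) - 0.5) / 0.5, 0.2)
  expect_lt(abs(mean(recov[2, ]) - 0.04), 0.02)
  # no-pleiotropy simulations: intercept CI covers zero most of the time
  cover <- mean(replicate(20, {
    bxs <- runif(k, 0.05, 0.3)
    bys <- 0.5 * bxs + rnorm(k, 0, 0.02)
    f <- mr_egger(bxs, rep(0.01, k), bys, sy)
    abs(f$intercept) < qt(0.975, k - 2) * f$intercept_se
  }))
  expect_gte(cover, 0.9)
})

test_that("MR-PRESSO flags a planted outlier and stays quiet on clean data", {
  set.seed(62)
  k <- 20
  clean_flags <- replicate(10, {
    bx <- runif(k, 0.1, 0.3)
    by <- 0.4 * bx + rnorm(k, 0, 0.02)
    f <- mr_presso(bx, rep(0.01, k), by, rep(0.02, k),
      nb_distribution = 500, seed = 1)
    length(f$outliers) == 0
  })
  expect_gte(mean(clean_flags), 0.9)
  spike_hit <- replicate(10, {
    bx <- runif(k, 0.1, 0.3)
    by <- 0.4 * bx + rnorm(k, 0, 0.02)
    by[7] <- by[7] + 10 * 0.02
    f <- mr_presso(bx, rep(0.01, k), by, rep(0.02, k),
      nb_distribution = 1000, seed = 2)
    7 %in% f$outliers
  })
  expect_gte(mean(spike_hit), 0.9)
  # removing one non-outlier instrument barely moves the estimate
  bx <- runif(k, 0.1, 0.3)
  by <- 0.4 * bx + rnorm(k, 0, 0.02)
  full <- mr_ivw(bx, rep(0.01, k), by, rep(0.02, k))
  drop1 <- mr_ivw(bx[-3], rep(0.01, k - 1), by[-3], rep(0.02, k - 1))
  expect_lt(abs(full$estimate - drop1$estimate), full$se)
})

test_that("MR-PRESSO global P is uniform under the null", {
  set.seed(63)
  k <- 15
  ps <- replicate(200, {
    bx <- runif(k, 0.1, 0.3)
    by <- 0.4 * bx + rnorm(k, 0, 0.02)
    mr_presso(bx, rep(0.01, k), by, rep(0.02, k),
      nb_distribution = 300, seed = sample.int(1e6, 1))$global_p
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("instrument selection keeps the best variant per LD block", {
  set.seed(64)
  n <- 600
  b1 <- rbinom(n, 2, 0.5)
  b2 <- rbinom(n, 2, 0.5)
  near <- function(b) ifelse(runif(n) < 0.9, b, rbinom(n, 2, 0.5))
  dos <- cbind(b1, near(b1), near(b1), b2, near(b2), rbinom(n, 2, 0.5),
    rbinom(n, 2, 0.5), rbinom(n, 2, 0.5))
  gm <- toy_genotypes(dos)
  p <- c(1e-8, 1e-6, 1e-7, 1e-9, 1e-6, 1e-6, 0.5, 0.9)
  st <- data.frame(id = gm$variant_meta$id, p = p)
  inst <- select_instruments(st, gm, p_threshold = 1e-5)
  # blocks: {1,2,3} -> v1; {4,5} -> v4; {6} -> v6; 7 and 8 not suggestive
  expect_setequal(inst, gm$variant_meta$id[c(1, 4, 6)])
  # perfect LD pair collapses to one instrument
  gm2 <- toy_genotypes(cbind(b1, b1))
  st2 <- data.frame(id = gm2$variant_meta$id, p = c(1e-7, 1e-8))
  expect_identical(select_instruments(st2, gm2), gm2$variant_meta$id[2])
  # no suggestive variants: empty selection
  st3 <- data.frame(id = gm2$variant_meta$id, p = c(0.5, 0.2))
  expect_identical(length(select_instruments(st3, gm2)), 0L)
})

test_that("MR consensus recovers a causal chain and not its reverse", {
  n_rep <- 20
  fwd <- rev_ <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    sim <- simulate_mr_cohort(seed = r)
    sx <- run_gwas(sim$genotypes, sim$traits, "trait1", covariates = NULL)
    sy <- run_gwas(sim$genotypes, sim$traits, "trait2", covariates = NULL)
    res <- list()
    fi <- select_instruments(sx, sim$genotypes)
    ri <- select_instruments(sy, sim$genotypes)
    if (length(fi)) res$f <- mr_pair(sx, sy, fi, nb_distribution = 2000, seed = r)
    if (length(ri)) res$r <- mr_pair(sy, sx, ri, nb_distribution = 2000, seed = r)
    cm <- consensus_mr(res)
    fwd[r] <- any(cm$consensus_significant[cm$exposure == "trait1"])
    rev_[r] <- any(cm$consensus_significant[cm$exposure == "trait2"])
  }
  expect_gte(mean(fwd), 0.8)
  expect_lt(mean(rev_), 0.2)
})

test_that("consensus requires two of three significant methods", {
  mk <- function(expo, outc, p_ivw, p_egger, p_presso) {
    r <- list(
      exposure = expo, outcome = outc, n_instruments = 10,
      ivw = list(estimate = 0.5, p = p_ivw),
      egger = list(estimate = 0.5, p = p_egger),
      presso = list(estimate = 0.5, p = p_presso)
    )
    class(r) <- "mr_result"
    r
  }
  res <- list(
    mk("a", "b", 1e-6, 0.9, 0.8), # one method only
    mk("c", "d", 1e-6, 0.9, 1e-6), # IVW + PRESSO
    mk("e", "f", 1e-6, 1e-6, 1e-6) # all three
  )
  cm <- consensus_mr(res)
  expect_identical(cm$consensus_significant, c(FALSE, TRUE, TRUE))
  expect_identical(cm$direction, c("none", "unidirectional", "unidirectional"))
})

test_that("network export applies the anchoring rule for PC and MR edges", {
  gc <- data.frame(
    trait_i = c("A", "B"), trait_j = c("B", "C"),
    rg = c(0.6, 0.3), significant = c(TRUE, FALSE)
  )
  vsi <- data.frame(trait_i = "C", trait_j = "D", vsi = 12.5)
  pc <- data.frame(
    trait_i = c("A", "A"), trait_j = c("B", "E"),
    r = c(0.4, 0.9), significant = c(TRUE, TRUE)
  )
  mr <- data.frame(
    exposure = c("C", "E"), outcome = c("D", "A"),
    ivw_estimate = c(0.5, 0.7), consensus_significant = c(TRUE, TRUE)
  )
  net <- export_network(gc = gc, pc = pc, vsi = vsi, mr = mr)
  e <- net$edges
  # GC edge A-B (significant) and pleiotropy C-D present
  expect_identical(sum(e$type == "GC"), 1L)
  expect_identical(sum(e$type == "pleiotropy"), 1L)
  # PC A-B anchored by GC; PC A-E has no anchor and is dropped
  expect_identical(sum(e$type == "PC"), 1L)
  expect_false(any(e$type == "PC" & e$to == "E"))
  # MR C->D anchored by pleiotropy; E->A dropped
  mr_edges <- e[e$type == "MR", ]
  expect_identical(nrow(mr_edges), 1L)
  expect_identical(mr_edges$from, "C")
  expect_true(mr_edges$directed)
  # empty inputs give an empty graph
  empty <- export_network()
  expect_identical(nrow(empty$edges), 0L)
  # edge-list round trip to disk
  f <- withr::local_tempfile(fileext = ".tsv")
  export_network(gc = gc, pc = pc, vsi = vsi, mr = mr, path = f)
  expect_identical(nrow(read.delim(f)), nrow(e))
})
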