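#' Synthetic cohort configuration
#'
#' Collects the knobs of the cohort generator: population structure
#' (Balding-Nichols subpopulations at a given Fst), family structure
#' (related pairs produced by Mendelian gamete transmission), sequencing
#' batches and the fraction of variants carrying a batch-biased allele
#' balance at heterozygous calls, mean read depth, and a missing-call rate.
#'
#' @param n_samples number of samples (founders plus related individuals).
#' @param n_variants number of variants.
#' @param n_subpops number of subpopulations; samples are assigned in
#'   approximately equal blocks.
#' @param fst Balding-Nichols divergence parameter in \[0, 1); 0 gives a
#'   single panmictic population.
#' @param ancestral_af_range interval in (0, 1) from which ancestral
#'   alternate-allele frequencies are drawn uniformly.
#' @param related_pairs named integer vector: counts of relationship types
#'   among `"parent-offspring"`, `"full-sib"`, `"second-degree"`
#'   (half-sibs). Each pair consumes founders as parents and appends the
#'   non-founder individuals at the end of the sample list.
#' @param n_batches number of sequencing batches; samples are split evenly
#'   and the first batch is the one affected by read-count bias.
#' @param batch_biased_fraction fraction of variants whose heterozygous
#'   allele balance is biased in the affected batch.
#' @param bias_ab expected alternate-read fraction at biased heterozygous
#'   calls (unbiased calls have 0.5).
#' @param mean_depth mean sequencing depth (reads per site, Poisson).
#' @param missing_rate per-call probability of a missing genotype.
#' @param n_chrom number of chromosomes variants are spread over, with
#'   uniform spacing.
#' @param seed integer random seed; all generator functions are
#'   deterministic given the config seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 500, n_variants = 5000, n_subpops = 1,
                          fst = 0, ancestral_af_range = c(0.05, 0.95),
                          related_pairs = c(), n_batches = 2,
                          batch_biased_fraction = 0.05, bias_ab = 0.65,
                          mean_depth = 30, missing_rate = 0.005,
                          n_chrom = 1, seed = 1) {
  stopifnot(
    n_samples > 0, n_variants > 0, n_subpops >= 1,
    fst >= 0, fst < 1,
    length(ancestral_af_range) == 2,
    ancestral_af_range[1] > 0, ancestral_af_range[2] < 1,
    batch_biased_fraction >= 0, batch_biased_fraction <= 1,
    bias_ab > 0, bias_ab < 1, mean_depth > 0,
    missing_rate >= 0, missing_rate < 1
  )
  if (length(related_pairs)) {
    ok <- names(related_pairs) %in% c("parent-offspring", "full-sib", "second-degree")
    if (!all(ok)) stop("unknown relationship type in related_pairs")
  }
  structure(
    list(
      n_samples = as.integer(n_samples), n_variants = as.integer(n_variants),
      n_subpops = as.integer(n_subpops), fst = fst,
      ancestral_af_range = ancestral_af_range,
      related_pairs = related_pairs, n_batches = as.integer(n_batches),
      batch_biased_fraction = batch_biased_fraction, bias_ab = bias_ab,
      mean_depth = mean_depth, missing_rate = missing_rate,
      n_chrom = as.integer(n_chrom), seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# number of non-founder individuals implied by the relationship list
n_related_individuals <- function(related_pairs) {
  if (!length(related_pairs)) return(0L)
  # parent-offspring: 1 child; full-sib: 2 children; second-degree: 2 half-sib
  # children of a shared parent
  per <- c("parent-offspring" = 1L, "full-sib" = 2L, "second-degree" = 2L)
  sum(per[names(related_pairs)] * as.integer(related_pairs))
}

# mendelian gamete: one transmitted allele per variant given parental dosage
transmit_gamete <- function(dosage) {
  stats::rbinom(length(dosage), 1L, dosage / 2)
}

#' Simulate structured genotypes
#'
#' Founders are drawn per subpopulation under a Balding-Nichols model:
#' each subpopulation's allele frequency is Beta-distributed with mean equal
#' to the ancestral frequency and variance `fst * p * (1 - p)`; founder
#' genotypes are Hardy-Weinberg binomial draws within subpopulation. Related
#' individuals are appended by Mendelian gamete transmission from designated
#' founder parents. Missing calls are injected uniformly at
#' `config$missing_rate`.
#'
#' @param config a [cohort_config()].
#' @return list with `genotypes` (a [genotype_matrix()]), `truth` (list with
#'   `subpop` per-sample labels, `ancestral_af`, `subpop_af` matrix,
#'   `realized_af` from the simulated dosages, `kinship` data.frame of true
#'   related pairs with expected PI_HAT, `batch` per-sample batch labels).
#' @export
simulate_genotypes <- function(config) {
  set.seed(config$seed)
  n_rel <- n_related_individuals(config$related_pairs)
  n_founders <- config$n_samples - n_rel
  # each relationship consumes 2 founder parents
  n_parents_needed <- 2L * sum(as.integer(config$related_pairs))
  if (n_founders <= 0 || n_parents_needed > n_founders) {
    stop("related_pairs exceed available founders for n_samples")
  }
  M <- config$n_variants
  p_anc <- stats::runif(M, config$ancestral_af_range[1], config$ancestral_af_range[2])
  subpop_af <- matrix(NA_real_, config$n_subpops, M)
  for (k in seq_len(config$n_subpops)) {
    if (config$fst == 0) {
      subpop_af[k, ] <- p_anc
    } else {
      a <- p_anc * (1 - config$fst) / config$fst
      b <- (1 - p_anc) * (1 - config$fst) / config$fst
      subpop_af[k, ] <- stats::rbeta(M, a, b)
    }
  }
  subpop <- rep(seq_len(config$n_subpops), length.out = n_founders)
  subpop <- sort(subpop)
  dos <- matrix(0L, config$n_samples, M)
  for (k in seq_len(config$n_subpops)) {
    rows <- which(subpop == k)
    dos[rows, ] <- matrix(
      stats::rbinom(length(rows) * M, 2L, rep(subpop_af[k, ], each = length(rows))),
      nrow = length(rows)
    )
  }

  # related individuals: append after founders, consuming parents in order
  kin <- list()
  next_parent <- 1L
  next_child <- n_founders + 1L
  child_subpop <- integer(0)
  for (rel in names(config$related_pairs)) {
    for (r in seq_len(config$related_pairs[[rel]])) {
      pa <- next_parent
      pb <- next_parent + 1L
      next_parent <- next_parent + 2L
      make_child <- function() {
        dos_child <- transmit_gamete(dos[pa, ]) + transmit_gamete(dos[pb, ])
        dos[next_child, ] <<- as.integer(dos_child)
        child_subpop <<- c(child_subpop, subpop[pa])
        id <- next_child
        next_child <<- next_child + 1L
        id
      }
      if (rel == "parent-offspring") {
        c1 <- make_child()
        kin[[length(kin) + 1L]] <- data.frame(
          sample_i = pa, sample_j = c1, relationship = "parent-offspring",
          expected_pi_hat = 0.5
        )
      } else if (rel == "full-sib") {
        c1 <- make_child()
        c2 <- make_child()
        kin[[length(kin) + 1L]] <- data.frame(
          sample_i = c1, sample_j = c2, relationship = "full-sib",
          expected_pi_hat = 0.5
        )
      } else { # second-degree: half sibs sharing parent pa
        dos_c1 <- transmit_gamete(dos[pa, ]) +
          stats::rbinom(M, 1L, subpop_af[subpop[pa], ])
        dos[next_child, ] <- as.integer(dos_c1)
        child_subpop <- c(child_subpop, subpop[pa])
        c1 <- next_child
        next_child <- next_child + 1L
        dos_c2 <- transmit_gamete(dos[pa, ]) +
          stats::rbinom(M, 1L, subpop_af[subpop[pa], ])
        dos[next_child, ] <- as.integer(dos_c2)
        child_subpop <- c(child_subpop, subpop[pa])
        c2 <- next_child
        next_child <- next_child + 1L
        kin[[length(kin) + 1L]] <- data.frame(
          sample_i = c1, sample_j = c2, relationship = "second-degree",
          expected_pi_hat = 0.25
        )
      }
    }
  }
  kinship <- if (length(kin)) do.call(rbind, kin) else
    data.frame(sample_i = integer(0), sample_j = integer(0),
               relationship = character(0), expected_pi_hat = numeric(0))

  if (config$missing_rate > 0) {
    miss <- stats::runif(length(dos)) < config$missing_rate
    dos[miss] <- NA_integer_
  }

  per_chrom <- ceiling(M / config$n_chrom)
  chrom <- rep(seq_len(config$n_chrom), each = per_chrom)[seq_len(M)]
  pos_in_chrom <- stats::ave(seq_len(M), chrom, FUN = seq_along)
  meta <- data.frame(
    chrom = as.character(chrom),
    pos = pos_in_chrom * 1000L, # uniform 1 kb spacing
    ref = "A", alt = "G",
    stringsAsFactors = FALSE
  )
  sample_ids <- sprintf("S%04d", seq_len(config$n_samples))
  gm <- genotype_matrix(dos, meta, sample_ids)

  batch <- rep(paste0("batch", seq_len(config$n_batches)),
    length.out = config$n_samples
  )
  kinship$sample_i <- sample_ids[kinship$sample_i]
  kinship$sample_j <- sample_ids[kinship$sample_j]
  truth <- list(
    subpop = c(subpop, child_subpop),
    ancestral_af = p_anc,
    subpop_af = subpop_af,
    realized_af = allele_freq(gm),
    kinship = kinship,
    batch = batch,
    n_founders = n_founders
  )
  list(genotypes = gm, truth = truth)
}

#' Simulate per-sample read counts with an optional batch bias
#'
#' Depth at each call is Poisson(`mean_depth`). Alternate reads are binomial
#' with success probability 0, 0.5 or 1 for genotypes 0/1/2. At a randomly
#' chosen `batch_biased_fraction` of variants, heterozygous calls from
#' samples in the first batch use `bias_ab` instead of 0.5 — emulating a
#' library-preparation batch effect visible only where both alleles are
#' expected.
#'
#' @param genotypes a [genotype_matrix()].
#' @param config a [cohort_config()]; `batch`, bias fraction, depth and the
#'   derived seed come from here.
#' @param batch per-sample batch labels; defaults to the even split implied
#'   by `config`.
#' @return list with `ref_reads` and `alt_reads` integer matrices (NA at
#'   missing genotypes) and `biased_variants` (integer indices of the truth
#'   biased set).
#' @export
simulate_read_counts <- function(genotypes, config, batch = NULL) {
  set.seed(config$seed + 1L)
  n <- n_samples(genotypes)
  M <- n_variants(genotypes)
  if (is.null(batch)) {
    batch <- rep(paste0("batch", seq_len(config$n_batches)), length.out = n)
  }
  n_biased <- round(config$batch_biased_fraction * M)
  biased <- sort(sample.int(M, n_biased))
  dos <- genotypes$dosages
  depth <- matrix(stats::rpois(n * M, config$mean_depth), n, M)
  p <- dos / 2 # 0, 0.5, 1
  affected <- batch == "batch1"
  if (n_biased > 0) {
    het_bias <- affected & !is.na(dos[, biased, drop = FALSE]) &
      dos[, biased, drop = FALSE] == 1L
    pb <- p[, biased, drop = FALSE]
    pb[het_bias] <- config$bias_ab
    p[, biased] <- pb
  }
  p_draw <- p
  p_draw[is.na(p_draw)] <- 0 # missing calls: masked to NA below
  alt <- matrix(stats::rbinom(n * M, as.vector(depth), as.vector(p_draw)), n, M)
  alt[is.na(dos)] <- NA_integer_
  ref <- depth - alt
  ref[is.na(dos)] <- NA_integer_
  dimnames(ref) <- dimnames(alt) <- dimnames(dos)
  list(ref_reads = ref, alt_reads = alt, biased_variants = biased, batch = batch)
}

#' Trait model for the synthetic cohort
#'
#' @param n_traits number of quantitative traits.
#' @param h2 per-trait narrow-sense heritability in \[0, 1\] (recycled).
#' @param rg genetic-correlation matrix (symmetric, unit diagonal, PSD);
#'   default identity.
#' @param n_causal causal variants per trait.
#' @param pleiotropic_sets optional list of lists
#'   `list(traits = c(i, j), variants = idx)` forcing shared causal variants.
#' @param causal_edges optional data.frame `exposure`, `outcome`, `gamma`:
#'   the outcome trait is `gamma * exposure` plus its own genetic and
#'   environmental components.
#' @param covariate_effects named numeric vector of coefficients for
#'   `sex`, `age`, `age2`, `bmi` added to every trait.
#' @return a `trait_model` list.
#' @export
trait_model <- function(n_traits = 2, h2 = 0.5, rg = NULL, n_causal = 100,
                        pleiotropic_sets = NULL, causal_edges = NULL,
                        covariate_effects = c(sex = 0, age = 0, age2 = 0, bmi = 0)) {
  h2 <- rep_len(h2, n_traits)
  stopifnot(all(h2 >= 0), all(h2 <= 1))
  if (is.null(rg)) rg <- diag(n_traits)
  rg <- as.matrix(rg)
  stopifnot(nrow(rg) == n_traits, ncol(rg) == n_traits)
  if (max(abs(rg - t(rg))) > 1e-8 || any(abs(rg) > 1 + 1e-12)) {
    stop("rg must be symmetric with entries in [-1, 1]")
  }
  ev <- eigen(rg, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("rg must be positive semidefinite")
  if (!is.null(causal_edges)) {
    stopifnot(all(c("exposure", "outcome", "gamma") %in% names(causal_edges)))
    stopifnot(all(is.finite(causal_edges$gamma)))
  }
  structure(
    list(
      n_traits = as.integer(n_traits), h2 = h2, rg = rg,
      n_causal = as.integer(n_causal), pleiotropic_sets = pleiotropic_sets,
      causal_edges = causal_edges, covariate_effects = covariate_effects
    ),
    class = "trait_model"
  )
}

#' Simulate quantitative traits with genetic architecture
#'
#' Per-trait genetic values are sums of standardized causal genotypes times
#' effects drawn jointly across traits with correlation `rg`; environmental
#' noise is scaled against the realized genetic variance so that
#' var(g)/var(g + e) equals `h2` exactly in expectation. Sex, age, age
#' squared and BMI covariates are simulated from simple parametric
#' distributions and added with `covariate_effects`; causal trait-trait
#' edges add `gamma * exposure` to the outcome.
#'
#' @param genotypes a [genotype_matrix()].
#' @param model a [trait_model()].
#' @param seed integer seed.
#' @return list with `traits` (data.frame: sample_id, sex, age, age2, bmi,
#'   trait1..traitK) and `truth` (causal indices, effect matrix, genetic
#'   values, realized h2/rg, gamma edges).
#' @export
simulate_traits <- function(genotypes, model, seed = 1) {
  set.seed(seed)
  n <- n_samples(genotypes)
  M <- n_variants(genotypes)
  K <- model$n_traits
  if (model$n_causal > M) stop("n_causal exceeds n_variants")

  sex <- stats::rbinom(n, 1, 0.5)
  age <- round(stats::rnorm(n, 50, 10))
  bmi <- stats::rnorm(n, 24, 3)
  cov_part <- model$covariate_effects["sex"] * sex +
    model$covariate_effects["age"] * age +
    model$covariate_effects["age2"] * age^2 +
    model$covariate_effects["bmi"] * bmi

  # genetic correlation is carried by correlated effects at shared causal
  # variants: with any nonzero off-diagonal rg the traits share one causal
  # set; with identity rg each trait gets its own independent set
  shared_arch <- K > 1 && max(abs(model$rg[upper.tri(model$rg)])) > 0
  if (shared_arch) {
    base_set <- sort(sample.int(M, model$n_causal))
    causal <- rep(list(base_set), K)
  } else {
    causal <- lapply(seq_len(K), function(t) sort(sample.int(M, model$n_causal)))
  }
  if (!is.null(model$pleiotropic_sets)) {
    for (ps in model$pleiotropic_sets) {
      for (t in ps$traits) {
        causal[[t]] <- sort(union(causal[[t]], ps$variants))
      }
    }
  }
  all_causal <- sort(unique(unlist(causal)))
  Z <- genotypes$dosages[, all_causal, drop = FALSE]
  Z[is.na(Z)] <- 0L
  Z <- scale(Z)
  Z[, attr(Z, "scaled:scale") == 0] <- 0

  # joint effect draws: rows = variants in all_causal, cols = traits,
  # correlated across traits via the Cholesky-like square root of rg
  er <- eigen(model$rg, symmetric = TRUE)
  rg_sqrt <- er$vectors %*% diag(sqrt(pmax(er$values, 0)), K) %*% t(er$vectors)
  B <- matrix(stats::rnorm(length(all_causal) * K), ncol = K) %*% rg_sqrt
  # zero out effects at variants not causal for a trait
  for (t in seq_len(K)) {
    B[!(all_causal %in% causal[[t]]), t] <- 0
  }
  G <- Z %*% B # n x K genetic values
  g_var <- apply(G, 2, stats::var)

  Y <- matrix(0, n, K)
  E <- matrix(0, n, K)
  for (t in seq_len(K)) {
    if (model$h2[t] == 0 || g_var[t] == 0) {
      G[, t] <- 0
      E[, t] <- stats::rnorm(n, 0, 1)
    } else {
      e_sd <- sqrt(g_var[t] * (1 - model$h2[t]) / model$h2[t])
      E[, t] <- stats::rnorm(n, 0, e_sd)
    }
    Y[, t] <- G[, t] + E[, t]
  }
  if (!is.null(model$causal_edges)) {
    for (r in seq_len(nrow(model$causal_edges))) {
      ex <- model$causal_edges$exposure[r]
      ou <- model$causal_edges$outcome[r]
      Y[, ou] <- Y[, ou] + model$causal_edges$gamma[r] * Y[, ex]
    }
  }
  Y <- Y + cov_part

  traits <- data.frame(
    sample_id = genotypes$sample_ids, sex = sex, age = age, age2 = age^2,
    bmi = bmi
  )
  tn <- paste0("trait", seq_len(K))
  traits[tn] <- as.data.frame(Y)

  realized_rg <- if (K > 1) stats::cor(G) else matrix(1, 1, 1)
  realized_h2 <- ifelse(g_var > 0,
    apply(G, 2, stats::var) / (apply(G, 2, stats::var) + apply(E, 2, stats::var)),
    0
  )
  list(
    traits = traits,
    truth = list(
      causal = causal, effects = B, causal_index = all_causal,
      genetic_values = G, env_values = E, realized_h2 = realized_h2,
      realized_rg = realized_rg, causal_edges = model$causal_edges,
      trait_names = tn
    )
  )
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_read_counts()] and [simulate_traits()] under one seed.
#'
#' @param config a [cohort_config()].
#' @param model a [trait_model()], or `NULL` to skip traits.
#' @return a `synthetic_cohort` list: `genotypes`, `read_counts`, `traits`,
#'   `truth`.
#' @export
simulate_cohort <- function(config, model = trait_model()) {
  g <- simulate_genotypes(config)
  rc <- simulate_read_counts(g$genotypes, config, batch = g$truth$batch)
  tr <- if (is.null(model)) NULL else {
    simulate_traits(g$genotypes, model, seed = config$seed + 2L)
  }
  truth <- g$truth
  truth$biased_variants <- rc$biased_variants
  if (!is.null(tr)) truth <- c(truth, tr$truth)
  structure(
    list(
      genotypes = g$genotypes,
      read_counts = rc[c("ref_reads", "alt_reads")],
      traits = if (is.null(tr)) NULL else tr$traits,
      truth = truth,
      config = config
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", n_samples(x$genotypes), "samples,",
      n_variants(x$genotypes), "variants\n")
  if (!is.null(x$traits)) {
    cat("  traits:", paste(setdiff(names(x$traits),
      c("sample_id", "sex", "age", "age2", "bmi")), collapse = ", "), "\n")
  }
  invisible(x)
}
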