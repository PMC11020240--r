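# shared fixtures, built in code at test time

# tiny genotype matrix with explicit dosages (samples x variants)
toy_genotypes <- function(dosages, chrom = "1", spacing = 1000L) {
  dosages <- as.matrix(dosages)
  meta <- data.frame(
    chrom = chrom,
    pos = seq_len(ncol(dosages)) * spacing,
    ref = "A", alt = "G", stringsAsFactors = FALSE
  )
  genotype_matrix(dosages, meta)
}

# brute-force HWE exact P: enumerate every heterozygote configuration
# compatible with the allele counts and sum the probabilities <= observed
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- n_Aa + 2 * n_aa
  nA <- n_Aa + 2 * n_AA
  rare <- min(na, nA)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- vapply(hets, function(h) {
    hom_rare <- (rare - h) / 2
    hom_common <- n - h - hom_rare
    exp(lfactorial(n) - lfactorial(h) - lfactorial(hom_rare) -
      lfactorial(hom_common) + h * log(2) +
      lfactorial(rare) + lfactorial(2 * n - rare) - lfactorial(2 * n))
  }, numeric(1))
  probs <- probs / sum(probs)
  obs <- probs[hets == n_Aa]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# per-variant Hudson Fst from subpopulation allele frequencies
hudson_fst <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# two-trait cohort with a causal exposure -> outcome edge, for MR tests
simulate_mr_cohort <- function(seed, n = 2000, m = 400, gamma = 0.5) {
  cfg <- cohort_config(
    n_samples = n, n_variants = m, fst = 0, missing_rate = 0,
    ancestral_af_range = c(0.1, 0.9), n_chrom = 40, seed = seed
  )
  g <- simulate_genotypes(cfg)
  tm <- trait_model(
    n_traits = 2, h2 = 0.4, n_causal = 40,
    causal_edges = data.frame(exposure = 1, outcome = 2, gamma = gamma)
  )
  tr <- simulate_traits(g$genotypes, tm, seed = seed + 1000)
  list(genotypes = g$genotypes, traits = tr$traits, truth = tr$truth)
}
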