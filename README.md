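# kovariome

Post-genotyping analysis of population-scale whole-genome cohorts, from
variome quality control to trait-pair phenomics. The package is aimed at
researchers who have a jointly genotyped multi-sample VCF (with per-call
allele depths) and a matched clinical trait table, and who need the
standard downstream battery in one tested, scriptable place:

* **Variome QC** — per-sample missingness and het/hom filters;
  method-of-moments kinship (PI_HAT) with greedy unrelated-set selection;
  an **allele-balance batch-effect filter** that excludes variants whose
  mean heterozygous alternate-read fraction falls outside mean ± 1 SD of
  the genome-wide distribution; exact Hardy-Weinberg testing; LD pruning;
  PCA for structure.
* **Allele-frequency profiling** — singleton/doubleton/very-rare/rare/
  common/very-common categories, novelty annotation against known sites,
  and variant-discovery saturation curves over sample permutations.
* **Population specificity** — 1-df Pearson chi-square on allele counts
  against a panel of reference populations; a variant is
  population-specific only when P < 5e-5 against every panel.
* **WGWAS** — per-variant linear/logistic regression under an additive
  model with sex, age, age², BMI and genotype-PC covariates; genomic
  inflation λ_median; greedy LD clumping (r² 0.1, 250 kb); BH FDR.
* **Phenomics** — Pearson phenotypic correlations with Fisher-z CIs;
  pleiotropy detection with the **Variant-Sharing Index**
  (VSI = 100·|S_i∩S_j|/|S_i∪S_j| over suggestive-variant sets); GREML
  heritability and bivariate genetic correlation by REML on the GRM
  eigendecomposition, with the analytic power formula
  power = Φ(h²/SE − z_{1−α/2}), SE = √(2/(n²·var_A)); consensus Mendelian
  randomization (IVW, MR-Egger, MR-PRESSO; causal when ≥ 2 of 3 methods
  reach FDR < 0.05); multi-edge trait-network export.
* **Imputation evaluation** — squared Pearson correlation between true
  genotypes and imputed dosages, aggregated by alternate-allele-frequency
  bin.
* **Synthetic cohorts** — a Balding-Nichols generator with related pairs,
  batch-biased read counts, and traits of known heritability/genetic
  correlation/causal structure, with full ground truth for parameter
  recovery.

## Worked example

Simulate a 500-sample cohort in which 5% of variants carry a batch-biased
allele balance (heterozygous alternate-read fraction 0.65 instead of 0.5
in the affected batch), then recover them with the allele-balance filter:

```r
library(kovariome)

cfg <- cohort_config(n_samples = 500, n_variants = 3000,
                     batch_biased_fraction = 0.05, bias_ab = 0.65,
                     mean_depth = 30, seed = 101)
g  <- simulate_genotypes(cfg)
rc <- simulate_read_counts(g$genotypes, cfg, batch = g$truth$batch)

ab   <- compute_allele_balance(g$genotypes, rc)
keep <- filter_batch_effect(ab)           # keep inside [mean - SD, mean + SD]
```

This prints (via the calls below):

```
genome-wide mean AB = 0.5039, SD = 0.0180
excluded 246 of 3000 variants; recall of injected biased set = 1.000
```

The genome-wide mean sits just above 0.5 because the biased variants drag
it up slightly; the filter removes every injected biased variant (recall
1.000) plus a tail of noisy low-het-count variants. Two closed-form
phenomics quantities:

```r
compute_vsi(638, 632, 569)   # union = 701, VSI = 81.2
greml_power(2685, 0.3)       # 0.72
greml_power(4000, 0.3)       # 0.97
```

A trait pair sharing 569 of its 701 distinct suggestive variants has
VSI 81.2% — nearly interchangeable association signals — and a GREML
study of 2,685 phenotyped samples has power 0.72 to detect h² = 0.3,
rising to 0.97 at 4,000 samples.

The full pipeline (QC → profile → WGWAS → phenomics → network) runs from
one call:

```r
co <- simulate_cohort(cohort_config(n_samples = 150, n_variants = 4000,
                                    seed = 4),
                      trait_model(n_traits = 3, h2 = 0.5, n_causal = 200))
res <- run_pipeline(co$genotypes, co$read_counts, co$traits,
                    trait_cols = c("trait1", "trait2", "trait3"))
res$manifest   # thresholds, seed, per-filter sample/variant counts
```

A thin command-line wrapper lives in `inst/cli/kovariome.R`
(`simulate` and `run` subcommands).

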