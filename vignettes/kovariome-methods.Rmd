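---
title: "Methods: cohort variome QC, association, and phenomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort variome QC, association, and phenomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kovariome)
```

`kovariome` implements the post-genotyping stages of a population-scale
whole-genome cohort study: variome quality control, allele-frequency
profiling, population-specificity testing, covariate-adjusted genome-wide
association (WGWAS), and four trait-pair "phenomics" analyses — phenotypic
correlation, pleiotropy with a Variant-Sharing Index, GREML heritability
and genetic correlation, and consensus Mendelian randomization. Because
cohort-scale human genotype data are access-restricted, the package ships a
synthetic-cohort generator with full ground truth, and every stage is
validated by parameter recovery against that truth.

## Sample and variant quality control

Sample-level filters follow the standard sequence for sequencing cohorts:

* **Missingness.** Samples with more than 10% missing genotypes are
  flagged (`sample_qc()`, `max_missing = 0.10`).
* **Heterozygosity.** The per-sample ratio of heterozygous to
  non-reference homozygous calls is compared with the cohort mean; samples
  outside 3 SD are flagged. A sample with no non-reference homozygotes has
  an undefined ratio and is flagged for review rather than silently
  passed. When the cohort SD is zero (degenerate, e.g. identical samples)
  no outlier flag is raised.
* **Relatedness.** `estimate_ibd()` implements the method-of-moments
  IBD-state decomposition used by PLINK: observed identity-by-state
  counts across variants are equated with their expectations under IBD
  states 0/1/2 and solved sequentially; the state proportions are
  truncated to [0, 1] and renormalized, and
  `PI_HAT = P(IBD=1)/2 + P(IBD=2)`. When allele frequencies are estimated
  from the cohort itself, the expectations use without-replacement
  (hypergeometric) moments of the observed allele pool; the uncorrected
  infinite-population formulas (still used when an external reference AF
  is supplied) bias PI_HAT upward in small cohorts.
  `select_unrelated()` greedily drops the sample participating in the
  most pairs above the threshold (default `PI_HAT > 0.05`), breaking ties
  by sample label so the result is deterministic. The 0.05 threshold is
  far below typical third-degree cutoffs; it is kept as the default
  because it is the convention this pipeline mirrors, and it is
  configurable.

Two properties of the truncated estimator are worth knowing. First, raw
(untruncated) PI_HAT is unbiased for unrelated pairs with sampling SD of
roughly 0.018 at 5,000 common variants, but truncation of negative IBD
components inflates small values, so a few percent of genuinely unrelated
pairs exceed 0.05 at that marker count; the tail disappears as the marker
count grows. Second, parent-offspring pairs are estimated tightly around
0.5 (the Mendelian expectation) essentially independently of marker count
beyond a few thousand.

* **Allele balance (batch effects).** At a heterozygous call both alleles
  are expected in the reads, so the alternate-read fraction
  AB = alt/(ref+alt) should center on 0.5; systematic departures shared
  by many samples indicate library-preparation or sequencing batch
  artifacts. `compute_allele_balance()` averages AB per variant over
  heterozygous calls only — homozygous calls have expected AB 0 or 1 and
  would swamp the statistic — and `filter_batch_effect()` excludes
  variants whose mean falls outside the closed interval mean ± 1 SD of
  the genome-wide distribution. Three numerical choices are deliberate:
  the genome-wide mean and SD are computed once, over all variants with a
  defined mean, before any exclusion (a single pass, no iteration);
  variants exactly on the boundary are kept; variants with no
  heterozygous call are kept and marked, never silently scored 0.
  In the pipeline the filter runs after sample filters and unrelated
  selection, so the statistic reflects the analysis cohort.
* **Genotyping rate.** Variants with a call rate below 0.9 are dropped
  (`variant_qc()`), and the association prefilter additionally requires
  MAF ≥ 0.01, exact HWE P ≥ 1e-6, and missingness ≤ 0.01
  (`prefilter_variants()`).
* **Hardy-Weinberg.** `hwe_exact_test()` is the conditional exact test on
  genotype counts (the Levene distribution of the heterozygote count given
  allele counts), summing the probabilities of configurations no more
  likely than the observed one. No mid-p correction is applied; the test
  agrees with a full enumeration oracle to 1e-12 on all tables with
  total ≤ 50. Monomorphic variants return P = 1.
* **Structure.** `pca_genotypes()` eigendecomposes the covariance of
  standardized dosages; missing dosages are mean-imputed for PCA and LD
  computations only, never for association. `pca_outliers()` flags
  samples beyond k SD (default 6) of the target-population centroid on
  the first two components; the multiplier is configurable because no
  published rule exists for "divergent background" — it is a judgment
  call surfaced as a parameter.

## Allele-frequency profile and saturation

Polymorphic variants are partitioned by alternate allele count (AC) and
frequency (AF): singleton (AC = 1), doubleton (AC = 2), very rare
(AC > 2, AF ≤ 0.001), rare (0.001 < AF ≤ 0.01), common
(0.01 < AF ≤ 0.05), very common (AF > 0.05). Upper bin edges are
inclusive, and the alternate allele (not the minor allele) defines AF, so
sites above 0.5 stay in the very-common class. `saturation_curve()`
measures discovery: for random permutations of the samples (default 10,
seeded), it counts the distinct variants of each category carried by the
first k samples, holding category membership fixed from the full cohort —
re-categorizing at each k would make the curves ill-defined. Rarer
categories saturate later; cohort-wide singletons by construction keep
accumulating until the last carrier enters.

## Population specificity

`chi2_allele_test()` is the 1-df Pearson chi-square on the 2×2 table of
alternate/reference allele counts in two populations, without continuity
correction (the usual population-genetics convention), computed on allele
counts (2N) rather than genotype counts. `find_specific_variants()` calls
a variant population-specific only when P < 5e-5 against *every* reference
panel; variants untyped in any panel are excluded by default rather than
imputed at AF 0 (conservative; configurable). A zero-margin table (both
populations fixed for the same allele) returns P = 1 by convention.

## Whole-genome-wide association

`run_gwas()` fits, per variant, trait ~ dosage + covariates by least
squares (quantitative traits, QR decomposition; the no-missing fast path
uses the Frisch-Waugh residualization and is algebraically identical to
the full fit) or logistic IRLS (binary traits, 25-iteration cap with
separation detection). Samples missing the trait or a covariate are
dropped trait-wide; samples missing a genotype are dropped for that
variant only — complete-case, never imputed. The default covariates are
sex, age, age², BMI and leading genotype principal components, with BMI
removed for BMI-derived traits (adjusting a trait for itself biases the
genetic effect toward zero). Two-sided P values come from the t (linear)
or Wald z (logistic) statistic of the dosage coefficient.

Diagnostics and post-processing: `genomic_lambda()` converts P values to
1-df chi-square quantiles and reports median/0.4549364;
`ld_clump()` performs greedy index-first clumping (sort by P; the best
unassigned variant absorbs unassigned variants within 250 kb with dosage
r² > 0.1; both P gates default to 1 so each variant lands in exactly one
clump); `bh_fdr()` wraps `p.adjust(method = "BH")`. Significance
conventions are 5e-8 (genome-wide) and 1e-5 (suggestive), both
configurable. Trait pre-screening (`screen_traits()`) drops traits
observed in under 10% of samples and binary traits with minority class
under 20% (worse than 1:4); any further rejection of traits by QQ-plot
inspection is a manual judgment and is deliberately not automated.

## Phenomics

**Phenotypic correlation.** Pairwise-complete Pearson correlation with
95% CIs by the Fisher z-transform and BH FDR across all pairs; a pair is
reported significant only when FDR < 0.05 *and* the CI excludes zero.
Constant traits and pairs with fewer than 10 complete observations are
reported NA.

**Pleiotropy and VSI.** A variant suggestively associated
(P < 1e-5) with two or more traits is pleiotropic. For a trait pair with
suggestive sets S_i and S_j, the Variant-Sharing Index is the Jaccard
index on the percentage scale,
VSI = 100·|S_i∩S_j| / |S_i∪S_j|, rounded to one decimal. The percentage
scale and one-decimal rounding match the reference tabulation this
package reproduces in its tests.

**GREML.** `build_grm()` computes the GCTA-style genetic relationship
matrix A_jk = (1/M)Σ(x_ij−2p_i)(x_ik−2p_i)/(2p_i(1−p_i)) over variants
with MAF ≥ 0.01, skipping missing dosages with per-pair adjustment of M.
`reml_h2()` and `bivariate_rg()` maximize the restricted likelihood on
the eigendecomposition of the GRM, which makes every likelihood
evaluation O(n) after one O(n³) decomposition (reusable across traits via
the `eig` argument). Variance components are kept nonnegative by box
bounds (boundary projection); convergence is declared at relative
log-likelihood change below 1e-8 within 200 (univariate) or 400
(bivariate) iterations, and a boundary flag accompanies the SE, which is
taken from the inverse observed information with a delta-method transform
to the h² scale. The genetic correlation is parameterized directly as rg
in [−0.999, 0.999] so the covariance matrix stays positive definite; the
test of rg = 0 is a 1-df likelihood-ratio test against the fit with the
genetic covariance pinned at zero, and non-convergence produces an
explicit excluded-with-reason record, never a silent NA.

The sampling SD of a GREML h² estimate is approximately
√(2/(n²·var_A)), where var_A is the variance of GRM off-diagonals
(≈ 1/M for a homogeneous unrelated cohort). `greml_power()` turns this
into analytic detection power, Φ(h²/SE − z_{1−α/2}) with two-sided
α = 0.05 and the conventional var_A = 2e-5; two-sided α is used because
it is the convention under which the published operating points this
package reproduces are exact. The same formula explains a practical point
about null simulations: at desk scale (n = 1,000, M = 2,000) the null SD
of ĥ² is ≈ 0.06, so null estimates are asserted small relative to that
analytic SD rather than against an absolute constant.

**Mendelian randomization.** Instruments are suggestive exposure variants
thinned to one per LD block (clumping at r² 0.1 / 250 kb, smallest P
kept). Three estimators are run per exposure-outcome pair:

* `mr_ivw()` — weighted slope of outcome on exposure effects through the
  origin, weights 1/se_y²; with one instrument this is the Wald ratio.
  The SE uses multiplicative random effects with the residual scale
  floored at 1, so heterogeneity inflates but never deflates it.
* `mr_egger()` — weighted regression with an intercept (≥ 3 instruments);
  exposure effects are sign-oriented positive first, which leaves the
  slope invariant and makes the intercept interpretable as directional
  pleiotropy.
* `mr_presso()` — re-implemented from the published algorithm sketch:
  the observed leave-one-out IVW residual sum of squares is compared
  against a parametric null (default 10,000 resamples of the effects
  about their leave-one-out fitted values, seeded for reproducibility);
  when the global test rejects, per-instrument tails identify outliers
  (Bonferroni), which are removed before re-running IVW
  (≥ 4 instruments).

`consensus_mr()` applies BH FDR within each method across all tested
pairs (the FDR scope is a package choice; it is the least favorable
scope for any single pair) and declares a pair causal when at least 2 of
the 3 methods reach FDR < 0.05. Direction labels compare the two
orientations of each unordered pair. In recovery simulations (chain
exposure → outcome with γ = 0.5, both traits with their own genetic
architecture at h² = 0.4), the forward direction is recovered in
essentially every replicate while the reverse survives consensus rarely —
reverse estimates mix mediated instruments (consistent nonzero slope)
with outcome-specific instruments (slope zero), producing heterogeneity
that the random-effects SE and PRESSO outlier removal absorb.

**Network.** `export_network()` assembles the multigraph: genetic
correlation and pleiotropy edges anchor the display; phenotypic
correlation and MR edges are emitted only for pairs that also carry an
anchor edge; MR edges are directed. Output is GraphML (igraph) or an
edge-list TSV.

## Imputation accuracy

`per_variant_r2()` is the squared Pearson correlation between true
genotypes and imputed dosages; constant-genotype variants are undefined
(NA, counted separately). `aggregate_by_af()` averages per-variant R²
within alternate-AF bins — the Minimac-style convention; a pooled
correlation across all calls in a bin is available behind `pooled = TRUE`.
Default bin edges 0.001, 0.005, 0.01, 0.05, 0.1, 0.2, 0.5 are
configurable since no canonical set exists. When two panels are compared,
restrict first to variants imputed by both.

## The synthetic cohort

`simulate_cohort()` produces genotypes, read counts, and traits with
known truth:

* **Genotypes** follow a Balding-Nichols model: subpopulation AFs are
  Beta-distributed around a uniform ancestral AF with variance
  fst·p(1−p), and founders are Hardy-Weinberg binomial within
  subpopulation. This is the simplest structure model with a tunable
  Fst — sufficient for testing PCA separation and structure-aware
  stages. Related individuals (parent-offspring, full siblings,
  half-sibling second-degree pairs) are appended by Mendelian gamete
  transmission from designated founders. Missing calls are injected
  uniformly (default 0.5%) so missingness filters have something to do.
* **Read counts** are Poisson(depth) with binomial allele splits; at a
  configurable fraction of variants, heterozygous calls of samples in
  the affected batch draw alternate reads at probability 0.65 instead of
  0.5. The bias is applied at heterozygous calls only, because the
  allele-balance statistic is informative only where both alleles are
  expected. The magnitude 0.65 is a free parameter of the generator, not
  an estimate of any real batch effect. Sex, age, and BMI come from
  simple parametric distributions; only their role as covariates
  matters.
* **Traits** are built from standardized causal genotypes with effects
  drawn jointly across traits under the requested genetic-correlation
  matrix; environmental noise is scaled against the realized genetic
  variance so the realized h² matches the target. With any nonzero
  off-diagonal rg the traits share one causal set — genetic correlation
  is carried by correlated effects at shared causal variants, and
  independently drawn causal sets cannot realize it. Causal trait-trait
  edges add γ·exposure to the outcome after both traits' own components
  are built.

What the generator does *not* emulate: linkage disequilibrium from a
coalescent (positions are uniformly spaced and variants independent
unless blocks are copied), realistic site-frequency spectra, sequencing
and alignment artifacts beyond the depth/allele-split model,
multi-chromosome recombination maps, and genotype-calling error modes.
Passing parameter-recovery tests on this generator therefore validates
the estimators' statistical logic, not their behavior under real LD or
calling artifacts.

## Problem sizes and runtime choices

The test suite and recovery checks run at deliberately modest sizes
chosen to make the statistical assertions sharp rather than to mimic the
original cohort: batch-filter recovery at 500 samples × 3,000 variants;
kinship at 5,000 variants; null association calibration at 500 × 10,000
over 20 replicates; GREML recovery at n = 2,000, M = 5,000 (one GRM
eigendecomposition reused across replicate trait draws); MR direction
recovery at n = 2,000, 400 variants, 20 replicates with 2,000 PRESSO
resamples. The full-size analyses scale linearly in variants for QC and
association and cubically in samples for the one-off GRM
eigendecomposition.

## Known limitations

* The truncated method-of-moments PI_HAT has a small positive tail for
  unrelated pairs at modest marker counts (see above); kinship decisions
  at a 0.05 threshold should use as many pruned common variants as
  available.
* REML standard errors at a variance-component boundary come from the
  unconstrained information matrix and are flagged; they are
  approximations there.
* MR-PRESSO is a faithful re-implementation of the published resampling
  scheme, but exact P values depend on the resample count; use the
  default 10,000 (with a seed) for reportable results.
* The pipeline's PCA-outlier and QQ-plot-based trait rejection steps are
  surfaced as parameters/diagnostics, not automated judgments.
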