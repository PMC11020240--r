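Package: kovariome
Title: Cohort Variome QC, Whole-Genome-Wide Association, and Phenomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-genotyping analysis toolkit for population-scale
    whole-genome cohorts: sample and variant quality control including an
    allele-balance batch-effect filter, method-of-moments kinship (PI_HAT)
    and unrelated-set selection, allele-frequency profiling with
    variant-discovery saturation curves, chi-square population-specificity
    testing, covariate-adjusted whole-genome-wide association with genomic
    inflation diagnostics and LD clumping, and four trait-pair phenomics
    analyses (phenotypic correlation, pleiotropy with the Variant-Sharing
    Index, GREML heritability and genetic correlation, and consensus
    Mendelian randomization with IVW, Egger, and PRESSO estimators).
    Includes a synthetic-cohort generator with ground truth for
    parameter-recovery testing and a configuration-driven pipeline driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
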