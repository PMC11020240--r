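#' Pipeline configuration
#'
#' Collects every stage threshold with the pipeline's defaults, a seed,
#' and stage toggles. Unknown keys are rejected so silent typos cannot
#' change a run.
#'
#' @param ... named overrides of the defaults listed below.
#' @return a `pipeline_config` list.
#' @details Defaults: sample missing rate 0.10; het/hom outlier band 3 SD;
#'   PI_HAT threshold 0.05; allele-balance band 1 SD; genotyping rate 0.9;
#'   association MAF floor 0.01, HWE floor 1e-6, missing ceiling 0.01;
#'   suggestive P 1e-5; genome-wide significant P 5e-8; clump r2 0.1 and
#'   window 250 kb; MR instrument P 1e-5, NbDistribution 10000, signif
#'   0.05; FDR 0.05; seed 1; stage toggles `run_profile`, `run_wgwas`,
#'   `run_phenomics` all TRUE.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    sample_max_missing = 0.10,
    het_hom_sd = 3,
    pi_hat_threshold = 0.05,
    ab_n_sd = 1,
    min_genotyping_rate = 0.9,
    assoc_maf_min = 0.01,
    assoc_hwe_min = 1e-6,
    assoc_max_missing = 0.01,
    suggestive_p = 1e-5,
    significant_p = 5e-8,
    clump_r2 = 0.1,
    clump_kb = 250,
    mr_instrument_p = 1e-5,
    mr_nb_distribution = 10000,
    mr_signif = 0.05,
    fdr = 0.05,
    n_pcs = 5,
    seed = 1,
    run_profile = TRUE,
    run_wgwas = TRUE,
    run_phenomics = TRUE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown pipeline_config keys: ", paste(unknown, collapse = ", "))
  }
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes the stages in order: sample QC (missingness, het/hom) ->
#' kinship and unrelated selection -> allele-balance batch-effect filter ->
#' genotyping-rate filter -> allele-frequency profiling -> WGWAS per trait
#' with lambda diagnostics -> phenomics (phenotypic correlation,
#' pleiotropy/VSI, GREML heritability and genetic correlation, consensus
#' MR) -> trait network. Every threshold used, the seed, and the
#' per-filter sample/variant counts are recorded in the returned manifest.
#'
#' @param genotypes a [genotype_matrix()].
#' @param read_counts list with `ref_reads`/`alt_reads`, or NULL to skip
#'   the allele-balance filter.
#' @param traits trait/covariate data.frame, or NULL to skip association
#'   stages.
#' @param trait_cols trait columns to analyze; default every non-covariate
#'   column.
#' @param config a [pipeline_config()].
#' @return a `pipeline_result` list: `manifest`, `sample_qc`,
#'   `variant_qc`, `kinship`, `unrelated`, `profile`, `gwas` (per trait),
#'   `lambda`, `phenomics` (pc/pleiotropy/h2/rg/mr/network).
#' @export
run_pipeline <- function(genotypes, read_counts = NULL, traits = NULL,
                         trait_cols = NULL, config = pipeline_config()) {
  manifest <- list(
    thresholds = unclass(config),
    n_samples_in = n_samples(genotypes),
    n_variants_in = n_variants(genotypes),
    stages = list()
  )
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }
  out <- list()

  # --- sample filters ---------------------------------------------------
  sq <- sample_qc(genotypes,
    max_missing = config$sample_max_missing, het_hom_sd = config$het_hom_sd
  )
  out$sample_qc <- sq
  keep1 <- sq$sample_id[sq$kept]
  note("sample_qc",
    removed_high_missing = sum(sq$high_missing),
    removed_het_hom = sum(sq$het_hom_outlier & !sq$high_missing),
    removed_undefined_ratio = sum(sq$ratio_undefined & !sq$high_missing &
      !sq$het_hom_outlier),
    kept = length(keep1)
  )
  g1 <- subset_genotypes(genotypes, samples = keep1)

  # --- kinship and unrelated selection ---------------------------------
  common <- which(minor_allele_freq(g1) >= config$assoc_maf_min &
    variant_missing_rate(g1) <= 0.05)
  pruned <- common[ld_prune(subset_genotypes(g1, variants = common))]
  kin_input <- subset_genotypes(g1, variants = pruned)
  out$kinship <- estimate_ibd(kin_input)
  unrelated <- select_unrelated(out$kinship, g1$sample_ids,
    threshold = config$pi_hat_threshold
  )
  out$unrelated <- unrelated
  note("kinship",
    n_pairs_related = sum(out$kinship$pi_hat > config$pi_hat_threshold),
    removed_related = length(keep1) - length(unrelated),
    kept = length(unrelated)
  )
  g2 <- subset_genotypes(g1, samples = unrelated)

  # --- allele-balance batch-effect filter ------------------------------
  ab_keep <- rep(TRUE, n_variants(g2))
  if (!is.null(read_counts)) {
    srows <- match(g2$sample_ids, genotypes$sample_ids)
    rc <- list(
      ref_reads = read_counts$ref_reads[srows, , drop = FALSE],
      alt_reads = read_counts$alt_reads[srows, , drop = FALSE]
    )
    ab <- compute_allele_balance(g2, rc)
    ab_keep <- filter_batch_effect(ab, n_sd = config$ab_n_sd)
    out$allele_balance <- ab
  }
  vq <- variant_qc(g2, ab_keep = ab_keep, min_rate = config$min_genotyping_rate)
  out$variant_qc <- vq
  note("variant_qc",
    removed_allele_balance = sum(vq$ab_excluded),
    removed_genotyping_rate = sum(!vq$ab_excluded & !vq$kept),
    kept = sum(vq$kept)
  )
  g3 <- subset_genotypes(g2, variants = which(vq$kept))

  # --- allele-frequency profile ----------------------------------------
  if (isTRUE(config$run_profile)) {
    out$profile <- af_category_table(g3)
    out$saturation <- saturation_curve(g3, out$profile$category,
      seed = config$seed
    )
    note("profile", category_counts = as.list(table(out$profile$category)))
  }

  # --- WGWAS ------------------------------------------------------------
  if (isTRUE(config$run_wgwas) && !is.null(traits)) {
    assoc_keep <- prefilter_variants(g3,
      maf_min = config$assoc_maf_min, hwe_min = config$assoc_hwe_min,
      max_missing = config$assoc_max_missing
    )
    ga <- subset_genotypes(g3, variants = which(assoc_keep))
    note("assoc_prefilter", kept = n_variants(ga),
      removed = n_variants(g3) - n_variants(ga))
    traits_a <- traits[match(ga$sample_ids, traits$sample_id), , drop = FALSE]
    if (is.null(trait_cols)) {
      trait_cols <- screen_traits(traits_a)
    }
    # covariates: sex, age, age2, bmi plus leading PCs
    pcs <- pca_genotypes(ga, n_components = min(config$n_pcs,
      n_samples(ga) - 1))$scores
    traits_a <- cbind(traits_a, as.data.frame(pcs))
    spec <- covariate_spec(columns = c("sex", "age", "age2", "bmi",
      colnames(pcs)))
    out$gwas <- list()
    out$lambda <- list()
    for (tc in trait_cols) {
      v <- traits_a[[tc]][!is.na(traits_a[[tc]])]
      model <- if (all(v %in% c(0, 1))) "logistic" else "linear"
      st <- run_gwas(ga, traits_a, tc, covariates = spec, model = model)
      out$gwas[[tc]] <- st
      out$lambda[[tc]] <- genomic_lambda(st)
    }
    note("wgwas",
      traits = trait_cols,
      lambda_median = vapply(out$lambda, `[[`, numeric(1), "lambda_median")
    )

    # --- phenomics ------------------------------------------------------
    if (isTRUE(config$run_phenomics) && length(trait_cols) >= 2) {
      out$phenomics <- list()
      out$phenomics$pc <- phenotypic_correlation(traits_a,
        trait_cols = trait_cols, fdr_threshold = config$fdr
      )
      pl <- detect_pleiotropy(out$gwas, p_threshold = config$suggestive_p)
      out$phenomics$pleiotropy <- pl
      grm <- build_grm(ga, maf_min = config$assoc_maf_min)
      out$phenomics$h2 <- lapply(trait_cols, function(tc) {
        reml_h2(grm, traits_a[[tc]],
          covariates = traits_a[, c("sex", "age", "age2", "bmi")]
        )
      })
      names(out$phenomics$h2) <- trait_cols
      heritable <- trait_cols[vapply(out$phenomics$h2, function(h) {
        isTRUE(h$significant)
      }, logical(1))]
      rg_rows <- list()
      if (length(heritable) >= 2) {
        cmb <- utils::combn(heritable, 2)
        for (cix in seq_len(ncol(cmb))) {
          t1 <- cmb[1, cix]; t2 <- cmb[2, cix]
          r <- bivariate_rg(grm, traits_a[[t1]], traits_a[[t2]],
            covariates = traits_a[, c("sex", "age", "age2", "bmi")]
          )
          rg_rows[[length(rg_rows) + 1L]] <- data.frame(
            trait_i = t1, trait_j = t2,
            rg = r$rg, p_lrt = r$p_lrt, excluded = r$excluded,
            stringsAsFactors = FALSE
          )
        }
      }
      gc_df <- if (length(rg_rows)) do.call(rbind, rg_rows) else
        data.frame(trait_i = character(0), trait_j = character(0),
          rg = numeric(0), p_lrt = numeric(0), excluded = logical(0))
      if (nrow(gc_df)) {
        gc_df$fdr <- bh_fdr(gc_df$p_lrt)
        gc_df$significant <- !is.na(gc_df$fdr) & gc_df$fdr < config$fdr
      } else {
        gc_df$fdr <- numeric(0)
        gc_df$significant <- logical(0)
      }
      out$phenomics$rg <- gc_df

      mr_results <- list()
      for (ex in trait_cols) {
        inst <- select_instruments(out$gwas[[ex]], ga,
          p_threshold = config$mr_instrument_p,
          r2 = config$clump_r2, window_kb = config$clump_kb
        )
        for (ou in setdiff(trait_cols, ex)) {
          if (length(inst) < 1) next
          mr_results[[length(mr_results) + 1L]] <- mr_pair(
            out$gwas[[ex]], out$gwas[[ou]], inst,
            nb_distribution = config$mr_nb_distribution,
            signif = config$mr_signif, seed = config$seed
          )
        }
      }
      out$phenomics$mr <- if (length(mr_results)) {
        consensus_mr(mr_results, fdr_threshold = config$fdr)
      } else NULL
      out$phenomics$network <- export_network(
        gc = gc_df, pc = out$phenomics$pc, vsi = pl$vsi,
        mr = out$phenomics$mr
      )
      note("phenomics",
        n_pc_significant = sum(out$phenomics$pc$significant, na.rm = TRUE),
        n_pleiotropic = length(pl$pleiotropic),
        n_gc_significant = sum(gc_df$significant),
        n_mr_consensus = if (is.null(out$phenomics$mr)) 0 else
          sum(out$phenomics$mr$consensus_significant)
      )
    }
  }

  out$manifest <- manifest
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("pipeline_result:", m$n_samples_in, "samples,", m$n_variants_in,
      "variants in\n")
  for (s in names(m$stages)) {
    info <- m$stages[[s]]
    flat <- vapply(info, function(v) paste(format(unlist(v)), collapse = ","),
      character(1))
    cat("  ", s, ": ", paste(names(flat), flat, sep = "=", collapse = "; "),
      "\n", sep = "")
  }
  invisible(x)
}
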