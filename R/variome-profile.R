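#' Allele-frequency category of a variant
#'
#' Partition of polymorphic variants by alternate allele count (AC) and
#' frequency (AF = AC / AN): singleton (AC = 1), doubleton (AC = 2),
#' very_rare (AC > 2 and AF <= 0.001), rare (0.001 < AF <= 0.01), common
#' (0.01 < AF <= 0.05), very_common (AF > 0.05). Boundaries are inclusive
#' on the upper end of each bin.
#'
#' @param ac alternate allele count(s), > 0.
#' @param an allele number(s) (2 x genotyped samples), >= ac.
#' @return factor with levels singleton, doubleton, very_rare, rare,
#'   common, very_common.
#' @export
classify_af <- function(ac, an) {
  stopifnot(length(ac) == length(an))
  if (any(ac <= 0 | ac > an, na.rm = TRUE)) {
    stop("require 0 < ac <= an (monomorphic variants have no category)")
  }
  af <- ac / an
  lab <- ifelse(ac == 1, "singleton",
    ifelse(ac == 2, "doubleton",
      ifelse(af <= 0.001, "very_rare",
        ifelse(af <= 0.01, "rare",
          ifelse(af <= 0.05, "common", "very_common")
        )
      )
    )
  )
  factor(lab, levels = c(
    "singleton", "doubleton", "very_rare", "rare", "common", "very_common"
  ))
}

#' Categorize all polymorphic variants of a cohort
#'
#' @param genotypes a [genotype_matrix()].
#' @return data.frame: `id`, `ac`, `an`, `af`, `category` (NA category for
#'   monomorphic variants, which are excluded from the partition).
#' @export
af_category_table <- function(genotypes) {
  dos <- genotypes$dosages
  ac <- colSums(dos, na.rm = TRUE)
  an <- 2L * colSums(!is.na(dos))
  cat <- factor(rep(NA_character_, length(ac)), levels = levels(classify_af(1, 2)))
  poly <- ac > 0 & an > 0 # alternate allele observed at a genotyped site
  cat[poly] <- classify_af(ac[poly], an[poly])
  data.frame(
    id = genotypes$variant_meta$id,
    ac = ac, an = an, af = ifelse(an > 0, ac / an, NA_real_),
    category = cat,
    stringsAsFactors = FALSE
  )
}

#' Annotate variants against a known-sites list
#'
#' Exact matching on the (chrom, pos, ref, alt) key; also reports the known
#' fraction per allele-frequency category.
#'
#' @param variants data.frame with `id` keys (as produced by
#'   [af_category_table()], with `category`) or a [genotype_matrix()].
#' @param known_sites character vector of known keys `chrom:pos:ref:alt`,
#'   or a data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @return the variant table with a logical `known` column; attribute
#'   `known_fraction` holds the per-category known fraction.
#' @export
annotate_novelty <- function(variants, known_sites) {
  if (inherits(variants, "genotype_matrix")) {
    variants <- af_category_table(variants)
  }
  if (is.data.frame(known_sites)) {
    known_sites <- variant_key(known_sites)
  }
  variants$known <- variants$id %in% known_sites
  frac <- tapply(variants$known, variants$category, mean)
  attr(variants, "known_fraction") <- frac
  variants
}

#' Variant-discovery saturation curves by AF category
#'
#' For each of `n_permutations` random sample orderings, counts the
#' cumulative number of distinct variants of each (full-cohort) category
#' discovered — i.e., carried as a non-reference allele — by the first k
#' samples. Curves are averaged over permutations; the per-category
#' saturation point (smallest k reaching the category total) is reported
#' per permutation and as a median.
#'
#' @param genotypes a [genotype_matrix()].
#' @param categories optional factor from [af_category_table()]; computed
#'   if missing.
#' @param n_permutations number of random orderings, default 10.
#' @param seed random seed, default 1.
#' @return a `saturation_curve` list: `mean_curve` (n_samples x categories
#'   matrix of average cumulative counts), `n_saturate` (per permutation x
#'   category), `n_saturate_median`, `category_totals`.
#' @export
saturation_curve <- function(genotypes, categories = NULL, n_permutations = 10,
                             seed = 1) {
  if (is.null(categories)) categories <- af_category_table(genotypes)$category
  dos <- genotypes$dosages
  n <- nrow(dos)
  carrier <- !is.na(dos) & dos > 0
  lev <- levels(categories)
  use <- !is.na(categories)
  totals <- table(categories[use])
  set.seed(seed)
  curves <- array(0, c(n, length(lev), n_permutations),
    dimnames = list(NULL, lev, NULL)
  )
  n_sat <- matrix(NA_integer_, n_permutations, length(lev),
    dimnames = list(NULL, lev)
  )
  for (pm in seq_len(n_permutations)) {
    ord <- sample.int(n)
    rank_of <- integer(n)
    rank_of[ord] <- seq_len(n)
    # first-discovery position of each variant = min rank among carriers
    first <- apply(carrier, 2, function(col) {
      w <- which(col)
      if (!length(w)) NA_integer_ else min(rank_of[w])
    })
    for (l in seq_along(lev)) {
      f <- first[use & categories == lev[l] & !is.na(first)]
      cum <- cumsum(tabulate(f, nbins = n))
      curves[, l, pm] <- cum
      tot <- totals[lev[l]]
      if (!is.na(tot) && tot > 0 && any(cum == tot)) {
        n_sat[pm, l] <- min(which(cum == tot))
      }
    }
  }
  structure(
    list(
      mean_curve = apply(curves, c(1, 2), mean),
      curves = curves,
      n_saturate = n_sat,
      n_saturate_median = apply(n_sat, 2, stats::median),
      category_totals = totals,
      n_permutations = n_permutations, seed = seed
    ),
    class = "saturation_curve"
  )
}

#' @export
print.saturation_curve <- function(x, ...) {
  cat("saturation_curve over", nrow(x$mean_curve), "samples,",
      x$n_permutations, "permutations\n")
  cat("category totals:\n")
  print(x$category_totals)
  cat("median saturation sample count:\n")
  print(x$n_saturate_median)
  invisible(x)
}
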