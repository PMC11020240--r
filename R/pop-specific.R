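#' Pearson chi-square test on allele counts of two populations
#'
#' 2x2 table (alternate/reference alleles by population), Pearson statistic
#' without continuity correction, 1 df; vectorized over variants. A table
#' with a zero margin (both populations fixed for the same allele) is
#' maximally compatible with equality and returns P = 1.
#'
#' @param ac1,an1 alternate allele count and allele number in population 1.
#' @param ac2,an2 same for population 2.
#' @return data.frame with `chi2` and `p`.
#' @export
chi2_allele_test <- function(ac1, an1, ac2, an2) {
  stopifnot(all(an1 > 0), all(an2 > 0), all(ac1 >= 0), all(ac2 >= 0),
            all(ac1 <= an1), all(ac2 <= an2))
  a <- as.numeric(ac1); b <- as.numeric(an1 - ac1)
  c <- as.numeric(ac2); d <- as.numeric(an2 - ac2)
  n <- as.numeric(an1) + as.numeric(an2)
  # Pearson chi-square for a 2x2 table: n (ad - bc)^2 / (r1 r2 c1 c2)
  r1 <- an1; r2 <- an2; c1 <- a + c; c2 <- b + d
  denom <- as.numeric(r1) * r2 * c1 * c2
  chi2 <- ifelse(denom == 0, 0, n * (a * d - b * c)^2 / denom)
  p <- ifelse(denom == 0, 1, stats::pchisq(chi2, df = 1, lower.tail = FALSE))
  data.frame(chi2 = chi2, p = p)
}

#' Population allele-frequency table
#'
#' @param population population label.
#' @param id variant keys.
#' @param alt_count per-variant alternate allele counts.
#' @param total_count per-variant allele numbers.
#' @return a `population_af_table` data.frame.
#' @export
population_af_table <- function(population, id, alt_count, total_count) {
  stopifnot(all(alt_count >= 0), all(alt_count <= total_count))
  if (any(total_count %% 2 != 0)) {
    warning("odd total allele counts (expected even for diploid samples)")
  }
  structure(
    data.frame(
      population = population, id = id,
      alt_count = alt_count, total_count = total_count,
      stringsAsFactors = FALSE
    ),
    class = c("population_af_table", "data.frame")
  )
}

#' Find population-specific variants by chi-square against reference panels
#'
#' A variant is specific to the target population iff the allele-count
#' chi-square P value is below `alpha` against every reference population.
#' Variants missing from any reference panel are not testable against the
#' full panel and are excluded (configurable).
#'
#' @param target a [population_af_table()] for the target population.
#' @param references list of [population_af_table()]s.
#' @param alpha per-test significance threshold, default 5e-5.
#' @param drop_untyped drop variants missing from any reference (default
#'   TRUE); when FALSE, a variant only needs significance against the
#'   references in which it is typed.
#' @return data.frame with per-reference P values (`p_<population>`),
#'   `n_tested`, and logical `specific`.
#' @export
find_specific_variants <- function(target, references, alpha = 5e-5,
                                   drop_untyped = TRUE) {
  out <- data.frame(id = target$id, stringsAsFactors = FALSE)
  n_sig <- rep(0L, nrow(target))
  n_tested <- rep(0L, nrow(target))
  for (ref in references) {
    m <- match(target$id, ref$id)
    has <- !is.na(m)
    p <- rep(NA_real_, nrow(target))
    if (any(has)) {
      res <- chi2_allele_test(
        target$alt_count[has], target$total_count[has],
        ref$alt_count[m[has]], ref$total_count[m[has]]
      )
      p[has] <- res$p
    }
    out[[paste0("p_", ref$population[1])]] <- p
    n_tested <- n_tested + has
    n_sig <- n_sig + (has & !is.na(p) & p < alpha)
  }
  out$n_tested <- n_tested
  out$specific <- if (drop_untyped) {
    n_tested == length(references) & n_sig == length(references)
  } else {
    n_tested > 0 & n_sig == n_tested
  }
  if (!any(n_tested > 0)) warning("no variants shared with any reference panel")
  out
}
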