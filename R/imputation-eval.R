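#' Per-variant imputation accuracy (squared Pearson correlation)
#'
#' R-squared between true genotypes (0/1/2) and imputed dosages in \[0, 2\]
#' per variant. Variants with a constant true genotype (or constant
#' dosage) have undefined correlation and return NA; they are counted but
#' excluded from aggregation.
#'
#' @param true_genotypes samples x variants matrix of true genotypes.
#' @param dosages samples x variants matrix of imputed dosages.
#' @return numeric vector of per-variant R-squared (NA where undefined).
#' @export
per_variant_r2 <- function(true_genotypes, dosages) {
  stopifnot(all(dim(true_genotypes) == dim(dosages)))
  if (any(dosages < 0 | dosages > 2, na.rm = TRUE)) {
    stop("dosages must lie in [0, 2]")
  }
  vapply(seq_len(ncol(dosages)), function(j) {
    g <- true_genotypes[, j]
    d <- dosages[, j]
    ok <- !is.na(g) & !is.na(d)
    if (sum(ok) < 2 || stats::sd(g[ok]) == 0 || stats::sd(d[ok]) == 0) {
      return(NA_real_)
    }
    stats::cor(g[ok], d[ok])^2
  }, numeric(1))
}

#' Aggregate imputation accuracy by allele-frequency bin
#'
#' Mean of per-variant R-squared within bins of the panel alternate-allele
#' frequency (the Minimac-style aggregation). A pooled-correlation mode is
#' available behind `pooled = TRUE`. When comparing panels, restrict first
#' to the variants imputed by both.
#'
#' @param r2 per-variant R-squared from [per_variant_r2()].
#' @param panel_af per-variant alternate-allele frequency used for binning.
#' @param bin_edges increasing breakpoints inside (0, 1); bins are
#'   (0, e1\], (e1, e2\], ..., (ek, 1).
#' @param pooled if TRUE, `r2` must instead be a list with matrices
#'   `true_genotypes` and `dosages`, and the per-bin value is the squared
#'   correlation pooled over all calls in the bin.
#' @return data.frame: `bin`, `lo`, `hi`, `mean_r2`, `n_variants`
#'   (NA mean with count 0 for empty bins; undefined-R2 variants counted
#'   separately in `n_undefined`).
#' @export
aggregate_by_af <- function(r2, panel_af,
                            bin_edges = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.2, 0.5),
                            pooled = FALSE) {
  stopifnot(all(diff(bin_edges) > 0), all(bin_edges > 0), all(bin_edges < 1))
  breaks <- c(0, bin_edges, 1)
  if (pooled) {
    tg <- r2$true_genotypes
    ds <- r2$dosages
    stopifnot(ncol(tg) == length(panel_af))
  } else {
    stopifnot(length(r2) == length(panel_af))
  }
  bin <- cut(panel_af, breaks = breaks, include.lowest = FALSE)
  out <- lapply(seq_len(length(breaks) - 1), function(b) {
    inb <- !is.na(bin) & as.integer(bin) == b
    if (pooled) {
      g <- as.vector(tg[, inb, drop = FALSE])
      d <- as.vector(ds[, inb, drop = FALSE])
      ok <- !is.na(g) & !is.na(d)
      val <- if (sum(ok) < 2 || stats::sd(g[ok]) == 0 || stats::sd(d[ok]) == 0) {
        NA_real_
      } else {
        stats::cor(g[ok], d[ok])^2
      }
      data.frame(
        bin = levels(bin)[b], lo = breaks[b], hi = breaks[b + 1],
        mean_r2 = val, n_variants = sum(inb), n_undefined = NA_integer_
      )
    } else {
      vals <- r2[inb]
      data.frame(
        bin = levels(bin)[b], lo = breaks[b], hi = breaks[b + 1],
        mean_r2 = if (any(!is.na(vals))) mean(vals, na.rm = TRUE) else NA_real_,
        n_variants = sum(inb), n_undefined = sum(is.na(vals))
      )
    }
  })
  do.call(rbind, out)
}
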