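#' Remove outlier samples of one phenotype by mean inter-sample correlation
#'
#' For every sample of the given phenotype, the Pearson correlation of its
#' expression profile with each other sample of the same phenotype is
#' computed, and the per-sample mean of these coefficients taken. Samples
#' whose mean lies strictly outside `sd_multiple` standard deviations of the
#' mean of the per-sample means (both computed over all samples of the
#' phenotype) are removed. The rule is applied in a single pass, on the
#' intensities as provided. A zero-variance sample, for which the
#' correlation is undefined, is reported and removed as an outlier.
#'
#' Pearson correlation is invariant under positive affine maps, so the
#' decision does not change when all samples are rescaled by a common
#' positive factor.
#'
#' @param x feature-by-sample numeric matrix.
#' @param labels named character vector, sample id -> phenotype.
#' @param phenotype phenotype whose samples are screened.
#' @param sd_multiple width of the retention band in standard deviations
#'   (default 2).
#' @return list with elements
#'   \describe{
#'     \item{x}{the matrix with removed samples dropped (other phenotypes
#'       untouched),}
#'     \item{report}{a list: `phenotype`, `per_sample_mean_corr` (named
#'       numeric; `NA` for zero-variance samples), `center`, `spread`,
#'       `removed` (character vector of sample ids).}
#'   }
#' @examples
#' sim <- simulate_reo_cohort(n_features = 40, n_control = 10, n_case = 5,
#'                            n_stable_pairs = 5, n_reversed_pairs = 2,
#'                            noise_sd = 20, outlier_samples = 1, seed = 7)
#' qc <- remove_outliers(sim$x, sim$labels, "control")
#' qc$report$removed
#' @export
remove_outliers <- function(x, labels, phenotype, sd_multiple = 2) {
  validate_expression(x)
  validate_labels(x, labels)
  ids <- names(labels)[labels == phenotype]
  if (length(ids) == 0L) stop("no samples labeled '", phenotype, "'")
  if (length(ids) < 3L)
    stop("need at least 3 samples of phenotype '", phenotype,
         "' to screen outliers")
  sub <- x[, ids, drop = FALSE]
  sds <- apply(sub, 2L, stats::sd)
  cc <- suppressWarnings(stats::cor(sub))
  diag(cc) <- NA_real_
  mean_corr <- colMeans(cc, na.rm = TRUE)
  mean_corr[sds == 0] <- NA_real_   # correlation undefined
  center <- mean(mean_corr, na.rm = TRUE)
  spread <- stats::sd(mean_corr, na.rm = TRUE)
  out <- is.na(mean_corr)
  if (!is.na(spread))
    out <- out | (!is.na(mean_corr) & abs(mean_corr - center) > sd_multiple * spread)
  removed <- ids[out]
  list(x = x[, setdiff(colnames(x), removed), drop = FALSE],
       report = list(phenotype = phenotype,
                     per_sample_mean_corr = mean_corr,
                     center = center,
                     spread = spread,
                     removed = removed))
}
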