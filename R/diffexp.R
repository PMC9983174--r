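#' Per-feature two-group differential expression
#'
#' Two-sample t-test for every feature between two phenotypes, with
#' Benjamini-Hochberg adjustment over all tested features. The classic
#' equal-variance Student's t-test is the default; set `var_equal = FALSE`
#' for Welch. Tests run on the intensities as provided unless
#' `log2 = TRUE`, which applies `log2(x + 1)` first.
#'
#' A feature with zero variance in both groups has an undefined test
#' statistic; it is reported with `t = NA` and `p = 1`.
#'
#' @param x feature-by-sample numeric matrix.
#' @param labels named character vector, sample id -> phenotype.
#' @param label_a,label_b the two phenotypes compared (means reported in
#'   this order; `t > 0` means higher in `label_a`).
#' @param fdr FDR threshold for the `significant` flag (default 0.05).
#' @param var_equal pooled-variance Student's t (`TRUE`, default) or Welch.
#' @param log2 test on `log2(x + 1)` instead of raw intensities.
#' @return data frame with columns `feature_id`, `mean_a`, `mean_b`, `t`,
#'   `p`, `q`, `significant`, sorted by `q` then feature id.
#' @export
diff_expression <- function(x, labels, label_a, label_b, fdr = 0.05,
                            var_equal = TRUE, log2 = FALSE) {
  validate_expression(x)
  validate_labels(x, labels)
  ga <- names(labels)[labels == label_a]
  gb <- names(labels)[labels == label_b]
  if (length(ga) < 2L || length(gb) < 2L)
    stop("need at least 2 samples per group")
  xa <- x[, ga, drop = FALSE]
  xb <- x[, gb, drop = FALSE]
  if (log2) { xa <- log2(xa + 1); xb <- log2(xb + 1) }
  n <- nrow(x)
  tstat <- rep(NA_real_, n)
  pval <- rep(1, n)
  for (i in seq_len(n)) {
    va <- xa[i, ]; vb <- xb[i, ]
    if (stats::sd(va) == 0 && stats::sd(vb) == 0) next  # p undefined -> 1
    tt <- stats::t.test(va, vb, var.equal = var_equal)
    tstat[i] <- unname(tt$statistic)
    pval[i] <- tt$p.value
  }
  res <- data.frame(feature_id = rownames(x),
                    mean_a = rowMeans(xa), mean_b = rowMeans(xb),
                    t = tstat, p = pval, q = bh_adjust(pval),
                    stringsAsFactors = FALSE)
  res$significant <- res$q < fdr
  res <- res[order(res$q, res$feature_id, method = "radix"), ]
  rownames(res) <- NULL
  res
}
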