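## Pair screening: stable pairs in controls, reversal tests in cases.
##
## All pair enumeration is lexicographic by feature id (C-locale radix
## order), which fixes the deterministic "natural order" used downstream.

#' Count, for every ordered feature pair, samples where a exceeds b
#'
#' Returns the integer matrix `C` with `C[a, b]` = number of the given
#' samples in which `value(a) > value(b)` strictly. Evaluation is blocked
#' over feature rows so that the full pairs-by-samples boolean array is
#' never materialized.
#'
#' @noRd
pair_greater_counts <- function(x, samples = colnames(x), block = 256L) {
  sub <- x[, samples, drop = FALSE]
  n <- nrow(sub)
  counts <- matrix(0L, n, n, dimnames = list(rownames(sub), rownames(sub)))
  for (start in seq.int(1L, n, by = block)) {
    ii <- start:min(start + block - 1L, n)
    acc <- matrix(0L, length(ii), n)
    for (s in seq_len(ncol(sub)))
      acc <- acc + outer(sub[ii, s], sub[, s], ">")
    counts[ii, ] <- acc
  }
  counts
}

#' Lexicographic (C-locale) feature order
#' @noRd
lex_features <- function(x) {
  rownames(x)[order(rownames(x), method = "radix")]
}

#' Fraction of samples in which one feature exceeds another
#'
#' The within-sample relative expression ordering (REO) statistic
#' \eqn{P(E_a > E_b) = k/m}: `k` samples of the subset show
#' `value(a) > value(b)` strictly out of `m`. Ties (exact equality) count on
#' the `<=` side.
#'
#' @param x feature-by-sample numeric matrix.
#' @param a,b feature ids (rownames of `x`), `a != b`.
#' @param samples sample ids to use (default: all columns).
#' @return fraction in `[0, 1]`.
#' @export
pair_fraction <- function(x, a, b, samples = colnames(x)) {
  validate_expression(x)
  if (!a %in% rownames(x)) stop("unknown feature: ", a)
  if (!b %in% rownames(x)) stop("unknown feature: ", b)
  if (length(samples) == 0L) stop("empty sample subset")
  if (!all(samples %in% colnames(x)))
    stop("unknown sample id(s) in subset")
  mean(x[a, samples] > x[b, samples])
}

#' Find pairs with a stable ordering in a reference phenotype
#'
#' Enumerates all `n(n-1)` ordered pairs (a, b) of features and keeps those
#' whose ordering `E_a > E_b` holds in at least `stability_threshold` of the
#' samples carrying `control_label`. Output rows are in lexicographic order
#' by (a, b).
#'
#' @param x feature-by-sample numeric matrix.
#' @param labels named character vector, sample id -> phenotype.
#' @param control_label phenotype defining the reference ordering.
#' @param stability_threshold minimal holding fraction, in (0.5, 1]
#'   (default 0.95).
#' @return data frame with columns `a`, `b`, `n1` (samples with a > b),
#'   `p_control` (= n1 / m).
#' @export
find_stable_pairs <- function(x, labels, control_label,
                              stability_threshold = 0.95) {
  validate_expression(x)
  validate_labels(x, labels)
  if (stability_threshold <= 0.5 || stability_threshold > 1)
    stop("stability_threshold must be in (0.5, 1]")
  ctrl <- names(labels)[labels == control_label]
  if (length(ctrl) < 2L)
    stop("need at least 2 samples labeled '", control_label, "'")
  feats <- lex_features(x)
  counts <- pair_greater_counts(x[feats, , drop = FALSE], ctrl)
  m <- length(ctrl)
  stable <- counts >= stability_threshold * m - 1e-9
  diag(stable) <- FALSE
  idx <- which(t(stable))          # row-major => lexicographic (a, b)
  n <- length(feats)
  ai <- (idx - 1L) %/% n + 1L
  bi <- (idx - 1L) %% n + 1L
  n1 <- counts[cbind(ai, bi)]
  data.frame(a = feats[ai], b = feats[bi], n1 = n1, p_control = n1 / m,
             stringsAsFactors = FALSE)
}

#' Two-sided Fisher's exact test p-value for REO reversal
#'
#' Exact two-sided p-value for the 2x2 contingency table
#' `[[n1, n2], [m1, m2]]` of ordering counts (`n1`/`n2`: control samples
#' with `a > b` / `a <= b`; `m1`/`m2`: same in cases). The p-value is the
#' total hypergeometric probability of all tables with the observed margins
#' whose point probability does not exceed that of the observed table (the
#' convention of [stats::fisher.test()], including its relative tolerance).
#' Vectorized over the four count vectors; repeated tables are computed
#' once, which matters when screening millions of pairs that share group
#' sizes.
#'
#' @param n1,n2,m1,m2 non-negative integer vectors of equal length (or
#'   length 1, recycled).
#' @return numeric vector of p-values in `[0, 1]`.
#' @examples
#' fisher_reversal_p(10, 0, 0, 10)   # 2 / choose(20, 10)
#' fisher_reversal_p(5, 5, 5, 5)     # 1
#' @export
fisher_reversal_p <- function(n1, n2, m1, m2) {
  len <- max(length(n1), length(n2), length(m1), length(m2))
  n1 <- rep_len(as.integer(n1), len); n2 <- rep_len(as.integer(n2), len)
  m1 <- rep_len(as.integer(m1), len); m2 <- rep_len(as.integer(m2), len)
  if (anyNA(c(n1, n2, m1, m2)) || any(c(n1, n2, m1, m2) < 0))
    stop("counts must be non-negative integers")
  key <- paste(n1, n2, m1, m2)
  uniq <- !duplicated(key)
  pu <- vapply(which(uniq), function(i)
    fisher_2x2(n1[i], n2[i], m1[i], m2[i]), numeric(1))
  unname(pu[match(key, key[uniq])])
}

#' @noRd
fisher_2x2 <- function(n1, n2, m1, m2) {
  r1 <- n1 + n2; r2 <- m1 + m2; c1 <- n1 + m1; c2 <- n2 + m2
  if (r1 == 0L || r2 == 0L || c1 == 0L || c2 == 0L) return(1)
  support <- max(0L, c1 - r2):min(r1, c1)
  d <- stats::dhyper(support, r1, r2, c1)
  min(1, sum(d[d <= d[support == n1] * (1 + 1e-7)]))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment over the supplied family
#' (a validating wrapper around [stats::p.adjust()] with `method = "BH"`).
#' Output order matches input order; adjusted values satisfy
#' `q >= p` and `q <= 1`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Screen candidate reversed pairs between two phenotypes
#'
#' Full screening pass: find pairs stable in the control phenotype, test
#' each for reversal in the case phenotype with Fisher's exact test, adjust
#' over exactly the stable-pair family with Benjamini-Hochberg, and keep
#' pairs with `q_value < fdr` and reversal degree
#' \eqn{\Delta P = P_{control} - P_{case} \ge} `delta_p_threshold`.
#' \eqn{\Delta P = 1} means the ordering `a > b` holds in every control
#' sample and in no case sample (complete reversal).
#'
#' @param x feature-by-sample numeric matrix (after any QC).
#' @param labels named character vector, sample id -> phenotype.
#' @param control_label,case_label the two phenotypes screened.
#' @param stability_threshold minimal control holding fraction (default 0.95).
#' @param fdr BH false discovery rate cutoff (default 0.05).
#' @param delta_p_threshold minimal \eqn{\Delta P}, inclusive (default 1,
#'   i.e. complete reversal; 0.7 is the usual choice when contrasting a case
#'   against heterogeneous other-disease controls).
#' @param keep_all if `TRUE`, return every stable pair with its test results
#'   instead of only the candidates (filtering columns retained).
#' @return data frame with columns `a`, `b`, `n1`, `n2`, `m1`, `m2`,
#'   `p_control`, `p_case`, `delta_p`, `p_value`, `q_value`, sorted by
#'   decreasing `delta_p` with lexicographic (a, b) tie-break. Attributes
#'   `n_stable` and `n_reversed` carry the stage counts (stable pairs;
#'   stable pairs significant at the FDR before the \eqn{\Delta P} filter).
#' @export
screen_candidates <- function(x, labels, control_label, case_label,
                              stability_threshold = 0.95, fdr = 0.05,
                              delta_p_threshold = 1, keep_all = FALSE) {
  validate_expression(x)
  validate_labels(x, labels)
  ctrl <- names(labels)[labels == control_label]
  case <- names(labels)[labels == case_label]
  if (length(ctrl) < 2L) stop("need >= 2 samples labeled '", control_label, "'")
  if (length(case) < 1L) stop("no samples labeled '", case_label, "'")

  stable <- find_stable_pairs(x, labels, control_label, stability_threshold)
  n_ctrl <- length(ctrl); n_case <- length(case)
  if (nrow(stable) == 0L) {
    res <- data.frame(a = character(), b = character(),
                      n1 = integer(), n2 = integer(),
                      m1 = integer(), m2 = integer(),
                      p_control = numeric(), p_case = numeric(),
                      delta_p = numeric(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE)
    attr(res, "n_stable") <- 0L
    attr(res, "n_reversed") <- 0L
    return(res)
  }

  feats <- lex_features(x)
  case_counts <- pair_greater_counts(x[feats, , drop = FALSE], case)
  m1 <- case_counts[cbind(match(stable$a, feats), match(stable$b, feats))]

  res <- data.frame(a = stable$a, b = stable$b,
                    n1 = stable$n1, n2 = n_ctrl - stable$n1,
                    m1 = m1, m2 = n_case - m1,
                    p_control = stable$p_control,
                    p_case = m1 / n_case,
                    stringsAsFactors = FALSE)
  res$delta_p <- res$p_control - res$p_case
  res$p_value <- fisher_reversal_p(res$n1, res$n2, res$m1, res$m2)
  res$q_value <- bh_adjust(res$p_value)

  n_stable <- nrow(res)
  n_reversed <- sum(res$q_value < fdr)
  if (!keep_all)
    res <- res[res$q_value < fdr & res$delta_p >= delta_p_threshold - 1e-12, ,
               drop = FALSE]
  res <- res[order(-res$delta_p, res$a, res$b, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_stable") <- n_stable
  attr(res, "n_reversed") <- n_reversed
  res
}

#' Write screening results as TSV
#'
#' @param screen data frame from [screen_candidates()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screen_results <- function(screen, path) {
  out <- screen[, c("a", "b", "n1", "n2", "m1", "m2", "p_control",
                    "p_case", "delta_p", "p_value", "q_value")]
  names(out)[1:2] <- c("pair_a", "pair_b")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
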