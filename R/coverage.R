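## Greedy maximum-sample-coverage combinations and activity scoring.
##
## A training sample is "covered" by a pair when the pair shows the
## reference pattern on it: a > b for a control-labeled sample, a <= b for a
## case-labeled sample. Candidate order (row order of the candidates data
## frame) is the tie-break everywhere, so the whole module is deterministic.

#' Coverage indicator matrix: candidates x samples
#' @noRd
coverage_matrix <- function(candidates, x, labels, control_label, case_label) {
  ids <- names(labels)[labels %in% c(control_label, case_label)]
  if (length(ids) == 0L) stop("no samples carry the two phenotypes")
  miss <- setdiff(unique(c(candidates$a, candidates$b)), rownames(x))
  if (length(miss))
    stop("candidate feature(s) absent from matrix: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  gt <- x[candidates$a, ids, drop = FALSE] > x[candidates$b, ids, drop = FALSE]
  is_case <- labels[ids] == case_label
  gt[, is_case] <- !gt[, is_case, drop = FALSE]
  dimnames(gt) <- list(NULL, ids)
  gt
}

#' Does a pair show the reference pattern on one labeled sample?
#'
#' The reference pattern is `value(a) > value(b)` when the sample is
#' control-labeled and `value(a) <= value(b)` (ties included) when it is
#' case-labeled.
#'
#' @param values named numeric vector, one sample's expression.
#' @param pair character vector `c(a, b)` of feature ids.
#' @param label the sample's phenotype.
#' @param control_label,case_label phenotype names.
#' @return logical scalar.
#' @export
sample_covered <- function(values, pair, label, control_label, case_label) {
  if (!all(pair %in% names(values)))
    stop("pair feature(s) absent from sample vector")
  if (!label %in% c(control_label, case_label))
    stop("sample label '", label, "' is neither control nor case")
  gt <- values[[pair[1L]]] > values[[pair[2L]]]
  if (label == control_label) gt else !gt
}

#' Training-sample coverage of a pair combination
#'
#' Fraction of all training samples (both phenotypes) on which at least one
#' member pair exhibits the reference pattern.
#'
#' @param members data frame with columns `a`, `b` (one row per pair).
#' @param x feature-by-sample numeric matrix.
#' @param labels named character vector, sample id -> phenotype.
#' @param control_label,case_label phenotype names.
#' @return fraction in `[0, 1]`.
#' @export
combination_coverage <- function(members, x, labels, control_label,
                                 case_label) {
  if (NROW(members) == 0L) stop("empty member list")
  cov <- coverage_matrix(members, x, labels, control_label, case_label)
  mean(colSums(cov) > 0L)
}

#' Grow the maximum-sample-coverage combination for a seed pair
#'
#' Greedy forward search: starting from the seed alone, every remaining
#' candidate is tentatively added and the candidate yielding the largest
#' strict increase in sample coverage joins the combination; growth stops at
#' the first round in which no addition increases coverage. Ties are broken
#' by candidate order (first row wins).
#'
#' @param seed row index into `candidates`, or a character vector
#'   `c(a, b)` identifying the seed pair (must be a candidate).
#' @param candidates data frame with columns `a`, `b`.
#' @inheritParams combination_coverage
#' @return object of class `"coverage_combination"`: list with `seed` (row
#'   index), `members` (data frame, seed first, in order of addition),
#'   `coverage` (final fraction) and `history` (coverage after each
#'   addition; strictly increasing).
#' @export
grow_combination <- function(seed, candidates, x, labels, control_label,
                             case_label) {
  if (is.character(seed)) {
    idx <- which(candidates$a == seed[1L] & candidates$b == seed[2L])
    if (length(idx) != 1L) stop("seed pair is not a candidate")
    seed <- idx
  }
  seed <- as.integer(seed)
  if (seed < 1L || seed > nrow(candidates)) stop("seed index out of range")
  cov <- coverage_matrix(candidates, x, labels, control_label, case_label)
  grow_combination_impl(seed, cov, candidates)
}

#' Greedy growth on a precomputed coverage matrix
#' @noRd
grow_combination_impl <- function(seed, cov, candidates) {
  n_samples <- ncol(cov)
  members <- seed
  covered <- cov[seed, ]
  history <- sum(covered) / n_samples
  remaining <- setdiff(seq_len(nrow(cov)), seed)
  while (length(remaining)) {
    gains <- if (length(remaining) == 1L)
      sum(cov[remaining, ] & !covered)
    else
      rowSums(cov[remaining, , drop = FALSE][, !covered, drop = FALSE])
    best <- which.max(gains)                 # first max: candidate-order tie-break
    if (gains[best] <= 0L) break
    pick <- remaining[best]
    members <- c(members, pick)
    covered <- covered | cov[pick, ]
    history <- c(history, sum(covered) / n_samples)
    remaining <- setdiff(remaining, pick)
  }
  structure(list(seed = seed,
                 members = candidates[members, c("a", "b"), drop = FALSE],
                 member_index = members,
                 coverage = history[length(history)],
                 history = history),
            class = "coverage_combination")
}

#' @export
print.coverage_combination <- function(x, ...) {
  cat("Maximum-sample-coverage combination\n")
  cat("  seed pair : (", x$members$a[1L], ", ", x$members$b[1L], ")\n", sep = "")
  cat("  members   : ", nrow(x$members), "\n", sep = "")
  cat("  coverage  : ", sprintf("%.4f", x$coverage), "\n", sep = "")
  invisible(x)
}

#' Activity scores of candidate pairs
#'
#' Grows one maximum-sample-coverage combination per candidate (each
#' candidate acting as seed) and scores every candidate by the number of
#' combinations in which it occurs. Each candidate belongs at least to its
#' own combination, so scores lie in `[1, n_candidates]`. The ranking is by
#' decreasing score, ties broken by candidate order.
#'
#' @inheritParams grow_combination
#' @return data frame with columns `a`, `b`, `score`, sorted by the
#'   ranking; attribute `combinations` holds the list of
#'   `coverage_combination` objects in seed order.
#' @export
activity_scores <- function(candidates, x, labels, control_label, case_label) {
  if (NROW(candidates) == 0L) stop("no candidates")
  cov <- coverage_matrix(candidates, x, labels, control_label, case_label)
  n <- nrow(candidates)
  combos <- vector("list", n)
  score <- integer(n)
  for (s in seq_len(n)) {
    combos[[s]] <- grow_combination_impl(s, cov, candidates)
    idx <- combos[[s]]$member_index
    score[idx] <- score[idx] + 1L
  }
  ord <- order(-score, seq_len(n), method = "radix")
  ranking <- data.frame(a = candidates$a[ord], b = candidates$b[ord],
                        score = score[ord], stringsAsFactors = FALSE)
  attr(ranking, "combinations") <- combos
  ranking
}

#' Select the final panel by the geometric mean of NPV and PPV
#'
#' For `k = 1..n` the top-`k` pairs of the activity ranking form a
#' majority-vote model which is evaluated on the training samples; the panel
#' returned is the smallest `k` whose geometric mean `sqrt(NPV * PPV)`
#' attains the global maximum of the curve. A predictive value undefined
#' because its predicted class is empty enters the geometric mean as 0.
#'
#' @param ranking data frame from [activity_scores()] (columns `a`, `b`,
#'   in ranked order).
#' @inheritParams combination_coverage
#' @param vote_threshold optional integer vote threshold passed to every
#'   candidate model; default `NULL` uses the strict-majority default
#'   `floor(k / 2)` for each `k`.
#' @return list with `model` (a [voting_model()]) and `curve` (data frame
#'   `k`, `ppv`, `npv`, `geometric_mean`, `acc`).
#' @export
select_top_k <- function(ranking, x, labels, control_label, case_label,
                         vote_threshold = NULL) {
  if (NROW(ranking) == 0L) stop("empty ranking")
  ids <- names(labels)[labels %in% c(control_label, case_label)]
  truth <- labels[ids]
  n <- nrow(ranking)
  curve <- data.frame(k = seq_len(n), ppv = NA_real_, npv = NA_real_,
                      geometric_mean = NA_real_, acc = NA_real_)
  models <- vector("list", n)
  for (k in seq_len(n)) {
    thr <- if (is.null(vote_threshold)) k %/% 2L else min(vote_threshold, k - 1L)
    models[[k]] <- voting_model(ranking[seq_len(k), c("a", "b")],
                                control_label, case_label,
                                vote_threshold = thr)
    pred <- predict(models[[k]], x[, ids, drop = FALSE])
    met <- evaluate_predictions(pred, truth, case_label)
    curve$ppv[k] <- met$ppv
    curve$npv[k] <- met$npv
    curve$geometric_mean[k] <- met$geometric_mean
    curve$acc[k] <- met$acc
  }
  best <- which.max(curve$geometric_mean)   # first k at the global maximum
  list(model = models[[best]], curve = curve)
}
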