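#' Construct a majority-vote REO panel model
#'
#' A panel of ordered feature pairs plus an integer vote threshold. For a
#' sample, every pair with `value(a) > value(b)` (the control reference
#' pattern; ties count as `<=`) contributes one control vote; the sample is
#' called `control_label` iff the vote count strictly exceeds
#' `vote_threshold`, else `case_label`.
#'
#' The default threshold `floor(n_pairs / 2)` is a strict majority: a
#' 32-pair panel calls control only on more than 16 control-pattern votes,
#' so a 16-vote sample is a case. Published rules are sometimes stricter
#' (e.g. a 5-pair panel calling control only on more than 3 votes); pass
#' `vote_threshold = 3` to reproduce that behavior.
#'
#' @param pairs data frame with character columns `a`, `b`, one row per
#'   pair, order significant; pairs must be distinct with `a != b`.
#' @param control_label,case_label the two phenotype names.
#' @param vote_threshold integer in `[0, n_pairs)`; default
#'   `floor(n_pairs / 2)`.
#' @param metadata optional named list stored with the model.
#' @return object of class `"voting_model"`.
#' @seealso [predict.voting_model()], [save_model()], [load_model()]
#' @export
voting_model <- function(pairs, control_label, case_label,
                         vote_threshold = NULL, metadata = list()) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!all(c("a", "b") %in% names(pairs)))
    stop("pairs must have columns 'a' and 'b'")
  pairs <- data.frame(a = as.character(pairs$a), b = as.character(pairs$b),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) stop("model needs at least one pair")
  if (any(pairs$a == pairs$b)) stop("pair with identical features")
  if (anyDuplicated(paste(pairs$a, pairs$b))) stop("duplicate pair in panel")
  if (!nzchar(control_label) || !nzchar(case_label) ||
      control_label == case_label)
    stop("control and case labels must be distinct non-empty strings")
  if (is.null(vote_threshold)) vote_threshold <- nrow(pairs) %/% 2L
  vote_threshold <- as.integer(vote_threshold)
  if (is.na(vote_threshold) || vote_threshold < 0L ||
      vote_threshold >= nrow(pairs))
    stop("vote_threshold must satisfy 0 <= threshold < number of pairs")
  structure(list(pairs = pairs,
                 control_label = control_label,
                 case_label = case_label,
                 vote_threshold = vote_threshold,
                 metadata = metadata),
            class = "voting_model")
}

#' @export
print.voting_model <- function(x, ...) {
  cat("REO majority-vote model: ", nrow(x$pairs), " pair(s), call '",
      x$control_label, "' on > ", x$vote_threshold,
      " control-pattern votes (else '", x$case_label, "')\n", sep = "")
  show <- utils::head(x$pairs, 5L)
  cat(paste0("  (", show$a, " > ", show$b, ")", collapse = "\n"), "\n")
  if (nrow(x$pairs) > 5L) cat("  ... and", nrow(x$pairs) - 5L, "more\n")
  invisible(x)
}

#' Count control-pattern votes for each sample
#'
#' @param model a [voting_model()].
#' @param x feature-by-sample numeric matrix (or a single named numeric
#'   vector for one sample); must contain every model feature; no
#'   imputation of missing features is attempted.
#' @return named integer vector of votes (pairs with `value(a) > value(b)`).
#' @export
count_votes <- function(model, x) {
  if (is.numeric(x) && is.null(dim(x)))
    x <- matrix(x, ncol = 1L, dimnames = list(names(x), "sample"))
  feats <- unique(c(model$pairs$a, model$pairs$b))
  miss <- setdiff(feats, rownames(x))
  if (length(miss))
    stop("sample(s) missing model feature(s): ",
         paste(utils::head(miss, 5L), collapse = ", "))
  gt <- x[model$pairs$a, , drop = FALSE] > x[model$pairs$b, , drop = FALSE]
  stats::setNames(as.integer(colSums(gt)), colnames(x))
}

#' Predict phenotype labels by majority vote
#'
#' @param object a [voting_model()].
#' @param newdata feature-by-sample numeric matrix, or a single named
#'   numeric vector.
#' @param type `"label"` (default) for phenotype calls, `"votes"` for a data
#'   frame with vote counts alongside the calls.
#' @param ... unused.
#' @return named character vector of labels, or a data frame
#'   (`sample_id`, `votes_control_pattern`, `n_pairs`, `predicted_label`).
#' @export
predict.voting_model <- function(object, newdata, type = c("label", "votes"),
                                 ...) {
  type <- match.arg(type)
  votes <- count_votes(object, newdata)
  labels <- ifelse(votes > object$vote_threshold,
                   object$control_label, object$case_label)
  names(labels) <- names(votes)
  if (type == "label") return(labels)
  data.frame(sample_id = names(votes),
             votes_control_pattern = unname(votes),
             n_pairs = nrow(object$pairs),
             predicted_label = unname(labels),
             stringsAsFactors = FALSE)
}

#' Classification metrics with the case phenotype as positive class
#'
#' Confusion-matrix metrics for hard calls: sensitivity, specificity,
#' accuracy, positive and negative predictive value, and the geometric mean
#' `sqrt(NPV * PPV)` used for panel-size selection. A predictive value whose
#' denominator is zero (empty predicted class) is reported as `NA` and
#' enters the geometric mean as 0.
#'
#' @param predicted named character vector of predicted labels.
#' @param truth named character vector of true labels (same sample ids).
#' @param case_label label treated as positive.
#' @return object of class `"reo_metrics"`: list with `sen`, `spe`, `acc`,
#'   `ppv`, `npv`, `geometric_mean` and `confusion` (named counts `tp`,
#'   `fp`, `tn`, `fn`).
#' @export
evaluate_predictions <- function(predicted, truth, case_label) {
  if (is.null(names(predicted)) || is.null(names(truth))) {
    if (length(predicted) != length(truth))
      stop("predicted and truth differ in length and carry no sample ids")
  } else {
    if (!setequal(names(predicted), names(truth)))
      stop("predicted and truth cover different sample ids")
    truth <- truth[names(predicted)]
  }
  pos_pred <- predicted == case_label
  pos_true <- truth == case_label
  tp <- sum(pos_pred & pos_true); fp <- sum(pos_pred & !pos_true)
  fn <- sum(!pos_pred & pos_true); tn <- sum(!pos_pred & !pos_true)
  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  ppv <- ratio(tp, tp + fp)
  npv <- ratio(tn, tn + fn)
  gm <- sqrt(ifelse(is.na(ppv), 0, ppv) * ifelse(is.na(npv), 0, npv))
  structure(list(sen = ratio(tp, tp + fn),
                 spe = ratio(tn, tn + fp),
                 acc = ratio(tp + tn, tp + tn + fp + fn),
                 ppv = ppv, npv = npv, geometric_mean = gm,
                 confusion = c(tp = tp, fp = fp, tn = tn, fn = fn)),
            class = "reo_metrics")
}

#' @export
print.reo_metrics <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "  NA  " else sprintf("%6.2f%%", 100 * v)
  cat("Classification metrics (case = positive)\n")
  cat("  SEN", pct(x$sen), " SPE", pct(x$spe), " ACC", pct(x$acc), "\n")
  cat("  PPV", pct(x$ppv), " NPV", pct(x$npv),
      " sqrt(NPV*PPV)", pct(x$geometric_mean), "\n")
  cat("  confusion: tp =", x$confusion["tp"], "fp =", x$confusion["fp"],
      "tn =", x$confusion["tn"], "fn =", x$confusion["fn"], "\n")
  invisible(x)
}

#' Save a voting model as JSON
#'
#' Schema (version 1):
#' `{"schema_version": 1, "control_label", "case_label",
#'   "pairs": [{"a", "b"}, ...], "vote_threshold", "metadata": {}}`.
#' Pair order is significant and preserved exactly.
#'
#' @param model a [voting_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "voting_model")) stop("not a voting_model")
  obj <- list(schema_version = 1L,
              control_label = model$control_label,
              case_label = model$case_label,
              pairs = model$pairs,
              vote_threshold = model$vote_threshold,
              metadata = if (length(model$metadata)) model$metadata
                         else stats::setNames(list(), character(0)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a voting model from JSON
#'
#' @param path path to a file written by [save_model()].
#' @return a [voting_model()].
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != 1L)
    stop("unsupported model schema version: ",
         if (is.null(obj$schema_version)) "<missing>" else obj$schema_version)
  req <- c("control_label", "case_label", "pairs", "vote_threshold")
  if (!all(req %in% names(obj)))
    stop("model file missing field(s): ",
         paste(setdiff(req, names(obj)), collapse = ", "))
  meta <- if (is.null(obj$metadata)) list() else as.list(obj$metadata)
  voting_model(obj$pairs, obj$control_label, obj$case_label,
               vote_threshold = obj$vote_threshold, metadata = meta)
}
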