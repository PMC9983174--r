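#' Fit an REO majority-vote biomarker panel
#'
#' Runs the full discovery pipeline on a labeled training cohort:
#' correlation-based outlier removal per phenotype (optional), screening of
#' stable and significantly reversed pairs, and panel construction in one
#' of two modes:
#'
#' * `mode = "direct"`: take the first `panel_size` candidate pairs in
#'   lexicographic order. This is the natural construction when
#'   `delta_p_threshold = 1`, where every candidate already separates the
#'   training phenotypes perfectly and a small fixed panel suffices.
#' * `mode = "coverage"`: rank candidates by activity score (occurrence
#'   count across greedily grown maximum-sample-coverage combinations) and
#'   pick the smallest top-`k` panel whose training geometric mean
#'   `sqrt(NPV * PPV)` first attains its maximum. The usual choice with a
#'   relaxed reversal threshold (e.g. `delta_p_threshold = 0.7`) against a
#'   heterogeneous control group.
#'
#' @param x feature-by-sample numeric matrix of non-negative intensities.
#' @param labels named character vector, sample id -> phenotype; samples
#'   with other phenotypes are ignored.
#' @param control_label,case_label the phenotypes to contrast.
#' @param stability_threshold minimal control holding fraction of a stable
#'   pair (default 0.95).
#' @param fdr BH false discovery rate for reversal calls (default 0.05).
#' @param delta_p_threshold minimal reversal degree \eqn{\Delta P},
#'   inclusive (default 1).
#' @param mode panel construction mode, `"coverage"` (default) or
#'   `"direct"`.
#' @param panel_size panel size for `mode = "direct"` (default 5; capped at
#'   the number of candidates).
#' @param vote_threshold optional vote threshold override; default is the
#'   strict majority `floor(n_pairs / 2)`.
#' @param qc run [remove_outliers()] on each phenotype first (default
#'   `TRUE`).
#' @param qc_sd_multiple retention band width for QC (default 2).
#' @param subsample optional list `list(phenotype =, n =, seed =)`: after
#'   QC, keep a seeded random subset of `n` samples of that phenotype
#'   (balances a dominating phenotype before screening).
#' @return object of class `"reo_fit"`: list with `model` (a
#'   [voting_model()]), `screen` (candidate table), `counts` (stable /
#'   reversed / candidate pair counts), `activity` and `curve`
#'   (`mode = "coverage"` only), `training` (training-set
#'   [evaluate_predictions()] metrics), `qc` (per-phenotype outlier
#'   reports), `samples` (ids used for screening) and `call`.
#' @examples
#' sim <- simulate_reo_cohort(n_features = 80, n_control = 30, n_case = 30,
#'                            n_stable_pairs = 10, n_reversed_pairs = 5,
#'                            noise_sd = 150, seed = 2)
#' fit <- reo_fit(sim$x, sim$labels, "control", "case",
#'                mode = "direct", panel_size = 5, qc = FALSE)
#' fit
#' predict(fit, sim$x[, 1:3])
#' @export
reo_fit <- function(x, labels, control_label, case_label,
                    stability_threshold = 0.95, fdr = 0.05,
                    delta_p_threshold = 1,
                    mode = c("coverage", "direct"), panel_size = 5L,
                    vote_threshold = NULL,
                    qc = TRUE, qc_sd_multiple = 2, subsample = NULL) {
  mode <- match.arg(mode)
  validate_expression(x)
  validate_labels(x, labels)
  labels <- labels[labels %in% c(control_label, case_label)]
  if (!any(labels == control_label)) stop("no '", control_label, "' samples")
  if (!any(labels == case_label)) stop("no '", case_label, "' samples")
  x <- x[, names(labels), drop = FALSE]

  qc_reports <- list()
  if (qc) {
    for (ph in c(control_label, case_label)) {
      res <- remove_outliers(x, labels, ph, sd_multiple = qc_sd_multiple)
      x <- res$x
      labels <- labels[colnames(x)]
      qc_reports[[ph]] <- res$report
    }
  }
  if (!is.null(subsample)) {
    stopifnot(all(c("phenotype", "n") %in% names(subsample)))
    ids <- names(labels)[labels == subsample$phenotype]
    if (length(ids) > subsample$n) {
      seed <- if (is.null(subsample$seed)) 1L else subsample$seed
      set.seed(seed)
      drop <- setdiff(ids, sample(ids, subsample$n))
      x <- x[, setdiff(colnames(x), drop), drop = FALSE]
      labels <- labels[colnames(x)]
    }
  }

  screen <- screen_candidates(x, labels, control_label, case_label,
                              stability_threshold = stability_threshold,
                              fdr = fdr,
                              delta_p_threshold = delta_p_threshold)
  counts <- list(stable = attr(screen, "n_stable"),
                 reversed = attr(screen, "n_reversed"),
                 candidates = nrow(screen))
  if (nrow(screen) == 0L)
    stop("no candidate pairs at stability ", stability_threshold,
         ", FDR ", fdr, ", delta_p >= ", delta_p_threshold,
         " (stable: ", counts$stable, ", reversed: ", counts$reversed, ")")

  activity <- NULL
  curve <- NULL
  if (mode == "direct") {
    nat <- screen[order(screen$a, screen$b, method = "radix"), ]
    panel <- utils::head(nat, panel_size)
    model <- voting_model(panel[, c("a", "b")], control_label, case_label,
                          vote_threshold = vote_threshold,
                          metadata = list(mode = "direct"))
  } else {
    activity <- activity_scores(screen, x, labels, control_label, case_label)
    sel <- select_top_k(activity, x, labels, control_label, case_label,
                        vote_threshold = vote_threshold)
    model <- sel$model
    model$metadata$mode <- "coverage"
    curve <- sel$curve
  }

  pred <- predict(model, x)
  training <- evaluate_predictions(pred, labels, case_label)

  structure(list(model = model, screen = screen, counts = counts,
                 activity = activity, curve = curve, training = training,
                 qc = qc_reports, samples = colnames(x),
                 mode = mode, call = match.call()),
            class = "reo_fit")
}

#' @export
print.reo_fit <- function(x, ...) {
  cat("REO biomarker panel fit (mode: ", x$mode, ")\n", sep = "")
  cat("  pairs: stable ", x$counts$stable, " -> reversed ",
      x$counts$reversed, " -> candidates ", x$counts$candidates, "\n",
      sep = "")
  cat("  panel: ", nrow(x$model$pairs), " pair(s), vote threshold ",
      x$model$vote_threshold, "\n", sep = "")
  cat("  training acc ", sprintf("%.2f%%", 100 * x$training$acc),
      ", sqrt(NPV*PPV) ", sprintf("%.4f", x$training$geometric_mean),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.reo_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.reo_fit")
}

#' @export
print.summary.reo_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nPanel pairs (reference pattern a > b in '",
      f$model$control_label, "'):\n", sep = "")
  panel <- merge(f$model$pairs, f$screen, by = c("a", "b"), sort = FALSE)
  print(panel[, c("a", "b", "p_control", "p_case", "delta_p", "q_value")],
        row.names = FALSE, digits = 4)
  if (!is.null(f$curve)) {
    best <- which.max(f$curve$geometric_mean)
    cat("\nGeometric-mean curve: maximum ",
        sprintf("%.4f", f$curve$geometric_mean[best]),
        " first reached at k = ", f$curve$k[best], " of ",
        nrow(f$curve), "\n", sep = "")
  }
  cat("\nTraining metrics:\n")
  print(f$training)
  invisible(x)
}

#' Panel pairs of a fitted REO model
#'
#' @param object a [reo_fit()] object.
#' @param ... unused.
#' @return data frame of panel pairs with their screening statistics.
#' @export
coef.reo_fit <- function(object, ...) {
  merge(object$model$pairs, object$screen, by = c("a", "b"), sort = FALSE)
}

#' Predict phenotypes for new samples from a fitted panel
#'
#' @param object a [reo_fit()] object.
#' @param newdata feature-by-sample numeric matrix containing every panel
#'   feature.
#' @param type `"label"` or `"votes"` (see [predict.voting_model()]).
#' @param ... unused.
#' @export
predict.reo_fit <- function(object, newdata, type = c("label", "votes"),
                            ...) {
  predict(object$model, newdata, type = match.arg(type))
}

#' Plot the panel-size selection curve of a fitted REO model
#'
#' For coverage-mode fits, plots the training geometric mean
#' `sqrt(NPV * PPV)` against panel size `k` and marks the selected panel.
#' For direct-mode fits, plots the reversal degree of the candidate pairs.
#'
#' @param x a [reo_fit()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.reo_fit <- function(x, ...) {
  if (!is.null(x$curve)) {
    graphics::plot(x$curve$k, x$curve$geometric_mean, type = "b",
                   xlab = "panel size k",
                   ylab = "sqrt(NPV x PPV), training", ...)
    k_sel <- nrow(x$model$pairs)
    graphics::abline(v = k_sel, lty = 2)
    graphics::mtext(paste("selected k =", k_sel), side = 3, line = 0.2,
                    cex = 0.8)
  } else {
    graphics::plot(seq_len(nrow(x$screen)), x$screen$delta_p, type = "h",
                   xlab = "candidate pair (ranked)",
                   ylab = expression(Delta * P), ...)
  }
  invisible(x)
}
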