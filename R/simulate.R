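#' Simulate an expression cohort with planted ordering structure
#'
#' Generates a feature-by-sample intensity matrix for a control and a case
#' phenotype with known relative-expression-ordering (REO) ground truth:
#'
#' * Baseline feature levels are log-normal (median around 1e4 intensity
#'   units) with additive Gaussian sample noise of scale `noise_sd`, which
#'   randomly flips the orderings of features with similar levels.
#' * `n_stable_pairs` planted pairs, on mutually disjoint features, show
#'   `a > b` in exactly `ceiling(stable_hold_fraction * n_control)` control
#'   samples. The first `n_reversed_pairs` of them show `a > b` in only
#'   `floor((stable_hold_fraction - target_delta_p) * n_case)` case
#'   samples, so their realized reversal degree is at least
#'   `target_delta_p` (rounding is conservative); the remaining planted
#'   pairs keep the control fraction in the cases. Directions are enforced
#'   by swapping the
#'   two planted features' values within a sample, which cannot disturb any
#'   other planted pair (disjoint features), so the realized fractions are
#'   exact for every seed; `truth` records them.
#' * Optionally, `outlier_samples` anti-correlated control profiles are
#'   appended (see [inject_outliers()]) and a strictly monotone per-sample
#'   distortion is applied last. A monotone distortion changes every
#'   intensity but no within-sample ordering, emulating batch effects that
#'   REO-based analysis must ignore.
#'
#' @param n_features number of features.
#' @param n_control,n_case samples per phenotype.
#' @param n_stable_pairs planted stable pairs (needs `2 * n_stable_pairs <=
#'   n_features`).
#' @param stable_hold_fraction control-group holding fraction of planted
#'   pairs, in (0.5, 1] (default 1: completely stable, as for panels built
#'   from fully reversed pairs).
#' @param n_reversed_pairs planted reversed pairs, `<= n_stable_pairs`.
#' @param target_delta_p reversal degree of planted reversed pairs, in
#'   (0, 1] and at most `stable_hold_fraction` (default 1: complete
#'   reversal).
#' @param noise_sd additive Gaussian noise scale in intensity units
#'   (default 0).
#' @param distortion per-sample monotone distortion applied last: `"none"`,
#'   `"per_sample_scale"` (random positive factor), `"log"` (natural log),
#'   or `"batch_shift"` (random additive offset).
#' @param outlier_samples number of anti-correlated control samples to
#'   append (default 0).
#' @param seed RNG seed for the samples (noise, planted-direction
#'   assignment, distortion); runs are fully reproducible from it.
#' @param structure_seed RNG seed for the cohort structure (baseline
#'   feature levels and planted pair placement); defaults to `seed`. Keep
#'   it fixed while varying `seed` to draw independent cohorts from the
#'   same generative process, e.g. a validation cohort for a panel trained
#'   on another draw.
#' @param control_label,case_label phenotype names.
#' @return list with
#'   \describe{
#'     \item{x}{the intensity matrix,}
#'     \item{labels}{named phenotype vector covering all samples,}
#'     \item{truth}{list: `stable_pairs` (data frame `a`, `b`,
#'       `p_control`), `reversed_pairs` (`a`, `b`, `p_control`, `p_case`,
#'       `delta_p`, realized values), `outliers` (injected sample ids),}
#'     \item{config}{echo of the generator arguments.}
#'   }
#' @examples
#' sim <- simulate_reo_cohort(n_features = 60, n_control = 20, n_case = 20,
#'                            n_stable_pairs = 8, n_reversed_pairs = 4,
#'                            noise_sd = 150, seed = 1)
#' head(sim$truth$reversed_pairs)
#' @export
simulate_reo_cohort <- function(n_features = 200, n_control = 50,
                                n_case = 50, n_stable_pairs = 20,
                                stable_hold_fraction = 1,
                                n_reversed_pairs = 10,
                                target_delta_p = 1, noise_sd = 0,
                                distortion = c("none", "per_sample_scale",
                                               "log", "batch_shift"),
                                outlier_samples = 0, seed = 1L,
                                structure_seed = seed,
                                control_label = "control",
                                case_label = "case") {
  distortion <- match.arg(distortion)
  if (2L * n_stable_pairs > n_features)
    stop("infeasible: need 2 * n_stable_pairs <= n_features for disjoint pairs")
  if (n_reversed_pairs > n_stable_pairs)
    stop("n_reversed_pairs must not exceed n_stable_pairs")
  if (stable_hold_fraction <= 0.5 || stable_hold_fraction > 1)
    stop("stable_hold_fraction must be in (0.5, 1]")
  if (target_delta_p <= 0 || target_delta_p > 1)
    stop("target_delta_p must be in (0, 1]")
  if (target_delta_p > stable_hold_fraction)
    stop("infeasible: target_delta_p exceeds stable_hold_fraction ",
         "(the case fraction would be negative)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")

  feats <- sprintf("mir%04d", seq_len(n_features))
  samples <- c(sprintf("%s_%03d", control_label, seq_len(n_control)),
               sprintf("%s_%03d", case_label, seq_len(n_case)))
  labels <- stats::setNames(rep(c(control_label, case_label),
                                c(n_control, n_case)), samples)
  is_ctrl <- seq_len(n_control)
  is_case <- n_control + seq_len(n_case)

  set.seed(structure_seed)
  base <- exp(stats::rnorm(n_features, log(1e4), 0.4))
  pf <- sample.int(n_features, 2L * n_stable_pairs)
  pa <- pf[seq_len(n_stable_pairs) * 2L - 1L]
  pb <- pf[seq_len(n_stable_pairs) * 2L]
  gap <- 2 * noise_sd + 10
  centre <- base[pa]
  base[pa] <- centre + gap / 2
  base[pb] <- centre - gap / 2

  set.seed(seed)
  vals <- base + matrix(stats::rnorm(n_features * length(samples),
                                     sd = noise_sd),
                        n_features, length(samples))
  dimnames(vals) <- list(feats, samples)

  ## exact-count direction planting: swap the pair's two values where the
  ## current direction disagrees with the wanted one
  plant <- function(ai, bi, cols, k_up) {
    want <- logical(length(cols))
    want[sample.int(length(cols), k_up)] <- TRUE
    cur <- vals[ai, cols] > vals[bi, cols]
    flip <- cols[cur != want]
    if (length(flip)) {
      tmp <- vals[ai, flip]
      vals[ai, flip] <<- vals[bi, flip]
      vals[bi, flip] <<- tmp
    }
  }
  ## smallest/largest counts consistent with the targets, so the realized
  ## control fraction is >= stable_hold_fraction and the realized reversal
  ## degree is >= target_delta_p for every cohort size
  k_ctrl <- ceiling(stable_hold_fraction * n_control - 1e-9)
  p_case_target <- stable_hold_fraction - target_delta_p
  k_case_rev <- floor(p_case_target * n_case + 1e-9)
  k_case_stab <- ceiling(stable_hold_fraction * n_case - 1e-9)
  for (i in seq_len(n_stable_pairs)) {
    plant(pa[i], pb[i], is_ctrl, k_ctrl)
    plant(pa[i], pb[i], is_case,
          if (i <= n_reversed_pairs) k_case_rev else k_case_stab)
  }

  rev_idx <- seq_len(n_reversed_pairs)
  truth <- list(
    stable_pairs = data.frame(a = feats[pa], b = feats[pb],
                              p_control = k_ctrl / n_control,
                              stringsAsFactors = FALSE),
    reversed_pairs = data.frame(a = feats[pa[rev_idx]], b = feats[pb[rev_idx]],
                                p_control = rep(k_ctrl / n_control,
                                                n_reversed_pairs),
                                p_case = rep(k_case_rev / n_case,
                                             n_reversed_pairs),
                                delta_p = rep(k_ctrl / n_control -
                                              k_case_rev / n_case,
                                              n_reversed_pairs),
                                stringsAsFactors = FALSE),
    outliers = character(0))

  if (outlier_samples > 0) {
    inj <- inject_outliers(vals, labels, control_label, outlier_samples,
                           seed = seed + 1L)
    vals <- inj$x
    labels <- inj$labels
    truth$outliers <- inj$ids
  }

  vals <- apply_distortion(vals, distortion)

  list(x = vals, labels = labels, truth = truth,
       config = list(n_features = n_features, n_control = n_control,
                     n_case = n_case, n_stable_pairs = n_stable_pairs,
                     stable_hold_fraction = stable_hold_fraction,
                     n_reversed_pairs = n_reversed_pairs,
                     target_delta_p = target_delta_p, noise_sd = noise_sd,
                     distortion = distortion,
                     outlier_samples = outlier_samples, seed = seed,
                     structure_seed = structure_seed,
                     control_label = control_label,
                     case_label = case_label))
}

#' Strictly monotone per-sample distortions
#' @noRd
apply_distortion <- function(vals, distortion) {
  switch(distortion,
         none = vals,
         per_sample_scale = vals * rep(stats::runif(ncol(vals), 0.5, 2),
                                       each = nrow(vals)),
         log = {
           if (any(vals <= 0))
             stop("log distortion requires strictly positive intensities")
           log(vals)
         },
         batch_shift = vals + rep(stats::runif(ncol(vals), 0, 500),
                                  each = nrow(vals)))
}

#' Append anti-correlated outlier samples to one phenotype
#'
#' Builds the mean expression profile of the phenotype, reverses it in rank
#' (the feature with the lowest mean receives the highest value and so on)
#' and appends `count` copies of that profile, each with a minute seeded
#' jitter so the injected samples are not exactly identical. Such samples
#' are strongly anti-correlated with genuine members of the phenotype and
#' should be flagged by [remove_outliers()].
#'
#' @param x feature-by-sample numeric matrix.
#' @param labels named character vector, sample id -> phenotype.
#' @param phenotype phenotype to contaminate.
#' @param count number of samples to append (0 returns the input unchanged).
#' @param seed RNG seed for the jitter.
#' @return list with `x` (matrix with appended columns), `labels` (extended
#'   accordingly) and `ids` (the injected sample ids).
#' @export
inject_outliers <- function(x, labels, phenotype, count, seed = 1L) {
  validate_expression(x)
  validate_labels(x, labels)
  ids <- names(labels)[labels == phenotype]
  if (length(ids) == 0L) stop("no samples labeled '", phenotype, "'")
  count <- as.integer(count)
  if (count == 0L) return(list(x = x, labels = labels, ids = character(0)))
  set.seed(seed)
  mu <- rowMeans(x[, ids, drop = FALSE])
  rev_profile <- numeric(length(mu))
  rev_profile[order(mu)] <- sort(mu, decreasing = TRUE)
  jitter_sd <- max(1e-9, 1e-6 * (max(mu) - min(mu)))
  new_ids <- paste0("outlier_", phenotype, "_", seq_len(count))
  stopifnot(!any(new_ids %in% colnames(x)))
  add <- matrix(rev_profile, nrow(x), count) +
    matrix(stats::rnorm(nrow(x) * count, sd = jitter_sd), nrow(x), count)
  colnames(add) <- new_ids
  rownames(add) <- rownames(x)
  list(x = cbind(x, add),
       labels = c(labels, stats::setNames(rep(phenotype, count), new_ids)),
       ids = new_ids)
}
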