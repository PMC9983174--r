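## Independent brute-force oracles and fixture builders. Everything here is
## deliberately naive (explicit loops, no shared code with the package
## internals) so it can serve as a cross-check.

# fraction of samples with a > b, by explicit loop
brute_fraction <- function(x, a, b, samples = colnames(x)) {
  k <- 0L
  for (s in samples) if (x[a, s] > x[b, s]) k <- k + 1L
  k / length(samples)
}

# all ordered stable pairs by exhaustive recount, lexicographic order
brute_stable_pairs <- function(x, ctrl_ids, threshold) {
  feats <- sort(rownames(x), method = "radix")
  out <- list()
  for (a in feats) for (b in feats) {
    if (a == b) next
    p <- brute_fraction(x, a, b, ctrl_ids)
    if (p >= threshold - 1e-9)
      out[[length(out) + 1L]] <- data.frame(a = a, b = b, p_control = p,
                                            stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(a = character(), b = character(), p_control = numeric())
}

# coverage of a pair set by explicit per-sample loop
brute_coverage <- function(members, x, labels, control, case) {
  ids <- names(labels)[labels %in% c(control, case)]
  covered <- 0L
  for (s in ids) {
    hit <- FALSE
    for (r in seq_len(nrow(members))) {
      gt <- x[members$a[r], s] > x[members$b[r], s]
      if (if (labels[[s]] == control) gt else !gt) { hit <- TRUE; break }
    }
    if (hit) covered <- covered + 1L
  }
  covered / length(ids)
}

# naive greedy growth re-implementation (first-wins tie-break)
brute_grow <- function(seed_idx, candidates, x, labels, control, case) {
  members <- seed_idx
  repeat {
    rem <- setdiff(seq_len(nrow(candidates)), members)
    if (!length(rem)) break
    cur <- brute_coverage(candidates[members, , drop = FALSE],
                          x, labels, control, case)
    gains <- vapply(rem, function(j)
      brute_coverage(candidates[c(members, j), , drop = FALSE],
                     x, labels, control, case) - cur, numeric(1))
    if (max(gains) <= 1e-12) break
    members <- c(members, rem[which.max(gains)])
  }
  members
}

# Benjamini-Hochberg step-up, written from the definition
brute_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, p[ord[i]] * n / i)
    q[ord[i]] <- running
  }
  q
}

# two-sided Fisher p by hypergeometric enumeration (fisher.test convention)
brute_fisher <- function(n1, n2, m1, m2) {
  stats::fisher.test(matrix(c(n1, n2, m1, m2), 2L, byrow = TRUE))$p.value
}

# random strictly increasing transform (fresh draw each call)
rand_monotone <- function() {
  a <- stats::runif(1, 0.2, 5)
  b <- stats::runif(1, -2, 2)
  switch(sample(c("affine", "cube", "exp", "rank", "logshift"), 1L),
         affine  = function(v) a * v + b,
         cube    = function(v) (a * v + b)^3,
         exp     = function(v) exp(v / (max(abs(v)) + 1)) * a,
         rank    = function(v) rank(v, ties.method = "average"),
         logshift = function(v) log1p(a * (v - min(v))))
}

# apply an independent random monotone transform to every sample (column)
distort_cohort <- function(x) {
  for (s in seq_len(ncol(x))) x[, s] <- rand_monotone()(x[, s])
  x
}

# build an all-control cohort realizing prescribed per-pair coverage sets:
# pair j covers exactly the samples in sets[[j]]
cov_fixture <- function(sets, n_samples, label = "ctl") {
  n_pairs <- length(sets)
  feats <- sprintf("f%02d", seq_len(2L * n_pairs))
  samples <- sprintf("s%02d", seq_len(n_samples))
  x <- matrix(1, 2L * n_pairs, n_samples,
              dimnames = list(feats, samples))
  for (j in seq_len(n_pairs)) {
    a <- 2L * j - 1L; b <- 2L * j
    x[a, ] <- 10; x[b, ] <- 20
    if (length(sets[[j]])) x[a, sets[[j]]] <- 30
  }
  list(x = x,
       labels = stats::setNames(rep(label, n_samples), samples),
       candidates = data.frame(a = feats[seq(1L, 2L * n_pairs, 2L)],
                               b = feats[seq(2L, 2L * n_pairs, 2L)],
                               stringsAsFactors = FALSE))
}

# named prediction/truth vectors realizing a given confusion matrix
confusion_fixture <- function(tp, fn, fp, tn, case = "case", ctl = "ctl") {
  n <- tp + fn + fp + tn
  ids <- sprintf("s%04d", seq_len(n))
  truth <- stats::setNames(rep(c(case, ctl), c(tp + fn, fp + tn)), ids)
  pred <- stats::setNames(rep(c(case, ctl, case, ctl),
                              c(tp, fn, fp, tn)), ids)
  list(pred = pred, truth = truth)
}
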