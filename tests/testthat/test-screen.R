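ordered_matrix <- function() {
  # f1 > f2 > f3 in every one of 4 samples
  matrix(c(30, 20, 10,  31, 21, 11,  32, 22, 12,  33, 23, 13), 3, 4,
         dimnames = list(c("f1", "f2", "f3"), paste0("s", 1:4)))
}

test_that("pair_fraction counts strict exceedances with ties on the <= side", {
  x <- matrix(c(2, 1,  3, 1,  4, 1,  1, 2), 2, 4,
              dimnames = list(c("a", "b"), paste0("s", 1:4)))
  expect_equal(pair_fraction(x, "a", "b"), 0.75)
  expect_equal(pair_fraction(x, "a", "b", paste0("s", 1:3)), 1)
  tied <- matrix(5, 2, 3, dimnames = list(c("a", "b"), paste0("s", 1:3)))
  expect_equal(pair_fraction(tied, "a", "b"), 0)   # ties count as <=
  expect_error(pair_fraction(x, "zz", "b"), "unknown feature")
  expect_error(pair_fraction(x, "a", "b", character(0)), "empty")
})

test_that("a strict total ordering yields exactly the ordered pairs as stable", {
  x <- ordered_matrix()
  lab <- stats::setNames(rep("ctl", 4), colnames(x))
  st <- find_stable_pairs(x, lab, "ctl", 0.95)
  expect_equal(st[, c("a", "b")],
               data.frame(a = c("f1", "f1", "f2"), b = c("f2", "f3", "f3")),
               ignore_attr = TRUE)
  expect_equal(st$p_control, rep(1, 3))
})

test_that("at threshold 1.0 a single discordant sample excludes the pair", {
  x <- ordered_matrix()
  x["f2", "s4"] <- 40            # f2 > f1 in s4
  lab <- stats::setNames(rep("ctl", 4), colnames(x))
  st <- find_stable_pairs(x, lab, "ctl", 1)
  expect_false(any(st$a == "f1" & st$b == "f2"))
  st75 <- find_stable_pairs(x, lab, "ctl", 0.75)
  expect_true(any(st75$a == "f1" & st75$b == "f2"))
})

test_that("stable-pair detection matches the exhaustive recount oracle", {
  sim <- simulate_reo_cohort(n_features = 60, n_control = 40, n_case = 5,
                             n_stable_pairs = 20, n_reversed_pairs = 0,
                             stable_hold_fraction = 0.97, target_delta_p = 0.5,
                             noise_sd = 150, seed = 31)
  ctrl <- names(sim$labels)[sim$labels == "control"]
  st <- find_stable_pairs(sim$x, sim$labels, "control", 0.95)
  oracle <- brute_stable_pairs(sim$x, ctrl, 0.95)
  expect_equal(st[, c("a", "b", "p_control")], oracle, ignore_attr = TRUE)
  # every planted pair whose realized holding fraction clears the threshold
  planted <- sim$truth$stable_pairs
  keep <- planted$p_control >= 0.95
  expect_true(all(paste(planted$a, planted$b)[keep] %in% paste(st$a, st$b)))
})

test_that("Fisher reversal p-values match frozen enumeration values", {
  expect_equal(fisher_reversal_p(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(fisher_reversal_p(5, 5, 5, 5), 1)
  expect_equal(fisher_reversal_p(2, 0, 0, 2), 1 / 3, tolerance = 1e-12)
  expect_error(fisher_reversal_p(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher implementation agrees with fisher.test on random tables", {
  set.seed(5)
  for (i in 1:200) {
    tab <- rmultinom(1, sample(4:60, 1), runif(4, 0.05, 1))
    p <- fisher_reversal_p(tab[1], tab[2], tab[3], tab[4])
    expect_equal(p, brute_fisher(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
  }
  # vectorized call equals elementwise calls
  n1 <- c(10, 5, 2, 0); n2 <- c(0, 5, 0, 7); m1 <- c(0, 5, 0, 7); m2 <- c(10, 5, 2, 0)
  expect_equal(fisher_reversal_p(n1, n2, m1, m2),
               mapply(fisher_reversal_p, n1, n2, m1, m2))
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_equal(bh_adjust(c(0.005, 0.1, 0.2, 0.9)),
               c(0.02, 0.2, 0.2 * 4 / 3, 0.9))
  set.seed(6)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))^2
    q <- bh_adjust(p)
    expect_equal(q, brute_bh(p))
    expect_true(all(q >= p) && max(q) <= 1)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("a fully reversed planted pair screens with delta_p = 1", {
  sim <- simulate_reo_cohort(n_features = 30, n_control = 20, n_case = 20,
                             n_stable_pairs = 1, n_reversed_pairs = 1,
                             noise_sd = 0, seed = 8)
  sc <- screen_candidates(sim$x, sim$labels, "control", "case",
                          delta_p_threshold = 1)
  planted <- sim$truth$reversed_pairs
  hit <- sc[sc$a == planted$a & sc$b == planted$b, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$p_control, 1)
  expect_equal(hit$p_case, 0)
  expect_equal(hit$delta_p, 1)
  expect_equal(hit$n1, 20L)
  expect_equal(hit$m2, 20L)
})

test_that("pairs with identical REO distribution in both groups are dropped", {
  x <- cbind(ordered_matrix(), ordered_matrix() + 0.5)
  colnames(x) <- paste0("s", 1:8)
  lab <- stats::setNames(rep(c("ctl", "case"), each = 4), colnames(x))
  sc <- screen_candidates(x, lab, "ctl", "case", delta_p_threshold = 0)
  expect_equal(nrow(sc), 0L)
  full <- screen_candidates(x, lab, "ctl", "case", delta_p_threshold = 0,
                            keep_all = TRUE)
  expect_equal(attr(full, "n_stable"), 3L)
  expect_true(all(full$p_value == 1 & full$delta_p == 0))
})

test_that("screening recovers exactly the planted reversed pairs", {
  sim <- simulate_reo_cohort(n_features = 80, n_control = 40, n_case = 40,
                             n_stable_pairs = 10, n_reversed_pairs = 10,
                             stable_hold_fraction = 1, target_delta_p = 0.9,
                             noise_sd = 150, seed = 9)
  sc <- screen_candidates(sim$x, sim$labels, "control", "case",
                          fdr = 0.05, delta_p_threshold = 0.7)
  planted <- paste(sim$truth$reversed_pairs$a, sim$truth$reversed_pairs$b)
  found <- paste(sc$a, sc$b)
  expect_true(all(planted %in% found))
  # brute-force recount for every extra pair the screen reports
  ctrl <- names(sim$labels)[sim$labels == "control"]
  case <- names(sim$labels)[sim$labels == "case"]
  for (r in seq_len(nrow(sc))) {
    pc <- brute_fraction(sim$x, sc$a[r], sc$b[r], ctrl)
    pk <- brute_fraction(sim$x, sc$a[r], sc$b[r], case)
    expect_equal(sc$p_control[r], pc)
    expect_equal(sc$p_case[r], pk)
    expect_true(pc - pk >= 0.7)
  }
  # sorted by decreasing delta_p, lexicographic tie-break
  key <- order(-sc$delta_p, sc$a, sc$b, method = "radix")
  expect_equal(key, seq_len(nrow(sc)))
})

test_that("ordering fractions are antisymmetric on tie-free data", {
  sim <- simulate_reo_cohort(n_features = 20, n_control = 15, n_case = 5,
                             n_stable_pairs = 5, n_reversed_pairs = 0,
                             target_delta_p = 0.5, noise_sd = 80, seed = 10)
  ctrl <- names(sim$labels)[sim$labels == "control"]
  feats <- rownames(sim$x)[1:8]
  for (a in feats) for (b in feats) {
    if (a >= b) next
    expect_equal(pair_fraction(sim$x, a, b, ctrl) +
                 pair_fraction(sim$x, b, a, ctrl), 1)
  }
})

test_that("delta_p is bounded and extreme only at complete reversal", {
  sim <- simulate_reo_cohort(n_features = 40, n_control = 25, n_case = 25,
                             n_stable_pairs = 8, n_reversed_pairs = 4,
                             stable_hold_fraction = 0.96, target_delta_p = 0.8,
                             noise_sd = 200, seed = 12)
  sc <- screen_candidates(sim$x, sim$labels, "control", "case",
                          delta_p_threshold = 0, fdr = 1.1, keep_all = TRUE)
  expect_true(all(sc$delta_p >= -1 & sc$delta_p <= 1))
  at_one <- sc$delta_p == 1
  expect_equal(at_one, sc$p_control == 1 & sc$p_case == 0)
  expect_true(all(sc$q_value >= sc$p_value))
  expect_equal(sc$n1 + sc$n2, rep(25L, nrow(sc)))
  expect_equal(sc$m1 + sc$m2, rep(25L, nrow(sc)))
})

test_that("screen results are unchanged by a monotone per-sample transform", {
  sim <- simulate_reo_cohort(n_features = 50, n_control = 20, n_case = 20,
                             n_stable_pairs = 10, n_reversed_pairs = 5,
                             noise_sd = 120, seed = 13)
  base <- screen_candidates(sim$x, sim$labels, "control", "case",
                            delta_p_threshold = 0.5)
  set.seed(99)
  warped <- distort_cohort(sim$x)
  expect_identical(screen_candidates(warped, sim$labels, "control", "case",
                                     delta_p_threshold = 0.5), base)
})
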