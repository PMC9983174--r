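---
title: "Rank-based pair panels: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based pair panels: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reopair)
```

## The model

The unit of signal is an ordered feature pair (a, b) read qualitatively
within one sample: either `E_a > E_b` or `E_a ≤ E_b`. The working
assumption is that in a reference ("control") phenotype the ordering of
some pairs is almost deterministic — the fraction

$$P(E_a > E_b) = k/m$$

over the $m$ control samples is close to 1 — while a disease state
perturbs the underlying regulation enough to reverse the ordering in case
samples. A pair that is *stable* in controls
($P \ge \theta$, default $\theta = 0.95$) and whose ordering distribution
differs significantly between phenotypes (two-sided Fisher's exact test on
the 2×2 ordering-count table, Benjamini–Hochberg FDR < 5% over the
stable-pair family) is a *reversed* pair; the effect size is
$\Delta P = P_{control} - P_{case}$, with $\Delta P = 1$ denoting complete
reversal. A panel of such pairs classifies a single sample by majority
vote, and because each vote is a within-sample comparison, the classifier
is exactly invariant to any strictly increasing per-sample transform.
That invariance is not an approximation: it is checked bit-for-bit in the
test suite and is the reason the method needs no normalization at
prediction time.

Two assumptions deserve emphasis. First, stability is a property of the
*reference* phenotype only; the screen is asymmetric by construction and
both orientations (a, b) and (b, a) are enumerated. Second, the Fisher
test treats samples as exchangeable within phenotype; technical replicates
or strong within-cohort substructure would violate it.

## Parameters that matter

| parameter | default | meaning, units, rationale |
|---|---|---|
| `stability_threshold` | 0.95 | minimal control fraction for a stable pair; 0.80 is a useful relaxation when the "control" group is itself heterogeneous (e.g. a mixture of other diseases) |
| `fdr` | 0.05 | BH false discovery rate over the stable-pair family |
| `delta_p_threshold` | 1 | minimal reversal degree, inclusive; 1 selects only complete reversals, 0.7 is the usual relaxed preset for specificity panels |
| `vote_threshold` | `⌊k/2⌋` | control votes strictly required to call control; the strict-majority default makes a 32-pair panel call case at exactly 16 votes. Published rules occasionally differ (a 5-pair panel calling control only above 3 votes), so the threshold is an explicit model field rather than a hidden convention |
| `qc_sd_multiple` | 2 | width, in standard deviations, of the retention band for mean inter-sample correlation |

## Numerical and procedural choices

* **Ties.** Equal intensities count as `E_a ≤ E_b` everywhere (screening,
  coverage, voting), matching the exhaustive dichotomy `>` vs `≤`. On
  continuous data ties have probability zero; on heavily rounded data the
  convention biases votes toward the case pattern, which is documented
  rather than hidden.
* **Enumeration order.** Features are ordered lexicographically by id in
  the C locale; pair enumeration, candidate tables, tie-breaks in greedy
  growth and activity ranking all derive from this single order, making
  every stage deterministic.
* **"Outside" is strict.** A QC sample at exactly `center ± 2·SD` is
  retained; QC runs one pass and does not iterate. A zero-variance sample
  (undefined correlation) is removed and reported as `NA`.
* **Fisher's exact test** is computed as the sum of hypergeometric point
  masses not exceeding that of the observed table (with the customary
  `1 + 1e-7` relative tolerance, the same convention as
  `stats::fisher.test`, against which it is tested). The implementation
  is vectorized and memoizes repeated tables: during a screen all tables
  share the two group sizes, so only the distinct `(n1, m1)` combinations
  are ever evaluated — this is what makes screening millions of pairs
  tractable. Degenerate margins return p = 1.
* **BH family.** Adjustment runs over exactly the stable pairs, not over
  all `n(n−1)` pairs: only stable pairs are tested, and the family follows
  the tests.
* **Blocked screening.** Pair counting materializes feature-block ×
  feature count matrices, never a pairs × samples boolean array, so a
  2,550-feature screen fits comfortably in memory.
* **Greedy coverage.** Combination growth adds, each round, the candidate
  with the largest strict coverage gain (first candidate wins ties) and
  stops at the first round with zero best gain; candidates skipped in an
  earlier round are reconsidered later. The greedy result is checked
  against exhaustive recomputation on small instances in the tests; no
  claim of global optimality is made.
* **Undefined predictive values.** An empty predicted class makes PPV or
  NPV undefined; they are reported as `NA` and enter the geometric mean as
  0, a conservative choice that prevents degenerate one-class panels from
  winning the k-selection.
* **Panel-size selection** evaluates every k on the training samples and
  returns the smallest k attaining the global maximum of
  `sqrt(NPV × PPV)`. No held-out split is used for k — the screening and
  selection cohorts coincide by design, so training metrics are optimistic
  and external validation is essential.

## What the generator emulates — and what it does not

`simulate_reo_cohort()` draws log-normal baseline feature levels (median
≈ 10⁴ intensity units, matching the order of magnitude of array
intensities) with additive Gaussian noise, plants stable pairs on
disjoint feature pairs, and enforces ordering directions by swapping the
two planted features' values within chosen samples. The swap construction
makes the realized holding fractions *exact* for any seed (the smallest
count consistent with the target on the control side, the largest on the
case side), which keeps recovery properties sharp under arbitrary seeds;
the recorded ground truth carries the realized fractions. Anti-correlated
outlier samples (rank-reversed mean profiles) exercise the QC rule, and
strictly monotone per-sample distortions (scaling, log, batch shifts)
exercise the invariance claim.

The generator deliberately does **not** emulate real serum data:
inter-feature correlation structure, platform-specific intensity
distributions, probe saturation, or biological heterogeneity within a
phenotype. Passing tests on synthetic cohorts therefore demonstrate
algorithmic correctness — recovery of planted structure, exact invariance,
agreement with enumeration oracles — not clinical performance. Null pairs
in the generator arise incidentally from baseline level differences, which
is enough to produce realistic screening funnels (thousands of stable
pairs, few reversed ones) but not to calibrate real-data false discovery
behavior.

## Open design points and how they were resolved

* The "natural order" in which equally good complete-reversal candidates
  are taken for a direct panel is not canonically defined; lexicographic
  feature-id order was chosen and is applied consistently, so direct
  panels are reproducible across runs and machines.
* Whether correlations for QC are computed on raw or log intensities is a
  genuine free choice; raw Pearson was chosen as the simplest reading of
  "correlation between expression levels", and the QC decision is in any
  case invariant under common positive rescaling.
* The candidate rule uses an inclusive threshold (`ΔP ≥ t`), and the vote
  rule an exclusive one (votes `> threshold`), mirroring how the worked
  analyses they come from are phrased; both are parameters, not
  constants.
* Student's equal-variance t-test is the default for per-feature
  differential expression (Welch via `var_equal = FALSE`), run on raw
  intensities with a `log2` flag — differential expression here is
  descriptive companion output, not part of the panel construction.

## Problem sizes

The test suite and the acceptance script run on cohorts of 20–200
features and 20–143 samples, with planted panels of 1–20 pairs; the
exhaustive coverage oracles run on fixtures of at most 8 candidates × 12
samples, and the exact-test enumeration covers all 2×2 tables with
margins up to 12. These sizes were chosen so that every brute-force
oracle remains exact and the whole suite completes in about a minute on
one CPU; the algorithms themselves (blocked counting, memoized exact
tests) are the ones that scale to array-sized screens of ~6.5 million
ordered pairs.

## Known limitations

* Hard voting only: no probabilistic output, no ROC analysis, no
  abstention; panels are evaluated purely through confusion metrics.
* k-selection on the training set can overfit small cohorts; the curve is
  returned so users can inspect flat maxima.
* Missing values are a hard error by design — the method has no principled
  imputation for orderings, and silently imputing would corrupt the
  invariance guarantee.
* The greedy maximum-coverage construction is a heuristic; activity
  scores inherit its tie-break conventions, and a different enumeration
  order would yield a (equally valid) different ranking.
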