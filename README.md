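# reopair

Qualitative diagnostic biomarker panels from within-sample **relative
expression orderings (REOs)** of feature pairs, as used for serum microRNA
diagnostics.

## The problem and who this is for

Quantitative expression biomarkers (composite scores of miRNA intensities)
are fragile in practice: intensities shift with batches, platforms,
normalization choices and RNA handling, so models trained on one cohort
often fail on the next. The REO idea sidesteps this. For an ordered feature
pair (a, b), the only thing read from a sample is the binary event

    E_a > E_b   versus   E_a ≤ E_b

which is invariant under *any* strictly increasing transform of that
sample's values — scaling, log, quantile shifts, batch offsets. A panel of
such pairs yields a single-sample classifier that needs no normalization
at prediction time. This package is for computational biologists building
or evaluating such rank-based panels on feature-by-sample intensity
matrices (bulk transcriptomics, serum miRNA arrays, and similar).

## The method

Given a training cohort with control and case phenotypes:

1. **QC.** Within each phenotype, every sample's mean Pearson correlation
   with the other samples of that phenotype is computed; samples whose
   mean lies outside `mean ± 2·SD` of the per-sample means are removed
   (single pass).
2. **Stable pairs.** All `n(n−1)` ordered pairs are screened; a pair is
   *stable* when `P(E_a > E_b) = k/m ≥ θ` in the controls (default
   θ = 0.95). Ties count on the `≤` side.
3. **Reversed pairs.** For every stable pair the 2×2 table of ordering
   counts `[[n1, n2], [m1, m2]]` (controls vs cases) is tested with
   Fisher's exact test, two-sided, with Benjamini–Hochberg control over
   the stable-pair family (FDR < 5%). The reversal degree is
   `ΔP = P_control(E_a > E_b) − P_case(E_a > E_b)`; candidates must reach
   a threshold (`ΔP = 1` is complete reversal).
4. **Panel selection.** Either take the first few candidates in
   lexicographic order (natural when `ΔP = 1`), or rank candidates by
   **activity score** — the number of greedily grown maximum-sample-coverage
   combinations (one seeded per candidate) that contain the pair — and
   keep the smallest top-k panel whose training geometric mean
   `√(NPV × PPV)` first attains its maximum.
5. **Prediction.** A sample is called control iff the number of panel
   pairs showing `E_a > E_b` strictly exceeds the vote threshold
   (default: strict majority `⌊k/2⌋`), else case. Performance is reported
   as SEN/SPE/ACC/PPV/NPV with the case phenotype as positive class.

## Worked example

```r
library(reopair)

## a synthetic serum-like cohort: 150 features, 60 controls + 40 cases,
## 12 planted stable pairs of which 6 are fully reversed in the cases,
## additive noise, and 2 injected outlier samples
sim <- simulate_reo_cohort(n_features = 150, n_control = 60, n_case = 40,
                           n_stable_pairs = 12, n_reversed_pairs = 6,
                           noise_sd = 120, outlier_samples = 2, seed = 11)

fit <- reo_fit(sim$x, sim$labels, "control", "case",
               mode = "direct", panel_size = 5, vote_threshold = 3)
fit
#> REO biomarker panel fit (mode: direct)
#>   pairs: stable 10697 -> reversed 19 -> candidates 6
#>   panel: 5 pair(s), vote threshold 3
#>   training acc 100.00%, sqrt(NPV*PPV) 1.0000
```

The stage counts mirror the screening funnel: 10,697 ordered pairs are
stable in the controls, 19 reverse significantly in the cases, 6 reverse
completely (`ΔP = 1`), and the first five in lexicographic order form the
panel. The panel pairs and their screening statistics:

```r
coef(fit)[, c("a", "b", "p_control", "p_case", "delta_p", "q_value")]
#>         a       b p_control p_case delta_p      q_value
#> 1 mir0037 mir0114         1      0       1 8.230716e-25
#> 2 mir0038 mir0039         1      0       1 8.230716e-25
#> 3 mir0052 mir0059         1      0       1 8.230716e-25
#> 4 mir0058 mir0050         1      0       1 8.230716e-25
#> 5 mir0072 mir0092         1      0       1 8.230716e-25
```

`p_control = 1, p_case = 0` means each pair's ordering holds in every
control and in no case sample. Validation on a fresh cohort from the same
generative process:

```r
valid <- simulate_reo_cohort(n_features = 150, n_control = 60, n_case = 40,
                             n_stable_pairs = 12, n_reversed_pairs = 6,
                             noise_sd = 120, seed = 12, structure_seed = 11)
evaluate_predictions(predict(fit, valid$x), valid$labels, "case")
#> Classification metrics (case = positive)
#>   SEN 100.00%  SPE 100.00%  ACC 100.00%
#>   PPV 100.00%  NPV 100.00%  sqrt(NPV*PPV) 100.00%
#>   confusion: tp = 40 fp = 0 tn = 60 fn = 0
```

Because predictions depend only on within-sample orderings,
`predict(fit, log(valid$x))` and `predict(fit, 1000 * valid$x)` give
identical calls.

For heterogeneous control groups where complete reversal is too strict,
use the coverage path: `reo_fit(..., delta_p_threshold = 0.7,
mode = "coverage")` ranks candidates by activity score and picks the panel
size from the geometric-mean curve (`plot(fit)` shows it).

## Command-line use

```sh
Rscript inst/cli/reopair.R simulate --out work --seed 5
Rscript inst/cli/reopair.R discover --matrix work/matrix.tsv --labels work/labels.tsv \
    --control-label control --case-label case --mode direct --panel-size 5 --out work
Rscript inst/cli/reopair.R predict --matrix work/matrix.tsv --model work/model.json --out work
Rscript inst/cli/reopair.R evaluate --predictions work/predictions.tsv \
    --labels work/labels.tsv --case-label case --out work
```

Exit codes: 0 success, 2 validation error, 3 empty screen (no candidate
pairs).
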