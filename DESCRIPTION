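Package: reopair
Title: Qualitative Biomarker Panels from Within-Sample Relative Expression Orderings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and application of rank-based qualitative biomarker
    panels built from the within-sample relative expression ordering (REO) of
    feature pairs, as used for serum microRNA diagnostics. Screens ordered
    feature pairs whose direction is stable in a reference phenotype and
    significantly reversed in a case phenotype (Fisher's exact test with
    Benjamini-Hochberg control and a reversal-degree threshold), selects a
    compact panel by greedy maximum-sample-coverage activity scoring and the
    geometric mean of predictive values, and classifies single samples by
    majority vote over panel pairs. Includes correlation-based outlier sample
    removal, per-feature differential expression, a synthetic cohort generator
    with planted ordering structure, and JSON model serialization. Because
    predictions depend only on within-sample orderings they are invariant to
    any monotone per-sample transform, hence robust to batch effects and
    normalization choices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
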