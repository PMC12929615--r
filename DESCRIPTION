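Package: patchlogit
Title: Self-Explainable Patch-Based Image Classification with Mean-Logit
    Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Patch-based multi-label image classification whose prediction is
    the sigmoid of the arithmetic mean of independent per-patch logits, so the
    per-patch contribution to every decision is exact by construction. Provides
    the partition/encode/aggregate arithmetic, raw and probability-scaled patch
    saliency maps with shift-and-average smoothing, a complete weakly
    supervised localization evaluation protocol (pointing-game hit rate, mean
    intersection-over-union across true positive, false positive and false
    negative cases, per-label threshold tuning, Youden classification
    thresholds, percentile bootstrap confidence intervals), a seeded training
    loop with the standard augmentation pipeline, and a synthetic
    chest-phantom generator with exact pixel ground-truth masks and optional
    shortcut (corner-marker) contamination for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), methods
Imports:
    stats,
    utils,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
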