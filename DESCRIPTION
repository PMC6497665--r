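Package: ethoindex
Title: Behaviour Indices for One-on-One Ethogram Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scores one-on-one encounter assays from per-second ethogram
    records on an ordinal peaceful-to-aggressive scale and computes five
    dyadic behaviour indices: the Aggression Index (AI), the Mean Maximum
    Aggression and Peace Indices (MMAI, MMPI), and the threshold-buffered
    Mean Behaviour Indices (MBI aggressive and peaceful). Includes the MBI
    decision cascade with empirical time-threshold selection by scanning
    classification counts, a Monte-Carlo encounter simulator covering eight
    behavioural scenarios, long-format ethogram CSV input/output with
    scoring-scale translation, and nonparametric index comparison
    (Spearman correlation, Wilcoxon-Mann-Whitney, Bonferroni-Holm).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
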