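Package: regenscreen
Title: Regeneration-Specificity Screening and Developmental-Shift Analysis
    for Limb Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Comparative-transcriptomics toolkit for studying how limb
    regeneration re-runs the developmental program. Implements the
    three-step screen for regeneration-specific genes built on a fixed
    12-condition development/regeneration design, including an exact
    negative-binomial differential-expression test, TPM/CPM/log/z-score
    normalization, and the 0-8 regeneration-specificity point score;
    single-cell marker detection under FDR, fold-change and
    percent-expressed criteria; and the developmental-shift concordance
    statistic that quantifies how a perturbation moves a blastema's
    expression profile toward the limb-bud state. A synthetic-data module
    generates negative-binomial bulk and single-cell datasets with planted
    ground truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
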