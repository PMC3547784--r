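Package: confcal
Title: Confidence Calibration Analysis for Dichotomous Clinical Risk Judgments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the calibration of confidence ratings attached
    to dichotomous clinical risk-assessment judgments. Implements the classic
    binned calibration score, over/underconfidence index, resolution and
    normalised resolution statistics, reliability-diagram (calibration curve)
    construction with a configurable low-confidence exclusion rule, Modified
    Early Warning Score (MEWS) scoring of five-cue vital signs with
    score/outcome-concordance difficulty labelling, and the inferential stage
    (pooled-variance t tests, Wilcoxon rank-sum, factorial ANOVA with
    interactions) used to compare judge groups and experimental conditions.
    A synthetic judge-cohort generator with known ground-truth bias and
    precision parameters makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
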