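Package: capstate
Title: Coactivation-Pattern Analysis of Transient Brain Network States
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Frame-wise coactivation-pattern (CAP) analysis for
    parcellated resting-state fMRI: identifies transient network states by
    k-means clustering of individual frames, selects the state count by
    the elbow method, and quantifies each state's spatial stability
    (distance to center, multi-site reproducibility, individual-level
    stable activation rate) and temporal behavior (dwell time, transition
    probabilities). Includes empirical-Bayes site harmonization,
    mixed-design ANOVA and covariate-adjusted group tests with false
    discovery rate correction, residualized correlations with symptom
    scores, permutation-tested canonical correlation analysis, and a
    synthetic multi-site cohort generator with planted states and full
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    car,
    sva,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
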