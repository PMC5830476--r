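Package: wfstox
Title: Weighted Feature Significance Models for Adverse Drug Effect Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates Weighted Feature Significance (WFS) models
    that predict adverse drug effects (ADEs) from sparse binary compound
    profiles: quantitative high-throughput screening (qHTS) assay activity
    calls, drug-target annotations (DTAs), structure fingerprint bits, and
    animal toxicity endpoints. Per-feature enrichment is scored with one-sided
    Fisher's exact tests to form a comprehensive feature fingerprint per
    adverse effect; drugs are then scored by a normalized sum of log
    p-values penalized for unannotated features. Includes a repeated 50/50
    holdout evaluation protocol with AUC-ROC and balanced accuracy,
    label- and annotation-permutation null models, univariate feature
    screening with threshold selection, triplicate assay reproducibility
    scoring, and a synthetic data generator with latent compound-target
    structure for end-to-end validation and parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    ggplot2,
    dplyr
Config/testthat/edition: 3
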