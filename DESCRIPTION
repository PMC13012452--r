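Package: spirokit
Title: Spirometry Curve Analysis, Cohort Quality Control, and
    Interpretable COPD Report Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for forced-expiratory spirogram analysis.
    Simulates flow-volume maneuvers with controllable obstructive
    ("scooped") morphology, computes the standard pulmonary function
    indices (FVC, FEV1, PEF, FEF25-75, FEF75) with LMS-based predicted
    values, lower limits of normal, and z-scores, runs a reproducible
    cohort quality-control pipeline (outlier trimming, blow-consistency
    filtering, class balancing, label-consistency screening, stratified
    splitting), trains a compact CNN-BiLSTM encoder for COPD probability
    with activation-map saliency, aligns encoder features to a language
    model embedding space through a two-layer projector, drafts
    guideline-grounded diagnostic reports via lexical retrieval and a
    deterministic rule engine, and evaluates generated reports with a
    six-dimension rubric, diagnosis extraction, AUROC/AUPRC/F1, and
    bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
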