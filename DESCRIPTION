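Package: edscores
Title: Emergency Department Physiologic Severity Scores and Mortality
    Prediction Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calculators for four emergency department physiologic severity
    scores (RAPS, REMS, MEWS, MEDS) with explicit band-boundary conventions,
    a seeded synthetic patient cohort generator calibrated to published
    survivor and non-survivor marginal distributions, and a mortality
    prediction evaluation toolkit: exact and normal-approximation
    Mann-Whitney U tests, Fisher's exact test, univariate logistic
    regression by iteratively reweighted least squares, ROC/AUROC analysis
    with Youden-index cutoff selection, and confusion-matrix test
    characteristics. Includes an end-to-end seeded study pipeline and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
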