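Package: hormetrics
Title: Hormetic Dose-Response Quantification and Biomarker Association
    for Organoid Drug Screens
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies drug response in patient-derived organoid panels
    using four complementary viability measures: replicate-median
    trapezoidal AUC and interpolated IC50, and fitted AUC and IC50 from a
    five-parameter hormetic model (a two-parameter logistic decline plus a
    scaled normal-density growth peak at low doses) estimated by bounded
    nonlinear least squares with a random-restart fallback. Downstream,
    samples are classified into monotonous and non-monotonous responders,
    somatic mutation records are filtered, binarized and grouped into
    collinear feature groups, expression matrices are mean-centered and
    variance-filtered, and features are associated with response via
    Welch t-tests (Benjamini-Hochberg adjusted), Pearson correlation
    screens and a two-of-four-measures robustness rule. A seeded
    synthetic-cohort generator with planted ground truth makes the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
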