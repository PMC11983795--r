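Package: epiperform
Title: Stratified Performance Evaluation of Epigenetic Predictors
Version: 0.1.0
Authors@R:
    person("NHANES", "Epigenetics Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Evaluates DNA methylation-based predictors of phenotypic traits
    (epigenetic clocks, telomere length, plasma proteins, leukocyte
    proportions) within demographic strata. Implements the quality-control
    and unit-conversion rules used for paired laboratory/DNAm biomarker
    tables, stratified Pearson correlation and median absolute error,
    percentile-bootstrap inference on between-group differences in those
    metrics (including an equal-n sensitivity variant), and
    interaction-term linear regression with a fixed Bonferroni budget.
    Ships a synthetic cohort generator with controllable group-specific
    correlation structure, injectable outliers, top-coded ages,
    sex-prediction mismatches and per-measure missingness, so every
    pipeline stage can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
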