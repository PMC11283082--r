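Package: serialbias
Title: Serial-Dependence Analysis for Orientation Adjustment Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying serial dependence in continuous-report
    (orientation adjustment) experiments. Computes signed circular
    adjustment errors in the 180-degree orientation space, applies a
    multi-stage exclusion cascade (lapse, systematic-bias removal via a sum
    of six sinusoids, interquartile-range outliers, slow response times),
    fits the first-derivative-of-Gaussian bias tuning curve with a
    grid-initialised bounded least-squares procedure, and performs
    permutation (sign-shuffle and condition-label-shuffle) and bootstrap
    inference on its half-amplitude and width parameters. Includes a
    synthetic observer generator that reproduces the structure of a
    dual-task working-memory-load design (alternating no-load and load
    trials, constrained stimulus sequences), per-participant error-scatter
    analysis with paired t-tests, Cohen's d and scaled JZS Bayes factors,
    and an end-to-end pipeline with a structured run report.
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
    minpack.lm,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
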