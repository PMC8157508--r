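Package: dentiv
Title: Instrumental-Variable Analysis of Tooth Loss and Depression via
    Childhood Water Fluoridation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for a natural-experiment analysis of the causal effect of
    tooth loss on depressive symptoms, using staggered county-level water
    fluoridation rollout as an instrument for adult tooth loss. Provides
    construction of the cumulative childhood fluoride-exposure instrument
    from county fluoridation histories, BRFSS-style tooth-loss bracket
    coding, PHQ-8 depression scoring, a from-scratch two-stage least squares
    estimator with weak-instrument diagnostics and robust covariance, a
    study pipeline (main, dichotomised, stratified, item-level and
    sensitivity analyses), and a synthetic-population generator with a
    known causal effect for estimator-recovery testing.
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
    sandwich,
    withr,
    optparse
Config/testthat/edition: 3
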