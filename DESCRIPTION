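Package: tremorspec
Title: Quantitative Spectral Analysis of Hand-Tremor Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantitative analysis of rest and postural hand-tremor
    acceleration recordings, built around a Welch power spectrum restricted to
    the 0.9-15 Hz tremor band. Computes the five classical spectral tremor
    parameters (intensity, center frequency, frequency dispersion, band energy
    distribution, harmonic index), provides a calibrated synthetic-cohort
    generator emulating occupationally exposed welders, de novo Parkinson's
    disease, and essential-tremor groups, a cohort statistics layer (group
    summaries, rest-vs-postural fold changes with paired t-tests, two-way
    ANOVA variance partitions, Fisher exact tests on clinical-sign tables,
    covariate regressions), and a transparent rule-based group classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr
Config/testthat/edition: 3
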