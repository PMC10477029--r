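Package: ropscreen
Title: Weight-Gain-Based Screening Algorithms for Retinopathy of Prematurity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements and evaluates postnatal weight-gain-based alarm
    algorithms for retinopathy of prematurity (ROP) screening: the G-ROP
    six-criterion rule set, the CO-ROP day-28 weight-gain rule, the CHOPROP
    logistic risk score, and an eligibility gate plus label adapter for the
    proprietary WINROP service. Provides longitudinal weight-series
    primitives (nearest-day lookup with tolerance, windowed gains, weekly
    daily-gain rates, postmenstrual-age arithmetic), a full diagnostic
    evaluation stage (confusion tables per endpoint, Wilson score intervals,
    predictive values, likelihood ratios with log-method intervals, and
    exam-reduction analysis), a calibrated synthetic neonatal cohort
    generator, and a small command-line pipeline tying simulation,
    screening and evaluation into one reproducible run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
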