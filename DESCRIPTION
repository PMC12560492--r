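Package: lcmediate
Title: Time-Sequenced Causal Mediation Analysis for Life-Course Cohort Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for regression-based causal mediation analysis of
    childhood adversity, time-ordered behavioural mediators (smoking,
    overweight) and adult disease in large population cohorts. Derives
    exposures from the five-item Childhood Trauma Screener, enforces a
    strict time sequence between mediator onset and age at first
    diagnosis, estimates risk ratios with log-link Poisson-mean
    regressions and robust (sandwich) standard errors, and decomposes
    exposure effects into natural direct and indirect components on the
    risk-ratio scale (two-way) and the excess-relative-risk scale
    (four-way, with mediated and reference interaction), with
    delta-method or bootstrap confidence intervals. Includes a synthetic
    cohort generator with analytically known ground-truth mediation
    effects so every stage of the pipeline can be validated without
    access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
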