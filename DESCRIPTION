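Package: glycofit
Title: Patient-Wise Glycemic Health Assessment from 5-Point OGTT Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess glycemic health status from oral glucose
    tolerance tests with insulinemia (5-point OGTT-I). Simulates and fits a
    five-compartment glucose-insulin compartmental model to per-subject
    curves, derives physiological rate parameters and dimensionless
    subsystem indices, constructs cohort-based normal/undesirable/abnormal
    diagnostic ranges from log-logistic distribution fits, quantifies
    subsystem coordination through correlation graphs and community
    detection, computes a logistic dysglycemia-risk probability, and
    evaluates dose-dependent nutritional interventions in paired crossover
    designs. Includes a synthetic-cohort generator so the full pipeline is
    exercisable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
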