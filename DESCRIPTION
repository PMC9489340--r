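Package: hfmarkov
Title: Markov Cohort and Survival Modelling of Long-Term Heart Failure Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing long-term outcomes in two-arm heart-failure
    cohorts followed at 6-month intervals. Provides derived echocardiographic
    indices (Devereux left ventricular mass, body surface area, LVMI),
    baseline-characteristics tables with automatic test dispatch, a
    Kaplan-Meier / log-rank / nested Cox proportional-hazards pipeline with
    time-dependent ROC and subgroup sensitivity analysis, and a five-state
    absorbing discrete-time Markov cohort model (NYHA I-IV plus a composite
    cardiovascular-event state) that estimates 6-month transition
    probabilities from paired observations, cycles them to 60 months, and
    validates predictions with a chi-square goodness-of-fit test. A synthetic
    cohort generator with a truth ledger stands in for confidential patient
    data and supports parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
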