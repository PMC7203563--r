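Package: renalrisk
Title: Kidney Failure Risk Prediction After Acute Kidney Injury Under
    Competing Risks
Version: 0.1.0
Authors@R:
    person("PROMIS", "Replication Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying long-term kidney failure risk after acute
    kidney injury (AKI) in nephrology clinic cohorts. Implements a
    KDIGO-based three-criterion AKI e-alert detector over longitudinal
    serum creatinine, the 2009 CKD-EPI creatinine eGFR equation, outcome
    adjudication (long-term renal replacement therapy or sustained
    eGFR < 15 mL/min/1.73 m2), landmark cohort construction avoiding
    immortal time bias, cause-specific Cox and Fine-Gray subdistribution
    hazard modelling, evaluation of the published 5-year kidney failure
    risk equation (KFRE) against refitted competing-risk models with and
    without AKI, model validation (AUC, DeLong comparison, calibration
    slope and deciles, decision-curve net benefit), and a synthetic
    cohort generator so the full pipeline is testable without registry
    access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
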