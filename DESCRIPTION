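Package: rocascreen
Title: Serial-Biomarker Risk Algorithm and Multimodal Ovarian Cancer
    Screening Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for longitudinal-biomarker cancer screening analysis
    built around serial CA-125 interpretation. Implements a change-point
    risk-of-ovarian-cancer calculation that compares a woman's serial
    CA-125 profile under a flat (healthy) lognormal model and a
    change-point exponential-rise (case) model, the multimodal screening
    triage state machine (annual level I CA-125, repeat testing,
    level II transvaginal ultrasound, clinical evaluation), a synthetic
    screening-cohort simulator with preclinical case kinetics and
    interval cancers, and a performance-evaluation suite (sensitivity,
    specificity, positive predictive value with exact binomial intervals,
    ROC curves, AUC, and the DeLong test for paired AUC differences).
    Bundles the published incidence-screening outcome counts of the UK
    Collaborative Trial of Ovarian Cancer Screening as a machine-readable
    fixture for worked-example arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
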