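Package: glycotraj
Title: Glycemic Variability, Glucose Trajectories and ICU Delirium Risk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the first-24-hour blood-glucose course of
    ICU patients in relation to postoperative delirium. Computes classical
    glycemic variability indices (mean blood glucose, mean absolute glucose
    change rate, mean amplitude of glycemic excursions, glycemic lability
    index, largest amplitude of glycemic excursion) from sparse 4-hourly
    glucose series; classifies 24-hour trajectories with a latent growth
    mixture model (quadratic growth curves with a patient-level random
    intercept, fitted by EM) and a four-condition class-selection protocol;
    fits nested logistic-regression ladders and subgroup analyses for the
    association of each exposure with delirium; and quantifies additive
    interaction between glycemic exposures and hepatorenal markers via the
    relative excess risk due to interaction (RERI) and attributable
    proportion (AP) with delta-method or bootstrap confidence intervals.
    Includes a cohort-definition engine (ICD-code phenotyping, exclusion
    rules, RASS/CAM-ICU delirium adjudication) and a synthetic-cohort
    generator for fully reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
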