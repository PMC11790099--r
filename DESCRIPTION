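Package: ehrcausal
Title: Target Trial Emulation and Robust Treatment-Effect Estimation for
    Longitudinal EHR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A step-by-step pipeline for estimating causal treatment effects
    from longitudinal electronic health record (EHR) data by emulating a
    target trial.  Provides a synthetic ICU data generator with known
    potential outcomes and severity-driven confounding; a PICOT cohort
    builder with selection flowcharts and a tunable eligibility window that
    can deliberately induce immortal time bias; pre-treatment covariate
    aggregation, median imputation and one-hot encoding; average
    treatment-effect estimation (risk difference, risk ratio, odds ratio)
    via inverse propensity weighting, G-formula T-learner, augmented IPW
    (AIPW) and double machine learning with cross-fitted random-forest or
    ridge-logistic nuisance models and bootstrap confidence intervals;
    vibration (multiverse) analyses over eligibility windows, confounder
    sets, aggregation strategies and estimators; and conditional average
    treatment-effect estimation with a DR-learner and subgroup summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    grDevices,
    graphics,
    jsonlite,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
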