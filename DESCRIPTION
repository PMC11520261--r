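Package: drclaims
Title: Doubly Robust Comparative Effectiveness of Glucose-Lowering Therapies from Insurance Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: New-user, active-comparator cohort construction from insurance
    claim streams and doubly robust (augmented inverse-probability-weighted)
    estimation of the 5-year heart-failure-rate difference between insulin and
    alternative glucose-lowering drug classes in type 2 diabetes. Includes a
    seeded synthetic claims generator with closed-form and Monte Carlo ground
    truth, high-dimensional phecode feature processing (prevalence filtering,
    mean imputation, comorbidity principal components), an age-spline
    interaction design shared by the propensity and outcome models, adaptive
    LASSO nuisance fits, inverse-probability-of-treatment weighting with
    balance diagnostics and weighted Kaplan-Meier curves, influence-function
    inference, and score-based treatment-effect heterogeneity (CATE) analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    graphics,
    jsonlite,
    splines,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
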