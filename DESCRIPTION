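Package: boolereg
Title: Logic Regression for Provider-Effect Discovery in Surgical Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Boolean-tree ("logic") regression for binary treatment-delivery
    endpoints in registry cohorts.  Covariates are adaptively constructed
    and/or/not combinations of binary predictors, searched by simulated
    annealing inside a logistic model scored by binomial deviance, with model
    complexity chosen by repeated stratified ten-fold cross-validation.
    Includes a synthetic claims-registry cohort generator with planted
    Boolean outcome rules, binary recoding of mixed-type covariates,
    descriptive cross-tabulations with chi-square screens, and ROC/AUC
    model evaluation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
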