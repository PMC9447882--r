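Package: ohcasweep
Title: Counterfactual Time-Factor Sweeps for Out-of-Hospital Cardiac
    Arrest Prognostic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a class-weighted three-layer neural prognostic model on
    Utstein-style prehospital cardiac-arrest records and quantifies the joint
    effect of simultaneously modifying two emergency-medical-service time
    factors via counterfactual sweeps rendered as relative-change heatmaps.
    Includes a synthetic cohort generator with a known logistic outcome model
    (including transport-by-intervention interactions) so that every stage of
    the pipeline, from feature encoding and stratified cross-validation to
    two-factor interaction grids, is verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    Rcpp,
    jsonlite,
    pROC,
    scales,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
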