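Package: nbsides
Title: Predictive Biomarker Screening and Subgroup Identification for
    Exacerbation Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A structured biomarker analysis plan for biomarker-stratified
    asthma exacerbation trials: simulation of trials with negative-binomial
    exacerbation counts, correlated right-skewed baseline biomarkers and
    longitudinal secondary endpoints; screening of candidate biomarkers for
    predictive (treatment-modifying) effects with negative-binomial
    regression and exposure offsets; a count-outcome SIDES (Subgroup
    Identification based on Differential Effect Search) algorithm; bootstrap
    quantification of cut-off uncertainty and a permutation null for the
    best-subgroup effect; cut-off refinement by grid scan; and
    repeated-measures models for consistency checks on secondary endpoints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    mgcv,
    nlme,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
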