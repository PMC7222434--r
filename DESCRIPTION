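Package: apcProj
Type: Package
Title: Bayesian Age-Period-Cohort Modelling and Projection of Cancer Incidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits registry-style cancer incidence counts with a Bayesian
    age-period-cohort (APC) model in which age, period and cohort effects
    carry second-order random-walk (RW2) smoothing priors with conjugate
    Gamma hyperpriors on the precisions. The posterior is explored by
    Metropolis-within-Gibbs sampling with exact conjugate precision updates,
    future case numbers and age-standardized rates are projected by
    stochastic extension of the period and cohort walks and summarized with
    highest-density intervals, and temporal trends are quantified by the
    average annual percentage change with increase/stable/decrease
    classification. A forecaster benchmark scores competing projection
    models by prediction error rate on a train/test split, and a
    synthetic-registry generator provides ground-truth data so the whole
    pipeline is testable without external registry downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    splines,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
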