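Package: nimopk
Title: Semi-Mechanistic Target-Mediated Population Pharmacokinetics of
    Nimotuzumab
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-steady-state target-mediated drug disposition (TMDD) model
    for the anti-EGFR monoclonal antibody nimotuzumab in autosomal dominant
    polycystic kidney disease, with two-site (central and peripheral) target
    binding and a turnover mediator that stimulates non-specific clearance.
    Provides a compiled ODE simulator for intravenous infusion regimens, a
    virtual phase-I trial generator with log-normal inter-individual
    variability and additive log-scale residual error, a Laplace-approximated
    nonlinear mixed-effects estimator with empirical Bayes estimates and
    shrinkage, stepwise covariate screening, prediction-corrected visual
    predictive checks, nonparametric subject-level bootstrap, and a
    deterministic dose-selection analysis based on time above the
    quasi-steady-state binding constant.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
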