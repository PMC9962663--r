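Package: zaltopk
Title: Population Pharmacokinetic Modelling and Dose Individualization for
    Zaltoprofen
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A population-pharmacokinetic analysis pipeline for the NSAID
    zaltoprofen: closed-form two-compartment first-order-absorption kinetics
    for single, multiple and steady-state oral dosing; a hierarchical
    (nonlinear mixed-effects) parameter model with creatinine-clearance,
    albumin and CYP2C9-genotype covariate effects on apparent clearance;
    FOCE-type estimation with eta-epsilon interaction; likelihood-ratio
    stepwise covariate selection; model qualification by CWRES/IWRES
    residual diagnostics, nonparametric bootstrap, visual predictive checks
    and normalized prediction distribution errors; per-subject
    non-compartmental analysis with covariate screening; a synthetic-cohort
    generator emulating a 26-subject bioequivalence design; and Monte-Carlo
    steady-state dosing simulations with covariate-based dose adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    yaml,
    withr
Config/testthat/edition: 3
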