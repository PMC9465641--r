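Package: colipk
Title: Population Pharmacokinetics and Dose Optimization of Intravenous
    Colistin Sulfate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population pharmacokinetic analysis of intravenous
    colistin sulfate in critically ill patients: a two-compartment
    infusion model with renal-function (CrCL) and liver-function (ALT)
    covariates evaluated in closed form, a Laplace-approximation
    nonlinear mixed-effects estimation engine with stepwise covariate
    modeling, bootstrap and prediction-corrected visual predictive
    checks, urinary-excretion (renal clearance) analysis, Monte Carlo
    dose-optimization on fAUC/MIC and average steady-state concentration
    targets, exposure-outcome ROC analysis, and a synthetic-study
    generator emulating a critically-ill TDM cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
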