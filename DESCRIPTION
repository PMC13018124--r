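Package: gabapkpd
Title: Population PK/PD Modelling and Trial Simulation for Gabapentin in
    Neuropathic Pain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint population pharmacokinetic/pharmacodynamic model of oral
    gabapentin in chronic neuropathic pain: a two-compartment model with
    first-order absorption, lag time and linear elimination, renal function
    (eGFR) as a power covariate on apparent clearance, and an effect-compartment
    Imax model on VAS pain scores with the SLC22A2 c.808G>T (OCT2) genotype
    scaling the effect-site influx rate constant. Provides closed-form and
    ODE-based simulation, inter-individual and residual variability with
    left-censoring below the quantification limit, Monte-Carlo clinical trial
    simulation across renal-function stages and genotypes (exposure, pain
    attenuation and probability of target attainment), synthetic study-like
    dataset generation, and Laplace-approximation nonlinear mixed-effects
    estimation with censored likelihood, stepwise covariate selection,
    bootstrap uncertainty and visual predictive checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    pracma,
    stats,
    utils,
    TMB
LinkingTo:
    TMB,
    RcppEigen
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
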