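Package: btkinetics
Title: Kinetic and Thermodynamic Models of IP6-Stimulated Btk Activation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative models of Bruton's tyrosine kinase (Btk) activation
    by inositol hexakisphosphate (IP6): a four-reaction autocatalytic
    trans-autophosphorylation scheme with transient dimerization (deterministic
    mass-action integration plus fixed-step and exact stochastic reference
    integrators), a geometric estimate of the effective Btk concentration on a
    PIP3-containing vesicle surface, a one-site isothermal titration
    calorimetry (ITC) forward model with nonlinear fitting and thermodynamic
    identities, estimators for coupled kinase assays (initial rate,
    Michaelis-Menten Km, four-parameter logistic EC50), seeded synthetic-data
    generators emulating each assay, and a pipeline orchestrator with
    config validation and run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
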