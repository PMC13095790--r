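Package: lymphodose
Title: Blood-Dose NTCP Modelling for Radiation-Induced Lymphopenia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling severe radiation-induced lymphopenia (SRIL)
    from the dose received by circulating blood during thoracic radiotherapy.
    Provides dose-volume histogram (DVH) containers and metrics (mean dose,
    generalized equivalent uniform dose, D_n%, V_nGy, linear-quadratic
    conversions), a Markov-compartment Monte Carlo simulator of the whole-blood
    DVH from organ DVHs and beam delivery times, the Lyman-Kutcher-Burman
    probit NTCP model with maximum-likelihood fitting (free and fixed
    volume-effect parameter), bootstrap confidence intervals, stratified
    cross-validation, goodness-of-fit and calibration analysis (Wilson
    intervals, LOWESS curve, calibration slope and intercept), CTCAE
    lymphopenia grading and absolute-lymphocyte-count decay kinetics, and a
    synthetic cohort generator emulating photon-like and proton-like blood
    dose distributions with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
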