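Package: thram
Title: Bayesian Threshold Animal Models for Ordinal Joint-Score Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits uni- and bivariate threshold (probit liability) animal
    models to ordinal orthopedic screening scores such as hip (1-7) and
    elbow (1-4) dysplasia grades, by Gibbs sampling with latent-liability
    augmentation. Provides pedigree algebra (inbreeding, the numerator
    relationship matrix A and its sparse inverse by Henderson's rules with
    the inbreeding adjustment), liability-scale heritabilities and genetic
    correlations, estimated breeding values with genetic trends by year of
    birth, a four-path (sires-of-sires, sires-of-dams, dams-of-sires,
    dams-of-dams) selection-response decomposition, MCMC convergence
    diagnostics, and a forward pedigree/score simulator with truncation
    selection for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, Matrix
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
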