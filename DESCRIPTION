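Package: carbsens
Title: Kinetic Modelling and Sensitivity Analysis of Plant Carbohydrate
    Metabolism During Cold Acclimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A condensed kinetic model of the central carbohydrate metabolism
    of Arabidopsis thaliana leaves (five pools: F6P, G6P, Suc, Frc, Glc;
    twelve reactions) together with the analysis pipeline built around it:
    steady-state solving, a perturbation-based sensitivity score for net
    photosynthesis variation, metabolic control analysis with summation-theorem
    checks, constrained steady-state parameter calibration across genotype-by-day
    conditions, standardized PCA of sensitivity profiles with a noise-robustness
    test, and a synthetic-study generator so that every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    deSolve,
    digest,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lhs,
    minpack.lm,
    numDeriv,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
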