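Package: rootnet
Title: Neural-Network Surrogate Modelling and Genetic-Algorithm
    Optimisation of Tissue-Culture Rooting Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models in vitro rooting responses of the Prunus rootstock
    G x N15 (root number, root length, rooting percentage, root fresh and
    dry weight) as functions of five macronutrient ion concentrations
    (NO3-, NH4+, K+, Ca2+, Cl-) using small feed-forward neural networks
    (5-8-1, hyperbolic-tangent hidden layer, linear output) trained by
    Levenberg-Marquardt. Ranks ion importance by variable sensitivity
    ratios, and locates medium compositions that maximise each response
    with a real-coded genetic algorithm using the trained network as the
    fitness function. Includes salt-to-ion stoichiometry for macronutrient
    formulations, a replicate-level synthetic-data generator driven by
    published treatment means and standard errors, and a reproducible
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
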