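Package: preypower
Title: Predator-Prey Biomass Power Laws and Intraguild Competition Margins
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for trophic biomass scaling in large-carnivore systems:
    conversion of survey densities to biomass densities, Bayesian log-log
    power-law regression via conjugate Gibbs sampling, joint two-predator
    analysis by canonical correlation with Wilks' lambda significance
    testing, derived marginal (competitor-free) scaling slopes, and a
    competition-gap measure. Includes a seeded synthetic survey generator
    so the full pipeline can be exercised and validated by parameter
    recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
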