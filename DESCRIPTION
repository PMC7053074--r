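Package: multicrypt
Title: Multiscale Simulation of Wnt-Driven Cell Dynamics in the Colorectal Crypt
Version: 0.1.0
Authors@R: person("Crypt", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Couples subcellular Wnt/beta-catenin signalling models to an
    off-lattice cell-centre model of a cylindrical colorectal crypt. Two
    ordinary-differential-equation models of beta-catenin regulation (a
    one-compartment destruction-complex model and a two-compartment
    binding/shuttling model) are parameterised by the local Wnt level and an
    APC-knockdown mutation parameter gamma, and drive cell proliferation via
    a transcription-complex threshold and cell migration via an
    adhesion-complex-dependent drag coefficient. Includes experiment drivers
    for crypt overcrowding, mutant-patch persistence, clonal takeover and
    cell-area measurement, and a translator between an SBML subset and the
    internal ODE representation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deldir,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
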