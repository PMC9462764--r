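Package: episkin
Title: Multiscale Simulation of Desquamation in the Interfollicular Epidermis
Version: 0.1.0
Authors@R:
    person("Maintainer", "episkin", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A multiscale model of epidermal homeostasis. A per-cell mass-action
    enzyme-kinetics model of corneodesmosome degradation (kallikrein protease,
    LEKTI inhibitor, pH regulation through the stratum corneum) is coupled to a
    three dimensional overlapping-spheres cell-centre tissue simulator with
    force-based cell removal. Includes the single-cell subcellular solver,
    tissue-scale scenario experiments (Netherton-Syndrome-like inhibitor
    depletion and heterogeneous recovery sweeps), and the associated analysis
    statistics (steady-state thickness, migration velocity, turnover times).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
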