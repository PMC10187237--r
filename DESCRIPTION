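Package: mtkmc
Title: Kinetic Monte Carlo Simulation of Nucleotide-Dependent Microtubule End Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic (Gillespie) kinetic Monte Carlo simulation of
    microtubule plus- and minus-end elongation on a 13-protofilament lattice
    with nucleotide-labelled subunits. Implements self-acting (cis) and
    interface-acting (trans) rules for how the exchangeable-site nucleotide
    (GMPCPP or GDP) sets tubulin:tubulin interaction affinities, terminal
    nucleotide exchange at the plus-end, growth-rate observables and
    concentration-series fits (apparent on-rate constant and critical
    concentration), a competitive nucleotide-binding model for mixed
    GMPCPP/GDP solutions, fluorescence-quenching binding and competition
    fits, and simulation-based calibration of kinetic parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
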