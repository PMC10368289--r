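Package: agedrift
Title: Age-Structured Cultural Transmission: Simulation and Neutrality
    Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward-time simulation of an age-structured infinite-alleles
    model of cultural transmission, with and without frequency-dependent
    bias, together with two procedures for inferring departures from
    unbiased (random-copying) transmission from a single cross-sectional
    sample of variant abundances: the Slatkin-style exact Ewens-Watterson
    neutrality test, and a generative-inference random-forest classifier
    trained on Hill-number diversity profiles of simulated samples.  Also
    provides variance-based estimation of the effective population size of
    the age-structured model, and command-line entry points for
    reproducible simulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ranger,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
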