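Package: delaykin
Title: Distributed-Delay Mass-Action Enzyme Kinetics and Conductometric
    Parameter Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Delay differential equation models of enzyme kinetics in which
    the lifetime of the enzyme-substrate complex is a random variable with a
    shifted gamma distribution ("delayed mass action"). Provides the gamma
    delay kernel with its Chebyshev truncation, a fixed-step method-of-steps
    integrator for models with instantaneous, discrete-delay and
    distributed-delay terms (enzyme-substrate, enzyme-substrate-inhibitor,
    and general multi-substrate multi-inhibitor lattice networks), a
    Kohlrausch-law observation model mapping product concentration to
    specific conductance, a penalty-based derivative-free parameter
    identification routine, and a synthetic conductometric experiment
    generator with a parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
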