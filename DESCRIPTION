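Package: blanketmem
Title: Memory and Transient Conditional Dependence in Markov Blanketed
    Stochastic Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how stochastic systems whose steady state
    carries a Markov blanket nonetheless exhibit transient memory. Builds
    three-state (internal, blanket, external) Ornstein-Uhlenbeck systems and
    their categorical master-equation analogues, propagates the Gaussian
    density dynamics (mode, covariance and precision flows) and the
    categorical density from imposed initial conditions, and quantifies the
    resulting transient violation of the blanket condition via
    blanket-conditioned mutual information, information length on the
    statistical manifold, and spectral decay time constants. Includes seeded
    ensemble simulation of the stochastic differential equation, parameter
    sweeps over the dissipative, solenoidal and steady-state precision
    parameters, and deterministic fixture generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
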