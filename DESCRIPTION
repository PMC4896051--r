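Package: ephysopt
Title: Feature-Based Multi-Objective Evolutionary Optimisation of Neuronal Models
Version: 0.1.0
Authors@R:
    person("EphysOpt", "Developers", email = "ephysopt@example.org",
           role = c("aut", "cre"))
Description: Tools for fitting the parameters of neuronal models to
    electrophysiological feature targets with an indicator-based
    evolutionary algorithm (IBEA). Includes a built-in single-compartment
    Hodgkin-Huxley simulator with square-pulse protocols, extraction of
    standard voltage-trace features (spike count, AP height and width,
    ISI statistics, AHP depths), z-score style objective scoring against
    experimental mean/std targets, and the Graupner-Brunel calcium-based
    model of spike-timing-dependent plasticity with analytic prediction
    of pairing-protocol outcomes, a stochastic simulation oracle, and a
    fitting evaluator. Ships a command-line interface and synthetic-data
    generators for benchmarking parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
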