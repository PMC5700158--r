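Package: fbnoise
Title: Feedback Topology Inference from Single-Cell Expression Noise
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact steady-state theory for stochastic gene expression with
    nonlinear autoregulatory feedback, and a data-analysis pipeline that
    infers the feedback sign (positive, negative, none) of a gene circuit
    from single-cell protein copy-number or concentration measurements.
    Provides the analytical stationary protein distribution of the bursty
    expression model, the decomposition of the protein noise into
    feedback-free and feedback contributions, bounds on noise suppression
    by negative feedback, Gillespie simulators for the full three-stage
    promoter/mRNA/protein Markov chain, estimators of the distribution's
    exponential tail-decay rate with bootstrap uncertainties, and a
    synthetic dose-response data generator emulating an inducer-tunable
    negative-feedback reporter circuit.
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
    yaml
Config/testthat/edition: 3
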