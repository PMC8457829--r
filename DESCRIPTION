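Package: morphotradeoff
Title: Cost-Precision Trade-Off Analysis of Morphogen Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic and stochastic tools for the cost-precision trade-off of
    morphogen gradient formation in the synthesis-diffusion-depletion (SDD)
    model. Provides closed-form steady-state profiles, local accumulation
    times, thermodynamic cost and positional-error measures for point and
    space-time-averaged concentration measurements, optimization of the
    gradient decay length, an exact Gillespie simulator of the underlying
    birth-hop-death lattice, a reversible-kinetics extension with entropy
    production rates, solvers for distributed sources and spherical
    geometries, and a pipeline that scores naturally occurring morphogen
    systems (Bicoid, Wingless, Hedgehog, Decapentaplegic) for optimality.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
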