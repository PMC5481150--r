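Package: exactqss
Title: Exact Quasi-Steady-State Reduction of Multiscale Stochastic
    Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Model reduction for multiscale stochastic biochemical reaction
    networks by exact quasi-steady-state (QSS) derivation. When the fast
    subnetwork is feedforward, stationary conditional moments of fast species
    are obtained from a finite linear moment closure derived symbolically from
    the chemical master equation; when it is weakly reversible with deficiency
    zero (complex balanced), they are obtained exactly from conservation-
    constrained partition functions of the product-form Poisson stationary law.
    The exact conditional moments are substituted into slow propensities to
    build reduced models, which are simulated with a compiled Gillespie direct
    method and compared against full models via ensemble summaries and
    oscillation period statistics. All structural and moment computations use
    exact big-rational arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    igraph,
    tibble,
    dplyr,
    ggplot2,
    generics,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
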