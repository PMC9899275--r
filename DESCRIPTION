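Package: rwexplore
Title: Exploration Dynamics of Random Walks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for the territory explored by
    discrete random walks. Measures the inter-visit times between discoveries
    of new sites for recurrent, marginal and transient walk classes (simple,
    persistent, Levy, true self-avoiding walks, fractional Brownian motion)
    on hypercubic lattices, the Sierpinski gasket, the T-fractal tree and
    critical bond-percolation clusters. Provides exact first-exit-time
    enumeration on frozen visited domains, Wang-Landau biased sampling of
    rare small-surface domains, closed-form regime predictions from the
    ratio of fractal to walk dimension, scaling-collapse and tail-rate
    estimators, multi-time visitation covariances, and starving-forager
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
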