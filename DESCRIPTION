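Package: tdcnet
Title: Dynamics-Sensitive Centrality and Spreading Analysis on Temporal Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ranking the spreading influence of nodes in temporal
    (snapshot-sequence) contact networks. Implements the temporal
    dynamics-sensitive centrality obtained from a linearized discrete-time
    SIR Markov recursion, the epidemic threshold defined by a unit spectral
    radius of the one-period infection propagator, a discrete-time Monte
    Carlo SIR simulator, static and temporal degree/closeness/betweenness
    benchmarks on the time-ordered graph, a time-order randomization null
    model that conserves the aggregated network, Kendall tau evaluation
    pipelines, and synthetic temporal scale-free and Erdos-Renyi generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
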