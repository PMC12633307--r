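Package: qsdbound
Title: Quasi-Stationary Bounds on Stochastic Switching in Gene Regulatory
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bounds the probability that a biochemical reaction network,
    modelled as a continuous-time Markov chain on species counts, leaves a
    finite region around a stable state within a given time. The region is
    turned into a cut-off process with an artificial absorbing state; its
    quasi-stationary distribution and decay parameter are computed from the
    principal eigenpair of the restricted generator, and a compensatory
    constant corrects the exponential survival bound for initial
    distributions that differ from the quasi-stationary one. Specialised
    boundary bounds for bounded birth-death chains, exact transient and
    stochastic-simulation oracles, and the bistable toggle-switch model
    family are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
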