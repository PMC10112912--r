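Package: actomyosim
Title: Agent-Based Simulation of Contractile Actomyosin Networks in Two Dimensions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Brownian-dynamics simulation of two-dimensional patches of
    actomyosin cortex: semiflexible actin filaments assembled by nucleators and
    Arp2/3 branching (72 degree branch angle) from a finite polymer pool, then
    contracted by two-headed myosin motors and passive crosslinkers that bind
    and unbind stochastically. The package implements the two-phase
    assembly/contraction protocol, extracts the network radius time series
    R(t), estimates the contraction rate B from the exponential fit
    A*exp(-B*t), and drives paired perturbation sweeps over random network
    architectures (doubled myosin, doubled F-actin, increased Arp2/3, reduced
    polymer mass) with full seed-level reproducibility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    minpack.lm,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
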