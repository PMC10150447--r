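Package: netdesign
Title: Network Experiment Design Under Interference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and evaluation of randomized experiments on networks where
    treatment effects can spill over between connected units. Implements an
    independent-set design that estimates direct treatment effects by assigning
    treatment and control only to non-adjacent nodes, and a cluster-matching
    design that estimates total treatment effects by combining weighted graph
    clustering (Markov clustering or restreamed linear deterministic greedy
    partitioning) with maximum-weight matching of covariate-balanced clusters.
    Includes node-level randomization, node matching, and stratified
    cluster-randomization baselines, synthetic graph and attribute generators,
    an interference simulator (direct spillover and contagion cascades), and
    diagnostics for estimation error, covariate balance, cross-arm spillover,
    and cluster-randomization bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
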