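Package: localcomm
Title: Individual-Based Delineation of Local Communities in Metacommunities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of spatial metacommunities in continuous
    space and continuous time (consumer-resource dynamics with partially
    shared resources, optionally extended with host-parasite dynamics),
    together with three operational definitions of the local community of a
    focal individual: overlap in space use (Bhattacharyya coefficient of
    utilization distributions), direct interactions, and fitness influence
    estimated from paired removal experiments. Local communities are
    delineated by modularity maximisation (Leiden algorithm) on the resulting
    individual-by-individual adjacency matrices, and delineations obtained
    under different definitions are compared via modularity, a cross-modularity
    consistency index, and distance-decay diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
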