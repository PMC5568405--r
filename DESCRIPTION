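Package: toposwarm
Title: Topological K-Nearest-Neighbor Swarm Simulation and Interaction-Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Agent-based simulator of collective motion driven by a piecewise
    Lennard-Jones-style attraction/repulsion force acting over each agent's K
    nearest neighbors (topological rather than metric interaction), with
    first-order position dynamics. Provides seeded initial-condition
    generators, classification of the emergent motions (straightness and
    helicity order parameters, rapid aggregation, disorder, and group
    fission), and analysis of the directed who-perceives-whom interaction
    network (degree distributions, density, entropy, geodesic distance,
    clustering) over time, plus parameter-sweep experiments and a thin
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    ggplot2,
    jsonlite,
    rlang,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
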