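Package: hypercurv
Title: Edge Curvatures for Graphs and Directed Hypergraphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Edge-based geometric measures for biological and other networks:
    Forman-Ricci curvature, degree difference, and Ollivier-Ricci curvature for
    undirected graphs, directed graphs and directed hypergraphs. Probability
    measures attached to the two sides of a (hyper)edge are built with exact
    rational arithmetic, and the 1-Wasserstein distance between them is computed
    with an exact minimum-cost transportation solver, together with the
    decomposition of the optimal plan by transport distance. Includes readers
    for edge lists, hyperedge records and metabolic reaction tables (with
    reversible-reaction splitting), seeded synthetic network generators, batch
    curvature computation, distribution summaries, degree assortativity, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
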