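Package: hypervne
Title: Von Neumann Entropy Centrality and Nonlinear Contagion on Hypergraphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies vital nodes in hypergraphs through the change in
    von Neumann graph entropy induced by hyperedge removal on the family of
    s-line graphs (high-order von Neumann entropy centrality, HVC), together
    with a fast variant based on the quadratic entropy approximation and a
    truncated order set (semi-SAVC).  Ships four baseline hypergraph
    centralities (hyperdegree, closeness, vector and sub-hypergraph
    centrality), a discrete-time nonlinear SIR contagion model with a
    per-hyperedge infection kernel, evaluation instruments (spreading
    influence, targeted-attack robustness, score correlation, ranking
    monotonicity, order-saturation sweeps), random and planted-overlap
    hypergraph generators, and plain-text hypergraph readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
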