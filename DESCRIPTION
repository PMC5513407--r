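Package: netprofiler
Title: Topological Profiling, Ranking, Clustering and Comparison of Biological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scriptable topological analysis of medium-scale biological
    networks (up to 50,000 edges) loaded from tab-delimited edge lists.
    Computes graph-level profiles (diameter, radius, average path length,
    density, clustering coefficients, assortativity, modularity, motif
    censuses of size 3 and 4, minimum s-t cuts, structural predicates),
    per-node and per-edge centralities (degree, closeness, betweenness,
    eigenvector) with ranking tables, histograms and feature correlation
    matrices, native Markov clustering (MCL), pairwise network intersection
    with Venn counts, and monopartite projections of bipartite graphs.
    Seeded Barabasi-Albert, Erdos-Renyi, Watts-Strogatz and random bipartite
    generators produce reproducible example networks. All graph algorithms
    are implemented natively and verified against brute-force oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
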