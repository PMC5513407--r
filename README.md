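# netprofiler

Topological profiling, ranking, clustering and comparison of biological
networks in R, from plain tab-delimited edge lists.

Biological interaction data — protein–protein interaction maps, gene–disease
associations, co-expression and metabolic networks — usually arrives as a
two-column list of pairwise connections. Before any biological
interpretation, such a network needs a topological characterization: how
large and dense is it, how far apart are its nodes, does it form clusters,
which nodes and edges act as hubs or bridges, and how does it compare to a
second dataset covering the same system? netprofiler answers these questions
as a scriptable library plus a small CLI, for networks up to 50,000 edges.

All graph algorithms are implemented natively in the package and verified in
the test suite against brute-force oracles (exhaustive enumeration, dense
eigendecomposition, Floyd–Warshall) and, where applicable, an independent
igraph cross-check; igraph is never used by the package itself.

## What it computes

**Graph-level profile** (one tibble row per network): node/edge/component
counts, self-loops; diameter, radius, average path length and average
eccentricity from BFS geodesics (reachable pairs only on disconnected
input); density m/(n(n−1)/2); global clustering 3N<sub>△</sub>/N<sub>∧</sub>
and average local clustering; degree assortativity (Pearson r of remaining
degrees over edge endpoints); Newman–Girvan modularity
Q = Σ<sub>c</sub>(e<sub>c</sub>/m − (d<sub>c</sub>/2m)²) of any partition;
minimum s–t cut by Edmonds–Karp max-flow; motif censuses of sizes 3 and 4
via ESU enumeration; and the structural predicates directed / DAG (Kahn) /
bipartite (BFS 2-coloring) / chordal (LexBFS + perfect elimination
ordering).

**Node and edge features**: degree (in/out on directed networks), closeness
with reachable-set scaling, Brandes betweenness (node and edge,
unnormalized), eigenvector centrality by shifted power iteration (max entry
1), local clustering, eccentricity — plus ranking tables with deterministic
tie-breaks, histograms (Sturges by default), pairwise Pearson feature
correlation matrices and exportable scatter coordinates.

**Clustering**: native MCL (expansion–inflation–prune loop on the
column-stochastic flow matrix; inflation is the granularity knob) returning
a hard node partition and its modularity.

**Comparison**: side-by-side multi-network profiles, pairwise intersection
with node/edge Venn counts and an exportable intersection subnetwork, and
monopartite projections of bipartite networks weighted by shared-neighbor
counts.

**Generators**: seeded Barabási–Albert, Erdős–Rényi, Watts–Strogatz and
random bipartite graphs; identical seeds give byte-identical edge lists.

## Worked example

```r
library(netprofiler)

g <- gen_barabasi_albert(200, 2, seed = 42)    # scale-free example network
profile_network(g)
#>  node_count edge_count diameter average_path_length density
#>         200        397        6                3.21  0.0199
#>  global_clustering_coefficient assortativity_degree
#>                         0.0436               -0.208
```

A 200-node preferential-attachment network: sparse (density 0.02), compact
(any node reaches any other in ~3 hops, at most 6), nearly triangle-free
(clustering 0.04), and disassortative (hubs link to low-degree nodes,
r = −0.21) — the expected scale-free signature.

```r
rank_table(node_table(g), "betweenness", "desc", top = 3)
#>  node degree betweenness closeness eigenvector
#>  v003     47        7459     0.506       1.000
#>  v002     36        4953     0.463       0.596
#>  v013     22        2240     0.379       0.170
```

The three strongest bridges are also the highest-degree hubs; `v003` lies on
~7,500 shortest paths.

```r
part <- mcl(g, inflation = 2.5)
glance(part)
#>   n_nodes n_clusters largest_cluster inflation iterations converged
#> 1     200         64              18       2.5         12 TRUE
modularity_score(g, part)
#> [1] 0.328
```

MCL carves the network into 64 flow clusters (many singleton leaves, one
18-node core) with modularity 0.33.

```r
h <- gen_erdos_renyi(200, 0.02, seed = 42); h$name <- "er"
intersect_networks(g, h)
#> <venn_result> ba vs er
#>   nodes: 0 only in ba | 200 shared | 0 only in er
#>   edges: 389 only in ba | 8 shared | 374 only in er
```

Against a density-matched random graph the node sets coincide by
construction while only 8 edges overlap — edge-level agreement between two
networks of the same genes is the informative quantity, and that is what the
Venn counts isolate.

The CLI mirrors the library
(`Rscript inst/cli/netprofiler.R profile graph.tsv`, `... cluster graph.tsv
--inflation 2`, `... intersect a.tsv b.tsv --venn venn.json`, `... generate
--model ba --n 1000 --seed 7`, ...).

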