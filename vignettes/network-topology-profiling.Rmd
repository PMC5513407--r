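---
title: "Topological profiling of biological networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological profiling of biological networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netprofiler)
```

netprofiler computes topological profiles of medium-scale biological
networks — protein–protein interaction maps, gene–disease associations,
metabolic and regulatory graphs — loaded from plain two- or three-column
tab-delimited edge lists. This vignette explains the statistics it computes,
the algorithmic and numerical choices behind them, and what the bundled
random-graph generators do and do not emulate.

## The data model

A network is a set of string-labelled nodes plus a list of edges with
positive weights (default 1 when the input has no third column). For
undirected networks every edge is stored under its *canonical key* — the
endpoint pair in lexicographic order — which makes duplicate detection,
network intersection and edge ranking deterministic. Duplicate input lines
are collapsed with their weights summed (the collapse count is kept, and
reported by the CLI as a warning), on the view that repeated records of the
same interaction are repeated evidence, so total interaction weight should
be conserved. Self-loops are retained and counted; they are excluded from
clustering coefficients, assortativity, motif counts and bipartiteness
(where a loop is an odd cycle of length 1 and forces a negative answer), and
a loop contributes 2 to undirected degree, following the usual handshake
convention.

The loader enforces a capacity of 50,000 edges by default. The limit is
configurable (`max_edges`); the dense-matrix Markov clustering below is the
component that most concretely motivates keeping medium scale as the target.

## Distance-based metrics

All geodesics are unit-length breadth-first-search hop counts; edge weights
do not enter path metrics by default. This matches how interaction networks
with presence/absence edges are usually profiled, and it keeps diameter,
radius and eccentricity integers. A `weighted = TRUE` flag switches the
distance metrics to Dijkstra with lengths $1/w$ (stronger interactions are
shorter); it exists for completeness and is off everywhere by default.

On disconnected networks — the common case for experimental interaction
maps — the diameter and the average path length are taken over *reachable
ordered pairs only*, a node's eccentricity is its distance to the farthest
node it can reach, and the radius is the minimum eccentricity within the
largest component. The profile reports the component count alongside, so a
finite diameter is never mistaken for evidence of connectivity. The
alternative (reporting infinity) destroys every downstream mean; we keep
profiles finite and flag the structure instead.

Closeness follows the same philosophy. For a node $v$ reaching $r$ other
nodes at total distance $S$,
$$C(v) = \frac{r}{S}\cdot\frac{r}{n-1},$$
i.e. the reciprocal mean distance to *reachable* nodes, damped by the
fraction of the network actually reached. Without the damping factor a node
in an isolated dyad would outrank the hub of a large component. Isolated
nodes score 0. This normalization is one of several in circulation;
rank-based comparisons are insensitive to the choice, but absolute closeness
values from other tools may differ by the scaling factor.

## Centralities

*Betweenness* uses Brandes' dependency accumulation on the BFS shortest-path
DAG, with shortest-path multiplicity handled fractionally. Scores are
unnormalized (a bridge between components of sizes $a$ and $b$ carries edge
betweenness exactly $a\,b$); `normalized = TRUE` divides node scores by
$(n-1)(n-2)/2$. On undirected networks each pair is counted once.

*Eigenvector centrality* is the principal eigenvector of the symmetrized
weighted adjacency, scaled so the maximum entry is 1, computed by power
iteration. Two numerical details matter. First, the iteration actually runs
on $A + I$: bipartite (sub)structures give $A$ a $-\lambda_1$ eigenvalue and
make the plain iteration oscillate — a star graph never converges — while
the unit shift preserves the eigenvectors and guarantees a strictly dominant
eigenvalue. Second, the computation is restricted to the largest connected
component (all other nodes score 0), because the principal eigenvector of a
disconnected graph concentrates arbitrarily on whichever component has the
larger spectral radius, which is rarely what a ranking should reflect.
Convergence is declared when the scaled iterate moves by less than `tol`
(default `1e-10`, max-norm); exceeding `max_iter` raises an error that
reports the residual rather than returning a silently unconverged vector.

*Degree assortativity* is the Pearson correlation of remaining degrees
(degree − 1) over the edge endpoint lists, each undirected edge entered in
both orientations; it is `NA` when an endpoint list has zero variance (e.g.
any regular graph), rather than 0, because an undefined correlation is not
evidence of non-assortativity.

Directed inputs are handled per metric: distances, betweenness and closeness
respect direction; clustering, motifs, chordality, bipartiteness,
assortativity and eigenvector centrality operate on the underlying
undirected simple graph. An undirected edge is treated as a 2-cycle by the
DAG test, so only an edgeless undirected network is a DAG.

## Clustering coefficients, motifs, structural predicates

The global clustering coefficient is the transitivity ratio
$3N_\triangle/N_{\wedge}$ (triangles over connected triples). The average
local clustering includes nodes of degree < 2 as zeros by default — the
mean then reflects the whole network rather than its dense core — with
`drop_low_degree = TRUE` for the other convention.

The motif census counts node subsets inducing each connected isomorphism
class of size 3 (`path3`, `triangle`) or 4 (`path4`, `star4`, `cycle4`,
`paw`, `diamond`, `k4`). Enumeration uses the ESU connected-subgraph
expansion, which visits every connected induced subgraph exactly once;
classes are keyed by induced edge count plus degree sequence, which is a
complete invariant at these sizes.

Chordality is decided by lexicographic BFS followed by verification of the
candidate perfect elimination ordering — the standard two-phase linear-time
recognition. Bipartiteness is a BFS 2-coloring per component; when it
fails, the two BFS-tree paths from the conflicting edge to their lowest
common ancestor are returned as an explicit odd-cycle witness, which the
bipartite-projection error reuses.

The minimum $s$–$t$ cut is computed as a maximum flow with shortest
augmenting paths (Edmonds–Karp), each undirected edge acting as two opposed
arcs of capacity $w$; the reported cut is the set of original edges crossing
the residual-reachability bipartition. The profile's single "mincut" number
is the minimum over a fixed source and all other targets. This is a
deliberate interpretation — a profile-level cut value is ambiguous without a
terminal pair — and is documented as such; an exact global mincut
(Stoer–Wagner) would be a drop-in upgrade.

## Markov clustering

MCL simulates flow: build the column-stochastic transition matrix from the
symmetrized weighted adjacency plus unit self-loops (van Dongen's standard
regularization, which damps odd/even oscillation), then repeat

1. **expansion** — raise the matrix to the `expansion` power (default 2),
2. **inflation** — entrywise power `inflation` (default 2), column renormalize,
3. **pruning** — zero entries below `prune_below` (default `1e-5`), renormalize,

until the largest entry change drops below `tol` (default `1e-8`) or
`max_iter` (200) is hit, in which case the partition is returned flagged
`converged = FALSE` rather than discarded. Inflation is the granularity
knob: higher values cut flow sooner and never coarsen the clustering in our
fixtures.

Clusters are read from the limit matrix's *attractors* — nodes retaining
return flow, i.e. a positive diagonal entry. A threshold-based attractor
rule (e.g. diagonal > 1/2) looks natural but fails on perfectly symmetric
structures: the limit of MCL on an isolated $k$-clique is the uniform block
with every diagonal entry $1/k$, and a clique must come out as one cluster,
not $k$ singletons. Each node is assigned to the attractor holding the
largest entry in its column, ties going to the smallest attractor label;
nodes outside every attractor's support become singletons. MCL can in
principle produce overlapping clusters; we resolve overlaps to hard
assignments because the output contract is a single-membership two-column
table.

The iteration is dense ($O(n^3)$ per expansion), which the edge cap keeps
tractable; clustering is the one feature deliberately not meant for large
networks.

Modularity of any partition (MCL's or user-supplied) is Newman–Girvan
$Q = \sum_c \left( e_c/m - (d_c/2m)^2 \right)$ on the undirected weighted
view; the one-community partition scores exactly 0 and two equal disjoint
cliques split correctly score exactly 0.5, both of which are pinned in the
tests.

## Comparison, intersection, projection

`inter_profile()` aligns per-network profiles row-wise, using means for
node-level features; a metric failing on one network yields `NA` there and
never aborts the comparison. `intersect_networks()` counts node overlap by
exact label match and edge overlap by canonical key, *ignoring weights*:
across independently measured datasets weights are not comparable, so
membership is a set question. The intersection subnetwork carries the first
argument's weights. Directed networks intersect arc-exactly and cannot be
intersected with undirected ones.

`project_bipartite()` connects two same-side nodes iff they share at least
`min_shared` (default 1 — no hidden thresholding) neighbors on the other
side, weighting each projected edge by the shared-neighbor count. Side 0 is
the side containing the lexicographically smallest label, making outputs
deterministic; networks built by `gen_bipartite()` carry their construction
coloring, which also fixes the side of isolated nodes that no coloring
algorithm could place.

## The random-graph generators

The generators exist to produce reproducible example and test networks in
the three classical families plus random bipartite graphs, at the preset
scales (tens to tens of thousands of nodes) typical for this kind of
profiling:

* **Erdős–Rényi** $G(n,p)$: the edge count is drawn $\mathrm{Binomial}(\binom n2, p)$
  and that many distinct pairs are sampled — equivalent to independent pair
  inclusion, in $O(m)$ memory.
* **Barabási–Albert**: growth from an $m_a$-clique seed (the initial
  condition is unspecified in most descriptions; we fix and document it for
  reproducibility), each new node attaching to $m_a$ distinct nodes with
  probability proportional to current degree via endpoint-multiset
  sampling. $m_a = 1$ provably yields a tree.
* **Watts–Strogatz**: ring lattice of even degree $k$ (lattice average
  local clustering $3(k-2)/(4(k-1))$, pinned in tests), each edge rewired
  with probability $p_r$ avoiding loops and duplicates.
* **Random bipartite**: independent cross-pairs with probability $p$;
  within-side edges are structurally impossible.

Every generator takes one explicit integer seed and leaves the session RNG
untouched; identical calls are byte-identical on disk. The generators
emulate degree heterogeneity, small-world shortcuts and community-free
nulls. They do **not** emulate the degree-correlation structure, hub
saturation or experimental ascertainment bias of real interactomes — a
passing test on generated fixtures validates the *algorithms*, not any
biological claim about real data.

## Verification strategy and problem sizes

Every graph algorithm is implemented natively and tested against an
independent oracle on sizes where exhaustive computation is feasible: BFS
distances against Floyd–Warshall ($n \le 30$), betweenness against explicit
all-shortest-path enumeration ($n \le 12$), motif censuses against
all-subset enumeration ($n \le 12$), minimum cuts against edge-subset brute
force ($n \le 8$), bipartiteness against all $2^n$ colorings ($n \le 10$),
chordality against chordless-cycle search ($n \le 7$), eigenvector
centrality against a dense eigendecomposition ($n \le 20$, agreement to
$10^{-6}$), and clustering/assortativity additionally against igraph, which
is used strictly as a cross-check in the test suite and never by the
package itself. Statistical generator checks use 50 seeds (ER density
within 3 standard errors; Barabási–Albert heavy-tail majority) and 20 seeds
(Watts–Strogatz path-length contraction at $n = 500$). These sizes were
chosen so the oracles remain exact yet the whole suite runs in well under a
minute per file.

## Known limitations

* Path metrics are hop-count by default; the inverse-weight option is a
  coarse surrogate for confidence-weighted distances.
* Betweenness is exact, never sampled; very large dense networks will be slow.
* The profile's mincut is the fixed-source global minimum described above,
  not Stoer–Wagner.
* MCL is dense; use it at the small-to-medium scales it is intended for.
* The closeness normalization on disconnected graphs is a documented choice;
  compare absolute values across tools with care.
* No GML/GraphML/SIF input; the edge-list dialect (TSV/CSV, 2–3 columns,
  `#` comments) is the only format.
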