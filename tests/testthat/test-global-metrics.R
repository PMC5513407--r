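test_that("BFS distances equal Floyd-Warshall on random and directed graphs", {
  d <- bfs_distances(path_graph(c("A", "B", "C")), "A")
  expect_equal(d$distance, c(0, 1, 2))
  d2 <- bfs_distances(parse_edge_list("A\tB\nC\tC"), "A")
  expect_equal(d2$distance[d2$node == "C"], Inf)
  expect_error(bfs_distances(complete_graph(3), "nope"), "unknown source")

  g <- random_graph(30, 0.15, 11)
  D <- oracle_floyd_warshall(g)
  for (v in g$nodes) {
    expect_equal(bfs_distances(g, v)$distance, unname(D[v, ]))
  }
  gd <- random_directed_graph(12, 0.2, 5)
  Dd <- oracle_floyd_warshall(gd)
  for (v in gd$nodes) {
    expect_equal(bfs_distances(gd, v)$distance, unname(Dd[v, ]))
  }
})

test_that("diameter, radius and eccentricities match closed forms and the oracle", {
  expect_equal(diameter(cycle_graph(6)), 3)
  expect_equal(diameter(star_graph(5)), 2)
  expect_equal(radius(cycle_graph(6)), 3)
  s5 <- star_graph(5)
  ecc <- eccentricities(s5)
  expect_equal(ecc$eccentricity[ecc$node == "ctr"], 1)
  expect_true(all(ecc$eccentricity[ecc$node != "ctr"] == 2))
  expect_equal(radius(s5), 1)
  expect_equal(diameter(netgraph(edges_df(character(), character()), nodes = "A")), 0)

  for (seed in c(3, 17)) {
    g <- random_graph(25, 0.12, seed)
    D <- oracle_floyd_warshall(g)
    fin <- D[row(D) != col(D) & is.finite(D)]
    expect_equal(diameter(g), if (length(fin)) max(fin) else 0)
    row_ecc <- apply(D, 1, function(r) { f <- r[is.finite(r)]; if (length(f)) max(f) else 0 })
    expect_equal(eccentricities(g)$eccentricity, unname(row_ecc))
    expect_equal(average_path_length(g), mean(fin))
  }
})

test_that("radius <= diameter <= 2*radius on connected undirected fixtures", {
  fixtures <- list(complete_graph(6), cycle_graph(7), star_graph(6),
                   two_cliques_bridge(4), gen_barabasi_albert(30, 2, 4),
                   gen_watts_strogatz(24, 4, 0.2, 9))
  for (g in fixtures) {
    r <- radius(g); d <- diameter(g)
    expect_lte(r, d)
    expect_lte(d, 2 * r)
  }
})

test_that("average path length matches closed forms", {
  expect_equal(average_path_length(path_graph(c("A", "B", "C"))), 4 / 3)
  expect_equal(average_path_length(complete_graph(7)), 1)
  expect_true(is.na(average_path_length(netgraph(edges_df(character(), character()),
                                                 nodes = c("A", "B")))))
})

test_that("density follows m over possible edges, excluding self-loops", {
  expect_equal(edge_density(complete_graph(4)), 1)
  expect_equal(edge_density(path_graph(c("A", "B", "C"))), 2 / 3)
  expect_equal(edge_density(parse_edge_list("A\tB\nA\tC", directed = TRUE)), 1 / 3)
  expect_equal(edge_density(parse_edge_list("A\tA\nA\tB")), 1)  # loop dropped
  expect_true(is.na(edge_density(netgraph(edges_df(character(), character()), nodes = "A"))))
})

test_that("clustering coefficients match brute-force triangle/triple enumeration", {
  expect_equal(clustering_global(complete_graph(3)), 1)
  expect_equal(clustering_average_local(complete_graph(3)), 1)
  expect_equal(clustering_global(star_graph(5)), 0)
  expect_equal(clustering_average_local(star_graph(5)), 0)

  g <- random_graph(25, 0.2, 21)
  A <- oracle_adjacency(g); A <- pmax(A, t(A)); diag(A) <- 0
  tri_total <- 0; triples <- 0; local <- numeric(length(g$nodes))
  for (v in seq_along(g$nodes)) {
    nb <- which(A[v, ] > 0)
    k <- length(nb)
    triples <- triples + choose(k, 2)
    t_v <- if (k >= 2) sum(A[nb, nb]) / 2 else 0
    tri_total <- tri_total + t_v
    local[v] <- if (k >= 2) t_v / choose(k, 2) else 0
  }
  expect_equal(clustering_global(g), tri_total / triples)
  expect_equal(clustering_average_local(g), mean(local))
  expect_equal(local_clustering(g)$local_clustering, local)
  # independent cross-check against igraph's transitivity
  expect_equal(clustering_global(g),
               igraph::transitivity(as_igraph(g), type = "global"))
})

test_that("degree assortativity equals a direct endpoint-degree correlation", {
  expect_true(is.na(assortativity_degree(complete_graph(5))))
  expect_equal(assortativity_degree(star_graph(5)), -1)
  expect_true(is.na(assortativity_degree(netgraph(edges_df(character(), character()),
                                                  nodes = "A"))))
  for (seed in c(2, 9)) {
    g <- random_graph(20, 0.2, seed)
    A <- oracle_adjacency(g); A <- pmax(A, t(A)); diag(A) <- 0
    deg <- rowSums(A)
    i <- match(g$edges$from, g$nodes); j <- match(g$edges$to, g$nodes)
    x <- c(deg[i], deg[j]) - 1; y <- c(deg[j], deg[i]) - 1
    expect_equal(assortativity_degree(g), stats::cor(x, y))
    expect_equal(assortativity_degree(g),
                 igraph::assortativity_degree(as_igraph(g)))
  }
})

test_that("modularity matches the naive double-sum and its closed forms", {
  g <- two_cliques_bridge(4)
  one <- stats::setNames(rep(0L, length(g$nodes)), g$nodes)
  expect_equal(modularity_score(g, one), 0)

  cl2 <- disjoint_cliques(c(4, 4))
  truth <- stats::setNames(rep(0:1, each = 4), cl2$nodes)
  expect_equal(modularity_score(cl2, truth), 0.5)

  for (seed in c(5, 13)) {
    g <- random_weighted_graph(15, 0.25, seed)
    part <- stats::setNames(sample(0:2, length(g$nodes), replace = TRUE), g$nodes)
    expect_equal(modularity_score(g, part), oracle_modularity(g, part))
  }
  expect_error(modularity_score(g, stats::setNames(0L, g$nodes[1])), "cover")
})

test_that("st-mincut equals edge-subset brute force and respects the cut bound", {
  res <- st_mincut(path_graph(c("A", "B", "C")), "A", "C")
  expect_equal(res$value, 1)
  expect_equal(nrow(res$cut), 1)

  bridge <- two_cliques_bridge(4)
  expect_equal(st_mincut(bridge, "a02", "b02")$value, 1)
  expect_error(st_mincut(bridge, "a01", "a01"), "differ")

  for (seed in 1:6) {
    g <- random_weighted_graph(6, 0.5, seed + 40)
    if (nrow(g$edges) > 12) next
    s <- g$nodes[1]; t <- g$nodes[length(g$nodes)]
    got <- st_mincut(g, s, t)
    expect_equal(got$value, oracle_st_mincut(g, s, t), tolerance = 1e-9,
                 info = paste("seed", seed))
    # removing the returned cut really separates s and t
    keep <- !(paste(g$edges$from, g$edges$to) %in% paste(got$cut$from, got$cut$to))
    g_cut <- netgraph(g$edges[keep, ], nodes = g$nodes)
    D <- oracle_floyd_warshall(g_cut)
    expect_true(is.infinite(D[s, t]))
    # cut bound: value <= weighted degree of either terminal
    wdeg <- function(v) sum(g$edges$weight[g$edges$from == v | g$edges$to == v])
    expect_lte(got$value, wdeg(s) + 1e-9)
    expect_lte(got$value, wdeg(t) + 1e-9)
  }
})

test_that("motif censuses of size 3 and 4 equal exhaustive subset enumeration", {
  m3 <- motif_census(complete_graph(3), 3)
  expect_equal(m3$count[m3$motif == "triangle"], 1)
  expect_equal(m3$count[m3$motif == "path3"], 0)
  m3k4 <- motif_census(complete_graph(4), 3)
  expect_equal(m3k4$count[m3k4$motif == "triangle"], 4)
  m4 <- motif_census(complete_graph(4), 4)
  expect_equal(m4$count[m4$motif == "k4"], 1)
  expect_error(motif_census(complete_graph(4), 5), "size")

  for (seed in c(1, 8)) {
    g <- random_graph(12, 0.3, seed + 70)
    for (size in c(3, 4)) {
      got <- motif_census(g, size)
      want <- oracle_motifs(g, size)
      expect_equal(stats::setNames(got$count, got$motif), want,
                   info = paste("seed", seed, "size", size))
    }
  }
})

test_that("the assembled profile agrees with individually invoked metrics", {
  k4 <- complete_graph(4)
  prof <- profile_network(k4, motifs = TRUE, mincut = TRUE)
  expect_equal(prof$node_count, 4)
  expect_equal(prof$edge_count, 6)
  expect_equal(prof$density, 1)
  expect_equal(prof$diameter, 1)
  expect_equal(prof$global_clustering_coefficient, 1)
  expect_false(prof$is_bipartite)
  expect_equal(prof$mincut_value, 3)
  expect_equal(prof$motif4_k4, 1)

  g <- gen_watts_strogatz(20, 4, 0.3, 31)
  prof <- profile_network(g, motifs = TRUE, partition = mcl(g))
  expect_equal(prof$diameter, diameter(g))
  expect_equal(prof$radius, radius(g))
  expect_equal(prof$average_path_length, average_path_length(g))
  expect_equal(prof$density, edge_density(g))
  expect_equal(prof$global_clustering_coefficient, clustering_global(g))
  expect_equal(prof$average_local_clustering, clustering_average_local(g))
  expect_equal(prof$assortativity_degree, assortativity_degree(g))
  expect_equal(prof$mean_betweenness, mean(betweenness(g)$nodes$betweenness))
  expect_equal(prof$mean_closeness, mean(closeness(g)$closeness))
  expect_equal(prof$average_eigenvector_centrality,
               mean(eigenvector_centrality(g)$eigenvector))
  expect_equal(prof$modularity, modularity_score(g, mcl(g)))
  m3 <- motif_census(g, 3)
  expect_equal(prof$motif3_triangle, m3$count[m3$motif == "triangle"])

  # degenerate input: metrics go NA, the profile never aborts
  empty <- netgraph(edges_df(character(), character()), nodes = sprintf("i%d", 1:5))
  prof0 <- profile_network(empty)
  expect_equal(prof0$mean_degree, 0)
  expect_true(is.na(prof0$average_path_length))
  expect_true(is.na(prof0$average_eigenvector_centrality))
})
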