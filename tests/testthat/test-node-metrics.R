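test_that("degrees count incident links, with self-loops adding 2", {
  s5 <- star_graph(4)
  deg <- node_degrees(s5)
  expect_equal(deg$degree[deg$node == "ctr"], 4)
  gl <- parse_edge_list("A\tA\nA\tB")
  expect_equal(node_degrees(gl)$degree, c(3, 1))
  gd <- parse_edge_list("A\tB\nA\tA", directed = TRUE)
  dd <- node_degrees(gd)
  expect_equal(dd$in_degree[dd$node == "A"], 1)
  expect_equal(dd$out_degree[dd$node == "A"], 2)

  g <- random_graph(15, 0.25, 3)
  scan <- vapply(g$nodes, function(v)
    sum(g$edges$from == v) + sum(g$edges$to == v), 0L)
  expect_equal(node_degrees(g)$degree, unname(scan))
})

test_that("betweenness matches path enumeration, closed forms and igraph", {
  p3 <- path_graph(c("A", "B", "C"))
  b <- betweenness(p3)$nodes
  expect_equal(b$betweenness, c(0, 1, 0))

  for (n in c(5, 8)) {
    star <- star_graph(n)
    bs <- betweenness(star)$nodes
    expect_equal(bs$betweenness[bs$node == "ctr"], n * (n - 1) / 2)
  }

  for (seed in c(4, 12)) {
    g <- random_graph(10 + seed %% 3, 0.25, seed + 200)
    got <- betweenness(g)$nodes
    expect_equal(stats::setNames(got$betweenness, got$node),
                 oracle_betweenness_nodes(g), tolerance = 1e-9)
    ig <- igraph::betweenness(as_igraph(g), directed = FALSE)
    expect_equal(got$betweenness, unname(ig[g$nodes]), tolerance = 1e-9)
  }
  # directed case against igraph
  gd <- random_directed_graph(9, 0.25, 77)
  got <- betweenness(gd)$nodes
  ig <- igraph::betweenness(as_igraph(gd), directed = TRUE)
  expect_equal(got$betweenness, unname(ig[gd$nodes]), tolerance = 1e-9)
})

test_that("edge betweenness of a bridge equals the product of the component sizes", {
  for (k in list(c(3, 4), c(4, 4), c(5, 2))) {
    g <- two_cliques_bridge(k[1], k[2])
    eb <- betweenness(g)$edges
    bridge_row <- eb$from == "a01" & eb$to == "b01"
    expect_equal(eb$betweenness[bridge_row], k[1] * k[2])
  }
  g <- random_graph(11, 0.3, 15)
  ig_eb <- igraph::edge_betweenness(as_igraph(g), directed = FALSE)
  expect_equal(betweenness(g)$edges$betweenness, unname(ig_eb), tolerance = 1e-9)
})

test_that("closeness uses reachable-set scaling and matches the distance-matrix oracle", {
  expect_true(all(closeness(complete_graph(6))$closeness == 1))
  iso <- netgraph(edges_df("A", "B"), nodes = c("A", "B", "C"))
  expect_equal(closeness(iso)$closeness[3], 0)

  for (seed in c(6, 19)) {
    g <- random_graph(18, 0.12, seed + 400)  # often disconnected
    expect_equal(closeness(g)$closeness, unname(oracle_closeness(g)))
  }
})

test_that("eigenvector centrality matches the dense principal eigenvector", {
  expect_equal(eigenvector_centrality(complete_graph(5))$eigenvector, rep(1, 5))
  s5 <- star_graph(4)
  ev <- eigenvector_centrality(s5)
  expect_equal(ev$eigenvector[ev$node == "ctr"], 1)
  expect_equal(ev$eigenvector[ev$node != "ctr"], rep(0.5, 4), tolerance = 1e-8)
  expect_error(eigenvector_centrality(netgraph(edges_df(character(), character()),
                                               nodes = "A")), "edge")

  for (seed in c(7, 23, 31)) {
    g <- random_weighted_graph(20, 0.2, seed + 600)
    got <- eigenvector_centrality(g, tol = 1e-12)
    expect_equal(got$eigenvector, unname(oracle_eigenvector(g)), tolerance = 1e-6)
  }

  # invariance under node relabeling
  g <- random_graph(15, 0.25, 41)
  perm <- withr::with_seed(99, sample(length(g$nodes)))
  relabeled <- stats::setNames(sprintf("r%02d", perm), g$nodes)
  g2 <- netgraph(edges_df(unname(relabeled[g$edges$from]), unname(relabeled[g$edges$to])),
                 nodes = unname(relabeled[g$nodes]))
  e1 <- eigenvector_centrality(g, tol = 1e-12)
  e2 <- eigenvector_centrality(g2, tol = 1e-12)
  expect_equal(e2$eigenvector[match(unname(relabeled[e1$node]), e2$node)],
               e1$eigenvector, tolerance = 1e-8)
})

test_that("ranking is a stable permutation with label tie-breaks and NA last", {
  s5 <- star_graph(4)
  tab <- node_table(s5)
  expect_equal(rank_table(tab, "degree", "desc")$node[1], "ctr")

  const <- tibble::tibble(node = c("c", "a", "b"), f = c(1, 1, 1))
  expect_equal(rank_table(const, "f")$node, c("a", "b", "c"))

  withna <- tibble::tibble(node = c("a", "b", "c"), f = c(NA, 2, 1))
  expect_equal(rank_table(withna, "f", "asc")$node, c("c", "b", "a"))
  expect_equal(rank_table(withna, "f", "desc")$node, c("b", "c", "a"))
  expect_error(rank_table(withna, "nope"), "unknown feature")

  for (seed in 1:5) {
    vals <- withr::with_seed(seed, sample(c(1:8, NA), 9, replace = TRUE))
    tb <- tibble::tibble(node = sprintf("n%02d", 1:9), f = as.numeric(vals))
    up <- rank_table(tb, "f", "asc")
    down <- rank_table(tb, "f", "desc")
    # permutation: same multiset of rows
    expect_setequal(up$node, tb$node)
    # asc reverses desc up to tie blocks and NA placement
    expect_equal(sort(up$f[!is.na(up$f)]), up$f[!is.na(up$f)])
    expect_equal(sort(down$f[!is.na(down$f)], decreasing = TRUE),
                 down$f[!is.na(down$f)])
    expect_true(all(is.na(utils::tail(up$f, sum(is.na(vals))))))
  }
})

test_that("histograms bin correctly, conserve counts and apply Sturges' rule", {
  h <- feature_histogram(c(1, 1, 2, 2), bins = 2)
  expect_equal(h$count, c(2, 2))
  hc <- feature_histogram(rep(3.5, 10), bins = 5)
  expect_equal(nrow(hc), 1)
  expect_equal(hc$count, 10)
  expect_error(feature_histogram(c(NA_real_, NA)), "non-NA")

  vals <- withr::with_seed(8, stats::rnorm(100))
  h <- feature_histogram(vals)
  expect_equal(nrow(h), ceiling(log2(100)) + 1)
  expect_equal(sum(h$count), 100)
  expect_equal(sum(feature_histogram(c(vals, NA), 7)$count), 100)
  # last bin right-closed: the maximum lands in the final bin
  hm <- feature_histogram(c(0, 10), bins = 4)
  expect_equal(hm$count, c(1, 0, 0, 1))
})

test_that("the feature correlation matrix matches direct Pearson computation", {
  tab <- tibble::tibble(node = letters[1:6], f = c(1, 3, 2, 5, 4, 6))
  tab$same <- tab$f
  tab$neg <- -tab$f
  tab$konst <- 5
  M <- correlation_matrix(tab, c("f", "same", "neg", "konst"))
  expect_equal(M["f", "same"], 1)
  expect_equal(M["f", "neg"], -1)
  expect_true(is.na(M["f", "konst"]))
  expect_true(isSymmetric(unclass(M)))

  g <- random_graph(20, 0.25, 55)
  nt <- node_table(g)
  M <- correlation_matrix(nt, c("degree", "closeness", "betweenness"))
  expect_equal(M["degree", "closeness"],
               stats::cor(nt$degree, nt$closeness))
  expect_equal(M["degree", "betweenness"],
               sum((nt$degree - mean(nt$degree)) * (nt$betweenness - mean(nt$betweenness))) /
                 sqrt(sum((nt$degree - mean(nt$degree))^2) *
                      sum((nt$betweenness - mean(nt$betweenness))^2)))

  # too few complete rows -> NA
  short <- tibble::tibble(node = c("a", "b", "c"), x = c(1, 2, NA), y = c(2, 1, 0))
  expect_true(is.na(correlation_matrix(short, c("x", "y"))["x", "y"]))
  expect_error(correlation_matrix(tab, "f"), "at least 2")

  coords <- scatter_coordinates(nt, "degree", "closeness")
  expect_equal(coords$x, nt$degree)
  expect_equal(nrow(scatter_coordinates(short, "x", "y")), 2)
})

test_that("node betweenness totals match the enumeration oracle's pair decomposition", {
  g <- random_graph(12, 0.25, 61)
  expect_equal(sum(betweenness(g)$nodes$betweenness),
               sum(oracle_betweenness_nodes(g)), tolerance = 1e-9)
})

test_that("Freeman centralization is 1 on stars and 0 on complete graphs", {
  expect_equal(freeman_centralization(star_graph(5), "degree"), 1)
  expect_equal(freeman_centralization(complete_graph(5), "degree"), 0)
  expect_equal(freeman_centralization(star_graph(5), "betweenness"), 1)
  g <- random_graph(12, 0.3, 71)
  for (f in c("degree", "closeness", "betweenness")) {
    v <- freeman_centralization(g, f)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})
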