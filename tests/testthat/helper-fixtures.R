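# Graph fixtures built in code. Labels are plain letters/numbers so canonical
# (lexicographic) edge keys are predictable.

edges_df <- function(from, to, weight = NULL) {
  if (is.null(weight)) tibble::tibble(from = from, to = to)
  else tibble::tibble(from = from, to = to, weight = weight)
}

complete_graph <- function(n, prefix = "n") {
  labs <- sprintf("%s%02d", prefix, seq_len(n))
  pr <- utils::combn(labs, 2)
  netgraph(edges_df(pr[1, ], pr[2, ]), name = paste0("k", n))
}

path_graph <- function(labels) {
  netgraph(edges_df(labels[-length(labels)], labels[-1]), name = "path")
}

cycle_graph <- function(n) {
  labs <- sprintf("c%02d", seq_len(n))
  netgraph(edges_df(labs, labs[c(2:n, 1)]), name = paste0("cycle", n))
}

star_graph <- function(n_leaves) {
  netgraph(edges_df(rep("ctr", n_leaves), sprintf("l%02d", seq_len(n_leaves))),
           name = "star")
}

# two k-cliques joined by a single bridge edge
two_cliques_bridge <- function(k = 4, k2 = k) {
  a <- sprintf("a%02d", seq_len(k))
  b <- sprintf("b%02d", seq_len(k2))
  pa <- utils::combn(a, 2); pb <- utils::combn(b, 2)
  netgraph(edges_df(c(pa[1, ], pb[1, ], a[1]), c(pa[2, ], pb[2, ], b[1])),
           name = "bridge")
}

# k disjoint cliques of the given sizes
disjoint_cliques <- function(sizes) {
  ed <- dplyr::bind_rows(lapply(seq_along(sizes), function(i) {
    labs <- sprintf("c%d_%02d", i, seq_len(sizes[i]))
    if (sizes[i] == 1) return(tibble::tibble(from = character(), to = character()))
    pr <- utils::combn(labs, 2)
    edges_df(pr[1, ], pr[2, ])
  }))
  all_nodes <- unlist(lapply(seq_along(sizes), function(i)
    sprintf("c%d_%02d", i, seq_len(sizes[i]))))
  netgraph(ed, name = "cliques", nodes = all_nodes)
}

random_graph <- function(n, p, seed) gen_erdos_renyi(n, p, seed)

random_directed_graph <- function(n, p, seed) {
  withr::with_seed(seed, {
    pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
    pairs <- pairs[pairs$i != pairs$j, ]
    keep <- stats::runif(nrow(pairs)) < p
  })
  labs <- sprintf("d%02d", seq_len(n))
  netgraph(edges_df(labs[pairs$i[keep]], labs[pairs$j[keep]]),
           directed = TRUE, nodes = labs, name = "rdir")
}

random_weighted_graph <- function(n, p, seed) {
  g <- gen_erdos_renyi(n, p, seed)
  withr::with_seed(seed + 1000, {
    g$edges$weight <- round(stats::runif(nrow(g$edges), 0.5, 3), 2)
  })
  g
}

# two planted ER communities with sparse cross-links
planted_two_communities <- function(n_per_side = 20, p_in = 0.4, p_out = 0.02, seed = 1) {
  g1 <- gen_erdos_renyi(n_per_side, p_in, seed)
  g2 <- gen_erdos_renyi(n_per_side, p_in, seed + 10000)
  cross <- gen_bipartite(n_per_side, n_per_side, p_out, seed + 20000)
  relab <- function(x, prefix) paste0(prefix, x)
  ed <- dplyr::bind_rows(
    edges_df(relab(g1$edges$from, "x"), relab(g1$edges$to, "x")),
    edges_df(relab(g2$edges$from, "y"), relab(g2$edges$to, "y")),
    edges_df(paste0("x", g1$nodes[as.integer(sub("^a", "", cross$edges$from))]),
             paste0("y", g2$nodes[as.integer(sub("^b", "", cross$edges$to))]))
  )
  nodes <- c(relab(g1$nodes, "x"), relab(g2$nodes, "y"))
  list(
    graph = netgraph(ed, nodes = nodes, name = "planted"),
    truth = stats::setNames(rep(c(0L, 1L), each = n_per_side), nodes)
  )
}

# convert to an igraph object (igraph is an independent cross-check only)
as_igraph <- function(g) {
  igraph::graph_from_data_frame(as.data.frame(g$edges), directed = g$directed,
                                vertices = g$nodes)
}
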