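#' Geodesic distances from one source node
#'
#' Breadth-first search hop counts from `source` to every node. Edge weights
#' are ignored unless `weighted = TRUE`, in which case edges have length
#' `1/weight` (stronger interactions are shorter) and Dijkstra's algorithm is
#' used. Direction is respected on directed networks. Unreachable nodes get
#' distance `Inf`.
#'
#' @param g a `netgraph`.
#' @param source node label.
#' @param weighted use inverse-weight edge lengths instead of hop counts?
#' @return tibble with columns `node` and `distance`.
#' @export
bfs_distances <- function(g, source, weighted = FALSE) {
  s <- match(source, g$nodes)
  if (is.na(s)) stop("unknown source node: ", source, call. = FALSE)
  d <- single_source_distances(g, s, weighted = weighted)
  tibble::tibble(node = g$nodes, distance = d)
}

# distances from node index s; Inf = unreachable
single_source_distances <- function(g, s, weighted = FALSE,
                                    adj = NULL, wadj = NULL) {
  n <- length(g$nodes)
  if (!weighted) {
    if (is.null(adj)) adj <- adjacency_list(g, mode = "out")
    d <- rep(Inf, n)
    d[s] <- 0
    queue <- integer(n)
    queue[1] <- s
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      nb <- adj[[v]]
      new <- nb[is.infinite(d[nb])]
      if (length(new)) {
        new <- unique(new)
        d[new] <- d[v] + 1
        queue[(tail + 1L):(tail + length(new))] <- new
        tail <- tail + length(new)
      }
    }
    d
  } else {
    if (is.null(wadj)) wadj <- weighted_adjacency_list(g)
    d <- rep(Inf, n)
    d[s] <- 0
    done <- rep(FALSE, n)
    repeat {
      v <- which.min(ifelse(done, Inf, d))
      if (done[v] || is.infinite(d[v])) break
      done[v] <- TRUE
      nb <- wadj$nb[[v]]; len <- wadj$len[[v]]
      relax <- d[v] + len < d[nb]
      d[nb[relax]] <- d[v] + len[relax]
      if (all(done | is.infinite(d))) break
    }
    d
  }
}

weighted_adjacency_list <- function(g) {
  n <- length(g$nodes)
  ei <- edge_indices(g)
  if (g$directed) {
    a <- ei$from; b <- ei$to; w <- ei$weight
  } else {
    a <- c(ei$from, ei$to); b <- c(ei$to, ei$from); w <- c(ei$weight, ei$weight)
  }
  nb <- rep(list(integer()), n)
  len <- rep(list(numeric()), n)
  if (length(a)) {
    ord <- order(a)
    sp_b <- split(b[ord], factor(a[ord], levels = seq_len(n)))
    sp_w <- split(1 / w[ord], factor(a[ord], levels = seq_len(n)))
    nb <- unname(sp_b); len <- unname(sp_w)
  }
  list(nb = nb, len = len)
}

# full n x n geodesic distance matrix (rows = sources)
distance_matrix <- function(g, weighted = FALSE) {
  n <- length(g$nodes)
  adj <- if (!weighted) adjacency_list(g, mode = "out") else NULL
  wadj <- if (weighted) weighted_adjacency_list(g) else NULL
  D <- matrix(Inf, n, n, dimnames = list(g$nodes, g$nodes))
  for (s in seq_len(n)) {
    D[s, ] <- single_source_distances(g, s, weighted = weighted, adj = adj, wadj = wadj)
  }
  D
}

finite_offdiag <- function(D) {
  if (!nrow(D)) return(numeric())
  vals <- D[row(D) != col(D)]
  vals[is.finite(vals)]
}

#' Graph-level distance metrics
#'
#' `diameter()` is the length of the longest geodesic — the maximum finite
#' shortest-path distance over all ordered reachable pairs (0 for edgeless
#' networks). A node's eccentricity is its distance to the farthest node it
#' can reach; `radius()` is the smallest eccentricity among nodes of the
#' largest component. `average_path_length()` is the mean geodesic distance
#' over all ordered reachable pairs, excluding self-pairs (`NA` when no such
#' pair exists). On disconnected networks all three are computed over
#' reachable pairs only.
#'
#' @param g a `netgraph`.
#' @param weighted use inverse-weight edge lengths? Default hop counts.
#' @return `diameter()`, `radius()`, `average_path_length()`: a single number;
#'   `eccentricities()`: tibble with columns `node` and `eccentricity`.
#' @export
diameter <- function(g, weighted = FALSE) {
  vals <- finite_offdiag(distance_matrix(g, weighted))
  if (!length(vals)) 0 else max(vals)
}

#' @rdname diameter
#' @export
eccentricities <- function(g, weighted = FALSE) {
  D <- distance_matrix(g, weighted)
  ecc <- apply(D, 1, function(row) {
    v <- row[is.finite(row)]
    if (length(v)) max(v) else 0
  })
  tibble::tibble(node = g$nodes, eccentricity = unname(ecc))
}

#' @rdname diameter
#' @export
radius <- function(g, weighted = FALSE) {
  n <- length(g$nodes)
  if (n == 0) return(0)
  comp <- component_ids(g)
  largest <- which.max(tabulate(comp))
  ecc <- eccentricities(g, weighted)$eccentricity
  min(ecc[comp == largest])
}

#' @rdname diameter
#' @export
average_path_length <- function(g, weighted = FALSE) {
  vals <- finite_offdiag(distance_matrix(g, weighted))
  if (!length(vals)) NA_real_ else mean(vals)
}

#' Edge density
#'
#' Ratio of the number of edges to the number of possible edges:
#' `m / (n(n-1)/2)` undirected, `m / (n(n-1))` directed. Self-loops are
#' excluded from both numerator and denominator.
#'
#' @param g a `netgraph`.
#' @return number in \[0, 1\], or `NA` when the network has fewer than 2 nodes.
#' @export
edge_density <- function(g) {
  n <- length(g$nodes)
  if (n < 2) return(NA_real_)
  m <- nrow(g$edges) - count_self_loops(g)
  possible <- if (g$directed) n * (n - 1) else n * (n - 1) / 2
  m / possible
}

# triangles through each node + degree on the simple undirected view
triangle_profile <- function(g) {
  adj <- simple_adjacency(g)
  n <- length(adj)
  deg <- lengths(adj)
  tri <- numeric(n)
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    if (length(nb) < 2) next
    t <- 0L
    for (i in seq_along(nb)[-length(nb)]) {
      u <- nb[i]
      t <- t + sum(nb[(i + 1):length(nb)] %in% adj[[u]])
    }
    tri[v] <- t
  }
  list(deg = deg, tri = tri)
}

#' Clustering coefficients
#'
#' `clustering_global()` is the transitivity ratio 3 x triangles / connected
#' triples. `clustering_average_local()` averages each node's local
#' clustering (triangles through the node / `choose(degree, 2)`); nodes of
#' degree < 2 contribute 0 and are included in the mean (set
#' `drop_low_degree = TRUE` to exclude them). Both operate on the underlying
#' undirected simple graph; self-loops are ignored.
#'
#' @param g a `netgraph`.
#' @param drop_low_degree exclude degree < 2 nodes from the local average?
#' @return number in \[0, 1\]; 0 when no node has degree >= 2.
#' @export
clustering_global <- function(g) {
  tp <- triangle_profile(g)
  triples <- sum(choose(tp$deg, 2))
  if (triples == 0) return(0)
  sum(tp$tri) / triples  # = 3 * (#triangles) / #triples: each triangle counted at 3 nodes
}

#' @rdname clustering_global
#' @export
clustering_average_local <- function(g, drop_low_degree = FALSE) {
  lc <- local_clustering(g)$local_clustering
  deg <- triangle_profile(g)$deg
  if (drop_low_degree) {
    lc <- lc[deg >= 2]
    if (!length(lc)) return(0)
  }
  mean(lc)
}

#' @rdname clustering_global
#' @return `local_clustering()`: tibble with columns `node`, `local_clustering`.
#' @export
local_clustering <- function(g) {
  tp <- triangle_profile(g)
  lc <- ifelse(tp$deg >= 2, tp$tri / choose(tp$deg, 2), 0)
  tibble::tibble(node = g$nodes, local_clustering = lc)
}

#' Degree assortativity
#'
#' Pearson correlation of remaining degrees (degree minus one) across the two
#' endpoint lists of every edge; each undirected edge enters in both
#' orientations. Positive values mean similar-degree nodes tend to connect.
#' Computed on the underlying undirected simple graph.
#'
#' @param g a `netgraph`.
#' @return number in \[-1, 1\], or `NA` when undefined (no non-loop edge, or
#'   zero degree variance as in a regular graph).
#' @export
assortativity_degree <- function(g) {
  adj <- simple_adjacency(g)
  deg <- lengths(adj)
  ei <- edge_indices(g)
  keep <- ei$from != ei$to
  a <- ei$from[keep]; b <- ei$to[keep]
  if (!length(a)) return(NA_real_)
  x <- c(deg[a], deg[b]) - 1
  y <- c(deg[b], deg[a]) - 1
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Average number of neighbors
#'
#' Mean degree over nodes; a self-loop contributes 2 to its node's degree on
#' undirected networks.
#'
#' @param g a `netgraph`.
#' @return nonnegative number.
#' @export
average_neighbors <- function(g) {
  n <- length(g$nodes)
  if (n == 0) return(NA_real_)
  mean(node_degrees(g)$degree)
}

#' Modularity of a node partition
#'
#' Newman–Girvan modularity `Q = sum_c (e_c/m - (d_c/2m)^2)` on the
#' undirected weighted view, where `e_c` is the intra-community edge weight,
#' `d_c` the community degree (weight) sum and `m` the total edge weight.
#' The one-community partition always scores 0; two equal disjoint cliques
#' split correctly score 0.5.
#'
#' @param g a `netgraph`.
#' @param partition a data frame with columns `node` and `cluster`, a named
#'   vector mapping node to cluster, or an `mcl_partition` object. Must cover
#'   every node.
#' @return number `Q` (at most 1; can be negative).
#' @export
modularity_score <- function(g, partition) {
  memb <- partition_membership(partition, g$nodes)
  ei <- edge_indices(g)
  w <- ei$weight
  m <- sum(w)
  if (m == 0) return(0)
  cf <- memb[ei$from]; ct <- memb[ei$to]
  # community degree sums: a self-loop adds 2w to its community
  clusters <- sort(unique(memb))
  dsum <- vapply(clusters, function(cl) {
    sum(w[cf == cl]) + sum(w[ct == cl])
  }, 0)
  esum <- vapply(clusters, function(cl) sum(w[cf == cl & ct == cl]), 0)
  sum(esum / m - (dsum / (2 * m))^2)
}

# normalize any accepted partition form to an integer vector aligned to nodes
partition_membership <- function(partition, nodes) {
  if (inherits(partition, "mcl_partition")) {
    memb <- partition$membership
  } else if (is.data.frame(partition)) {
    if (!all(c("node", "cluster") %in% names(partition))) {
      stop("partition data frame needs columns `node` and `cluster`", call. = FALSE)
    }
    memb <- stats::setNames(partition$cluster, partition$node)
  } else if (!is.null(names(partition))) {
    memb <- partition
  } else {
    stop("unsupported partition representation", call. = FALSE)
  }
  missing <- setdiff(nodes, names(memb))
  if (length(missing)) {
    stop("partition does not cover node(s): ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  as.integer(factor(memb[nodes]))
}

#' Minimum s-t cut
#'
#' Minimum total weight of edges whose removal eliminates every path from
#' `s` to `t`, computed as a maximum flow with the shortest-augmenting-path
#' (Edmonds–Karp) method. Each undirected edge is a pair of opposite arcs
#' with the edge weight as capacity.
#'
#' @param g a `netgraph`.
#' @param s,t source and target node labels (`s != t`). When both are `NULL`
#'   the global minimum over a fixed source and all other targets is returned.
#' @return list with `value` (the cut weight) and `cut` (tibble of cut edges
#'   `from`, `to`, `weight`); for the global variant also `s` and `t` used.
#' @export
st_mincut <- function(g, s = NULL, t = NULL) {
  n <- length(g$nodes)
  if (is.null(s) && is.null(t)) {
    if (n < 2) stop("need at least two nodes for a cut", call. = FALSE)
    best <- NULL
    s_lab <- g$nodes[1]
    for (t_lab in g$nodes[-1]) {
      res <- st_mincut(g, s_lab, t_lab)
      if (is.null(best) || res$value < best$value) {
        best <- res
        best$s <- s_lab
        best$t <- t_lab
      }
    }
    return(best)
  }
  si <- match(s, g$nodes); ti <- match(t, g$nodes)
  if (is.na(si) || is.na(ti)) stop("unknown node in s/t", call. = FALSE)
  if (si == ti) stop("`s` and `t` must differ", call. = FALSE)

  cap <- matrix(0, n, n)
  ei <- edge_indices(g)
  for (e in seq_along(ei$from)) {
    a <- ei$from[e]; b <- ei$to[e]; w <- ei$weight[e]
    if (a == b) next
    cap[a, b] <- cap[a, b] + w
    if (!g$directed) cap[b, a] <- cap[b, a] + w
  }
  flow <- matrix(0, n, n)
  value <- 0
  repeat {
    # BFS on residual capacities
    parent <- rep(NA_integer_, n)
    parent[si] <- si
    queue <- si
    while (length(queue) && is.na(parent[ti])) {
      v <- queue[1]; queue <- queue[-1]
      resid <- cap[v, ] - flow[v, ]
      nxt <- which(resid > 1e-12 & is.na(parent))
      parent[nxt] <- v
      queue <- c(queue, nxt)
    }
    if (is.na(parent[ti])) break
    # bottleneck along the path
    path <- ti
    while (path[1] != si) path <- c(parent[path[1]], path)
    aug <- Inf
    for (i in seq_len(length(path) - 1)) {
      aug <- min(aug, cap[path[i], path[i + 1]] - flow[path[i], path[i + 1]])
    }
    for (i in seq_len(length(path) - 1)) {
      flow[path[i], path[i + 1]] <- flow[path[i], path[i + 1]] + aug
      flow[path[i + 1], path[i]] <- flow[path[i + 1], path[i]] - aug
    }
    value <- value + aug
  }
  # S side = nodes reachable in the final residual graph
  reach <- rep(FALSE, n)
  reach[si] <- TRUE
  queue <- si
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nxt <- which(cap[v, ] - flow[v, ] > 1e-12 & !reach)
    reach[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  cross <- if (g$directed) {
    reach[ei$from] & !reach[ei$to]
  } else {
    xor(reach[ei$from], reach[ei$to])
  }
  cross <- cross & ei$from != ei$to
  list(
    value = value,
    cut = g$edges[cross, , drop = FALSE]
  )
}

# ---- motif census -----------------------------------------------------------

motif3_classes <- c("path3", "triangle")
motif4_classes <- c("path4", "star4", "cycle4", "paw", "diamond", "k4")

# classify a connected induced subgraph by edge count (+ degree sequence where
# the edge count is ambiguous)
classify_motif <- function(sub_deg, n_edges, size) {
  if (size == 3) {
    return(if (n_edges == 3) "triangle" else "path3")
  }
  switch(as.character(n_edges),
    "3" = if (max(sub_deg) == 3) "star4" else "path4",
    "4" = if (max(sub_deg) == 3) "paw" else "cycle4",
    "5" = "diamond",
    "6" = "k4"
  )
}

#' Motif census of size 3 or 4
#'
#' Counts node subsets of the given size that induce a connected subgraph,
#' by isomorphism class, on the underlying undirected simple view.
#' Enumeration uses the ESU connected-subgraph expansion; classes are keyed
#' by edge count plus degree sequence. Size-3 classes: `path3`, `triangle`.
#' Size-4 classes: `path4`, `star4`, `cycle4`, `paw`, `diamond`, `k4`.
#'
#' @param g a `netgraph`.
#' @param size motif size, 3 or 4.
#' @return tibble with columns `motif` and `count`, one row per class.
#' @export
motif_census <- function(g, size = 3) {
  if (!size %in% c(3, 4)) stop("`size` must be 3 or 4", call. = FALSE)
  adj <- simple_adjacency(g)
  n <- length(adj)
  classes <- if (size == 3) motif3_classes else motif4_classes
  counts <- stats::setNames(rep(0L, length(classes)), classes)

  count_subgraph <- function(vs) {
    sub_deg <- vapply(vs, function(v) sum(adj[[v]] %in% vs), 0L)
    m_sub <- sum(sub_deg) / 2
    cls <- classify_motif(sort(sub_deg), m_sub, size)
    counts[cls] <<- counts[cls] + 1L
  }

  # ESU: extend {v} with exclusive neighbors having index > v
  extend <- function(sub, ext, v) {
    if (length(sub) == size) {
      count_subgraph(sub)
      return(invisible())
    }
    while (length(ext)) {
      w <- ext[1]
      ext <- ext[-1]
      # exclusive neighborhood of w: neighbors not adjacent to current subgraph
      excl <- adj[[w]][adj[[w]] > v]
      nb_sub <- unique(unlist(adj[sub]))
      excl <- excl[!excl %in% c(sub, nb_sub)]
      extend(c(sub, w), unique(c(ext, excl)), v)
    }
  }
  for (v in seq_len(n)) {
    ext <- adj[[v]][adj[[v]] > v]
    extend(v, ext, v)
  }
  tibble::tibble(motif = classes, count = as.integer(counts))
}

# ---- assembled profile ------------------------------------------------------

#' Topological profile of a network
#'
#' Assembles the graph-level metrics into a one-row tibble: node and edge
#' counts, component count, self-loops, distance metrics (diameter, radius,
#' average path length, average eccentricity), density, clustering
#' coefficients, assortativity, mean degree/closeness/betweenness and average
#' eigenvector centrality, and the structural predicates (directed, DAG,
#' bipartite, chordal). Expensive extras — motif censuses, the global minimum
#' cut and partition modularity — are computed only on request. A metric that
#' fails on a degenerate input becomes `NA`; the profile never aborts.
#'
#' @param g a `netgraph`.
#' @param motifs include `motif3_*` / `motif4_*` columns?
#' @param mincut include the global minimum-cut value?
#' @param partition optional partition (see [modularity_score()]) to score.
#' @param weighted use inverse-weight edge lengths in distance metrics?
#' @return one-row tibble.
#' @export
profile_network <- function(g, motifs = FALSE, mincut = FALSE,
                            partition = NULL, weighted = FALSE) {
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  nt <- safe(node_table(g))
  col_mean <- function(col) {
    if (length(nt) == 1 && is.na(nt)) return(NA_real_)
    v <- nt[[col]]
    if (is.null(v)) NA_real_ else mean(v, na.rm = TRUE)
  }
  bip <- safe(check_bipartite(g)$bipartite)
  prof <- tibble::tibble(
    name = g$name,
    node_count = length(g$nodes),
    edge_count = nrow(g$edges),
    component_count = safe(max(component_ids(g), 0L)),
    self_loop_count = count_self_loops(g),
    is_directed = g$directed,
    is_dag = safe(check_dag(g)),
    is_bipartite = bip,
    is_chordal = safe(check_chordal(g)),
    diameter = safe(diameter(g, weighted)),
    radius = safe(radius(g, weighted)),
    average_path_length = safe(average_path_length(g, weighted)),
    average_eccentricity = safe(mean(eccentricities(g, weighted)$eccentricity)),
    density = safe(edge_density(g)),
    global_clustering_coefficient = safe(clustering_global(g)),
    average_local_clustering = safe(clustering_average_local(g)),
    assortativity_degree = safe(assortativity_degree(g)),
    average_neighbors = safe(average_neighbors(g)),
    mean_degree = col_mean("degree"),
    mean_closeness = col_mean("closeness"),
    mean_betweenness = col_mean("betweenness"),
    average_eigenvector_centrality = col_mean("eigenvector")
  )
  if (!is.null(partition)) {
    prof$modularity <- safe(modularity_score(g, partition))
  }
  if (mincut) {
    prof$mincut_value <- safe(st_mincut(g)$value)
  }
  if (motifs) {
    m3 <- safe(motif_census(g, 3))
    m4 <- safe(motif_census(g, 4))
    if (is.data.frame(m3)) {
      for (i in seq_len(nrow(m3))) prof[[paste0("motif3_", m3$motif[i])]] <- m3$count[i]
    }
    if (is.data.frame(m4)) {
      for (i in seq_len(nrow(m4))) prof[[paste0("motif4_", m4$motif[i])]] <- m4$count[i]
    }
  }
  prof
}
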