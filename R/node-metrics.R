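#' Node degrees
#'
#' Number of links incident on each node. A self-loop contributes 2 to the
#' undirected degree and 1 to each of in- and out-degree on directed
#' networks, which also get `in_degree` and `out_degree` columns.
#'
#' @param g a `netgraph`.
#' @return tibble keyed by `node`.
#' @export
node_degrees <- function(g) {
  n <- length(g$nodes)
  ei <- edge_indices(g)
  if (g$directed) {
    outd <- tabulate(ei$from, nbins = n)
    ind <- tabulate(ei$to, nbins = n)
    tibble::tibble(node = g$nodes, degree = outd + ind,
                   in_degree = ind, out_degree = outd)
  } else {
    deg <- tabulate(c(ei$from, ei$to), nbins = n)  # loop endpoints counted twice
    tibble::tibble(node = g$nodes, degree = deg)
  }
}

#' Betweenness centrality of nodes and edges
#'
#' The fraction-weighted number of shortest paths passing through each node
#' (or edge), accumulated with Brandes' algorithm on unit-length edges.
#' Values are unnormalized; on undirected networks each pair is counted once.
#' Shortest-path multiplicity is handled fractionally. `normalized = TRUE`
#' divides node scores by `(n-1)(n-2)/2` (undirected) or `(n-1)(n-2)`
#' (directed).
#'
#' @param g a `netgraph`.
#' @param normalized rescale node betweenness to \[0, 1\]?
#' @return list with elements `nodes` (tibble `node`, `betweenness`) and
#'   `edges` (tibble `from`, `to`, `betweenness`).
#' @export
betweenness <- function(g, normalized = FALSE) {
  n <- length(g$nodes)
  m <- nrow(g$edges)
  ei <- edge_indices(g)
  nonloop <- which(ei$from != ei$to)
  # adjacency carrying the edge row index alongside each neighbor
  if (g$directed) {
    a <- ei$from[nonloop]; b <- ei$to[nonloop]; id <- nonloop
  } else {
    a <- c(ei$from[nonloop], ei$to[nonloop])
    b <- c(ei$to[nonloop], ei$from[nonloop])
    id <- c(nonloop, nonloop)
  }
  adj <- rep(list(integer()), n)
  adj_eid <- rep(list(integer()), n)
  if (length(a)) {
    ord <- order(a)
    f <- factor(a[ord], levels = seq_len(n))
    adj <- unname(split(b[ord], f))
    adj_eid <- unname(split(id[ord], f))
  }
  cb <- numeric(n)
  ceb <- numeric(m)

  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    pred_eids <- vector("list", n)
    order_visited <- integer(n)
    queue <- integer(n); queue[1] <- s
    head <- 1L; tail <- 1L; cnt <- 0L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      cnt <- cnt + 1L
      order_visited[cnt] <- v
      nb <- adj[[v]]; eid <- adj_eid[[v]]
      for (k in seq_along(nb)) {
        w <- nb[k]
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          tail <- tail + 1L
          queue[tail] <- w
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
          pred_eids[[w]] <- c(pred_eids[[w]], eid[k])
        }
      }
    }
    delta <- numeric(n)
    for (i in rev(seq_len(cnt))) {
      w <- order_visited[i]
      pv <- preds[[w]]; pe <- pred_eids[[w]]
      for (k in seq_along(pv)) {
        v <- pv[k]
        contrib <- sigma[v] / sigma[w] * (1 + delta[w])
        delta[v] <- delta[v] + contrib
        ceb[pe[k]] <- ceb[pe[k]] + contrib
      }
      if (w != s) cb[w] <- cb[w] + delta[w]
    }
  }
  if (!g$directed) {
    cb <- cb / 2
    ceb <- ceb / 2
  }
  if (normalized) {
    denom <- if (g$directed) (n - 1) * (n - 2) else (n - 1) * (n - 2) / 2
    if (denom > 0) cb <- cb / denom
  }
  list(
    nodes = tibble::tibble(node = g$nodes, betweenness = cb),
    edges = tibble::tibble(from = g$edges$from, to = g$edges$to, betweenness = ceb)
  )
}

#' Closeness centrality
#'
#' How quickly a node reaches the rest of the network. For a node `v` with
#' `r` reachable other nodes at total geodesic distance `S`, closeness is
#' `(r / S) * (r / (n - 1))`: the harmonic of the mean distance to reachable
#' nodes, scaled down for nodes that reach only a small component. Isolated
#' nodes score 0. Direction is respected (outgoing distances) on directed
#' networks.
#'
#' @param g a `netgraph`.
#' @param weighted use inverse-weight edge lengths?
#' @return tibble with columns `node`, `closeness`.
#' @export
closeness <- function(g, weighted = FALSE) {
  n <- length(g$nodes)
  D <- distance_matrix(g, weighted)
  cl <- vapply(seq_len(n), function(v) {
    d <- D[v, -v]
    d <- d[is.finite(d)]
    r <- length(d)
    if (r == 0 || n < 2) return(0)
    (r / sum(d)) * (r / (n - 1))
  }, 0)
  tibble::tibble(node = g$nodes, closeness = cl)
}

#' Eigenvector centrality
#'
#' Influence score proportional to the sum of neighbors' scores: the
#' principal eigenvector of the (symmetrized, weighted) adjacency matrix,
#' computed by shifted power iteration and scaled so the maximum entry is 1.
#' The computation is restricted to the largest connected component; nodes
#' outside it score 0.
#'
#' @param g a `netgraph`.
#' @param tol convergence tolerance on the scaled iterate.
#' @param max_iter iteration cap; exceeding it is an error naming the
#'   residual.
#' @return tibble with columns `node`, `eigenvector`.
#' @export
eigenvector_centrality <- function(g, tol = 1e-10, max_iter = 1000) {
  n <- length(g$nodes)
  if (nrow(g$edges) == 0) stop("eigenvector centrality needs at least one edge", call. = FALSE)
  comp <- component_ids(g)
  largest <- which.max(tabulate(comp))
  inside <- comp == largest
  ei <- edge_indices(g)
  nl <- ei$from != ei$to
  # symmetrized mat-vec; self-loops contribute weight to the diagonal
  idx_a <- c(ei$from[nl], ei$to[nl], ei$from[!nl])
  idx_b <- c(ei$to[nl], ei$from[nl], ei$from[!nl])
  w_ab <- c(ei$weight[nl], ei$weight[nl], ei$weight[!nl])
  matvec <- function(x) {
    y <- numeric(n)
    val <- w_ab * x[idx_b]
    agg <- rowsum(val, idx_a)
    y[as.integer(rownames(agg))] <- agg
    y
  }
  x <- ifelse(inside, 1, 0)
  x <- x / max(x)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    y <- matvec(x) + x  # +x shifts the spectrum so bipartite components converge
    y[!inside] <- 0
    mx <- max(y)
    if (mx <= 0) { y <- x; break }
    y <- y / mx
    resid <- max(abs(y - x))
    x <- y
    if (resid < tol) break
    if (iter >= max_iter) {
      stop(sprintf("power iteration did not converge in %d iterations (residual %.3g)",
                   max_iter, resid), call. = FALSE)
    }
  }
  tibble::tibble(node = g$nodes, eigenvector = x)
}

#' Per-node feature table
#'
#' One row per node with degree (plus in/out on directed networks),
#' closeness, betweenness, eigenvector centrality, local clustering
#' coefficient and eccentricity — the inputs to ranking, histograms and the
#' feature correlation matrix.
#'
#' @param g a `netgraph`.
#' @param weighted use inverse-weight edge lengths in distance-based columns?
#' @return tibble keyed by `node`.
#' @export
node_table <- function(g, weighted = FALSE) {
  out <- node_degrees(g)
  out <- dplyr::left_join(out, closeness(g, weighted), by = "node")
  out <- dplyr::left_join(out, betweenness(g)$nodes, by = "node")
  eig <- tryCatch(eigenvector_centrality(g),
                  error = function(e) tibble::tibble(node = g$nodes, eigenvector = NA_real_))
  out <- dplyr::left_join(out, eig, by = "node")
  out <- dplyr::left_join(out, local_clustering(g), by = "node")
  dplyr::left_join(out, eccentricities(g, weighted), by = "node")
}

#' Per-edge feature table
#'
#' One row per stored edge with its weight and edge betweenness.
#'
#' @param g a `netgraph`.
#' @return tibble with columns `from`, `to`, `weight`, `betweenness`.
#' @export
edge_table <- function(g) {
  eb <- betweenness(g)$edges
  dplyr::bind_cols(g$edges, betweenness = eb$betweenness)
}

#' Rank a feature table
#'
#' Stable sort of a node or edge table by one feature, descending or
#' ascending. Ties are broken by key label ascending (`node`, or `from`/`to`
#' for edge tables); rows with `NA` in the feature sort last.
#'
#' @param table a tibble from [node_table()] or [edge_table()].
#' @param by feature column to sort on.
#' @param order `"desc"` (default) or `"asc"`.
#' @param top optional number of rows to keep.
#' @return the reordered tibble.
#' @export
rank_table <- function(table, by, order = c("desc", "asc"), top = NULL) {
  order <- match.arg(order)
  if (!by %in% names(table)) stop("unknown feature: ", by, call. = FALSE)
  v <- xtfrm(table[[by]])
  if (order == "desc") v <- -v
  key <- if ("node" %in% names(table)) table$node else paste(table$from, table$to)
  out <- table[base::order(is.na(table[[by]]), v, key), , drop = FALSE]
  if (!is.null(top)) out <- utils::head(out, top)
  out
}

#' Histogram of a topological feature
#'
#' Equal-width bins spanning `[min, max]` of the non-`NA` values; the last
#' bin is closed on the right. `bins = "auto"` applies Sturges' rule.
#'
#' @param values numeric vector (e.g. a [node_table()] column).
#' @param bins positive integer bin count or `"auto"`.
#' @return a `net_histogram`: tibble with columns `bin_lo`, `bin_hi`,
#'   `count`; counts sum to the number of non-`NA` values.
#' @export
feature_histogram <- function(values, bins = "auto") {
  x <- values[!is.na(values)]
  if (!length(x)) stop("no non-NA values to bin", call. = FALSE)
  if (identical(bins, "auto")) bins <- ceiling(log2(length(x))) + 1
  bins <- max(1L, as.integer(bins))
  lo <- min(x); hi <- max(x)
  if (lo == hi) {
    out <- tibble::tibble(bin_lo = lo, bin_hi = hi, count = length(x))
  } else {
    width <- (hi - lo) / bins
    idx <- pmin(floor((x - lo) / width) + 1L, bins)
    edges <- lo + width * (0:bins)
    out <- tibble::tibble(
      bin_lo = edges[seq_len(bins)],
      bin_hi = edges[seq_len(bins) + 1],
      count = tabulate(idx, nbins = bins)
    )
  }
  class(out) <- c("net_histogram", class(out))
  out
}

#' Pairwise feature correlation matrix
#'
#' Pearson correlation between every pair of node-level features, over the
#' rows where both values are non-`NA` — the numerical upper triangle of an
#' all-against-all feature comparison. A pair with fewer than 3 complete rows
#' or a constant feature gets `NA`.
#'
#' @param table a [node_table()].
#' @param features character vector of >= 2 column names; defaults to all
#'   numeric columns.
#' @return a `net_corr`: symmetric numeric matrix with the features as
#'   dimnames.
#' @export
correlation_matrix <- function(table, features = NULL) {
  if (is.null(features)) {
    features <- setdiff(names(table)[vapply(table, is.numeric, TRUE)], "node")
  }
  if (length(features) < 2) stop("need at least 2 features", call. = FALSE)
  missing <- setdiff(features, names(table))
  if (length(missing)) stop("unknown feature(s): ", paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(table) < 3) stop("need at least 3 rows", call. = FALSE)
  k <- length(features)
  M <- matrix(NA_real_, k, k, dimnames = list(features, features))
  for (i in seq_len(k)) {
    for (j in i:k) {
      x <- table[[features[i]]]
      y <- table[[features[j]]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) >= 3 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
        M[i, j] <- M[j, i] <- stats::cor(x[ok], y[ok])
      }
    }
  }
  structure(M, class = c("net_corr", class(M)))
}

#' @export
print.net_corr <- function(x, ...) {
  cat("<net_corr> pairwise Pearson correlation of", ncol(x), "features\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Scatter-plot coordinates for a feature pair
#'
#' The per-node (x, y) coordinates behind one panel of the all-against-all
#' feature comparison, ready for CSV export. Rows with `NA` in either
#' feature are dropped.
#'
#' @param table a [node_table()].
#' @param x,y feature column names.
#' @return tibble with columns `node`, `x`, `y`.
#' @export
scatter_coordinates <- function(table, x, y) {
  if (!all(c(x, y) %in% names(table))) stop("unknown feature", call. = FALSE)
  out <- tibble::tibble(node = table$node, x = table[[x]], y = table[[y]])
  out[!is.na(out$x) & !is.na(out$y), ]
}

#' Freeman graph centralization
#'
#' Graph-level index of how much the most central node dominates the others:
#' `sum(max(c) - c_i)` normalized by the same sum on the star graph of equal
#' size, where the maximum is attained for degree, closeness and betweenness.
#'
#' @param g a `netgraph`.
#' @param feature `"degree"`, `"closeness"` or `"betweenness"`.
#' @return number in \[0, 1\] (NA for `n < 3`).
#' @export
freeman_centralization <- function(g, feature = c("degree", "closeness", "betweenness")) {
  feature <- match.arg(feature)
  n <- length(g$nodes)
  if (n < 3) return(NA_real_)
  node_vals <- function(gr) {
    switch(feature,
      degree = node_degrees(gr)$degree,
      closeness = closeness(gr)$closeness,
      betweenness = betweenness(gr)$nodes$betweenness
    )
  }
  star <- netgraph(
    tibble::tibble(from = "c", to = paste0("l", seq_len(n - 1))),
    directed = FALSE, name = "star"
  )
  v <- node_vals(g)
  vs <- node_vals(star)
  denom <- sum(max(vs) - vs)
  if (denom == 0) return(NA_real_)
  sum(max(v) - v) / denom
}
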