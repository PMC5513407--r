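#' Markov clustering (MCL)
#'
#' Native implementation of the MCL flow-simulation clustering algorithm.
#' A column-stochastic transition matrix is built from the symmetrized
#' weighted adjacency plus unit self-loops (the standard regularization),
#' then the loop alternates expansion (matrix power), inflation (entrywise
#' power followed by column renormalization) and pruning of entries below
#' `prune_below` (with renormalization) until the largest entry change falls
#' below `tol` or `max_iter` is reached. Clusters are read off the attractor
#' rows (diagonal mass > 0.5): each node joins the attractor holding the
#' largest entry in its column, ties going to the smallest attractor label;
#' nodes in no attractor's support become singletons. Higher inflation gives
#' finer clusters.
#'
#' @param g a non-empty `netgraph`.
#' @param inflation entrywise power, must be > 1; the granularity knob.
#' @param expansion matrix power per iteration.
#' @param prune_below entries below this are zeroed each iteration.
#' @param max_iter iteration cap; hitting it returns `converged = FALSE`.
#' @param tol convergence threshold on the max entry change.
#' @return An `mcl_partition`: list with `membership` (named integer vector,
#'   0-based cluster ids ordered by smallest member label), `n_clusters`,
#'   `inflation`, `iterations`, `converged`.
#' @examples
#' g <- parse_edge_list("A\tB\nB\tC\nA\tC\nD\tE\nE\tF\nD\tF")
#' mcl(g)
#' @export
mcl <- function(g, inflation = 2, expansion = 2, prune_below = 1e-5,
                max_iter = 200, tol = 1e-8) {
  n <- length(g$nodes)
  if (n == 0) stop("cannot cluster an empty network", call. = FALSE)
  if (!is.numeric(inflation) || inflation <= 1) {
    stop("`inflation` must be > 1", call. = FALSE)
  }
  A <- matrix(0, n, n)
  ei <- edge_indices(g)
  for (e in seq_along(ei$from)) {
    a <- ei$from[e]; b <- ei$to[e]; w <- ei$weight[e]
    A[a, b] <- A[a, b] + w
    if (a != b) A[b, a] <- A[b, a] + w
  }
  diag(A) <- diag(A) + 1  # unit self-loops: damps parity effects
  M <- sweep(A, 2, colSums(A), "/")
  iterations <- 0L
  converged <- FALSE
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    M_new <- M
    for (i in seq_len(expansion - 1)) M_new <- M_new %*% M
    M_new <- M_new^inflation
    M_new <- sweep(M_new, 2, colSums(M_new), "/")
    M_new[M_new < prune_below] <- 0
    cs <- colSums(M_new)
    zero <- cs == 0
    if (any(zero)) { M_new[cbind(which(zero), which(zero))] <- 1; cs[zero] <- 1 }
    M_new <- sweep(M_new, 2, cs, "/")
    change <- max(abs(M_new - M))
    M <- M_new
    if (change < tol) { converged <- TRUE; break }
  }

  # attractors: nodes holding return flow in the limit matrix. On perfectly
  # symmetric structures (e.g. an isolated clique) the limit is the uniform
  # block with diagonal 1/k, so any positive diagonal marks an attractor.
  attractors <- which(diag(M) > 0)
  assign_to <- integer(n)
  for (v in seq_len(n)) {
    cand <- attractors[M[attractors, v] > 0]
    if (!length(cand)) {
      assign_to[v] <- -v  # singleton marker
    } else {
      best <- max(M[cand, v])
      winners <- cand[M[cand, v] >= best - 1e-12]
      assign_to[v] <- min(winners)
    }
  }
  # dense 0-based ids ordered by the smallest member label of each cluster
  groups <- split(g$nodes, assign_to)
  smallest <- vapply(groups, min, "")
  ids <- order(order(smallest)) - 1L
  membership <- stats::setNames(
    ids[match(as.character(assign_to), names(groups))],
    g$nodes
  )
  structure(
    list(
      membership = membership,
      n_clusters = length(groups),
      inflation = inflation,
      iterations = iterations,
      converged = converged
    ),
    class = "mcl_partition"
  )
}

#' @export
print.mcl_partition <- function(x, ...) {
  cat(sprintf("<mcl_partition> %d nodes in %d clusters (inflation %.2f, %d iterations%s)\n",
              length(x$membership), x$n_clusters, x$inflation, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Two-column cluster table
#'
#' The searchable (node, cluster) table: one row per node, sorted by cluster
#' id then node label, answering whether two nodes share a cluster.
#'
#' @param part an `mcl_partition` (or anything [modularity_score()] accepts
#'   as a partition).
#' @return tibble with columns `node`, `cluster`.
#' @export
cluster_table <- function(part) {
  memb <- if (inherits(part, "mcl_partition")) part$membership else part
  out <- tibble::tibble(node = names(memb), cluster = as.integer(memb))
  dplyr::arrange(out, .data$cluster, .data$node)
}

#' @export
tidy.mcl_partition <- function(x, ...) cluster_table(x)

#' @export
glance.mcl_partition <- function(x, ...) {
  sizes <- table(x$membership)
  tibble::tibble(
    n_nodes = length(x$membership),
    n_clusters = x$n_clusters,
    largest_cluster = as.integer(max(sizes)),
    inflation = x$inflation,
    iterations = x$iterations,
    converged = x$converged
  )
}
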