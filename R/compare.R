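#' Side-by-side topological profiles of several networks
#'
#' One [profile_network()] row per network, aligned into a single tibble for
#' direct comparison (the multi-network bar-chart view, machine readable).
#' Node-level features enter as means. A metric that fails on one network
#' becomes `NA` there; the comparison never aborts.
#'
#' @param graphs list of `netgraph` objects with unique names.
#' @param metrics optional character vector of profile columns to keep
#'   (besides `name`); default all.
#' @param ... passed to [profile_network()] (e.g. `motifs = TRUE`).
#' @return tibble, one row per network.
#' @export
inter_profile <- function(graphs, metrics = NULL, ...) {
  if (inherits(graphs, "netgraph")) graphs <- list(graphs)
  if (!length(graphs)) stop("need at least one network", call. = FALSE)
  nms <- vapply(graphs, function(g) g$name, "")
  if (anyDuplicated(nms)) {
    stop("duplicate network names: ", paste(unique(nms[duplicated(nms)]), collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::bind_rows(lapply(graphs, profile_network, ...))
  if (!is.null(metrics)) {
    missing <- setdiff(metrics, names(out))
    if (length(missing)) stop("unknown metric(s): ", paste(missing, collapse = ", "), call. = FALSE)
    out <- out[, c("name", setdiff(metrics, "name")), drop = FALSE]
  }
  out
}

#' Intersection of two networks with Venn counts
#'
#' Node overlap by exact label match; edge overlap by canonical endpoint-key
#' match, ignoring weights. The intersection subnetwork carries the first
#' network's weights and can be exported with [write_edge_list()].
#'
#' @param a,b `netgraph` objects, both directed or both undirected.
#' @return A `venn_result`: list with `nodes` and `edges` count tibbles
#'   (columns `only_a`, `shared`, `only_b`) and `intersection` (a
#'   `netgraph`).
#' @examples
#' a <- parse_edge_list("A\tB\nB\tC", name = "a")
#' b <- parse_edge_list("B\tC\nC\tD", name = "b")
#' intersect_networks(a, b)
#' @export
intersect_networks <- function(a, b) {
  if (a$directed != b$directed) {
    stop("cannot intersect a directed with an undirected network", call. = FALSE)
  }
  shared_nodes <- intersect(a$nodes, b$nodes)
  key <- function(g) paste(g$edges$from, g$edges$to, sep = "\r")
  ka <- key(a); kb <- key(b)
  shared_edge <- ka %in% kb
  inter <- netgraph(a$edges[shared_edge, , drop = FALSE], directed = a$directed,
                    name = paste0(a$name, "&", b$name),
                    nodes = if (length(shared_nodes)) shared_nodes else NULL)
  structure(
    list(
      nodes = tibble::tibble(
        only_a = length(a$nodes) - length(shared_nodes),
        shared = length(shared_nodes),
        only_b = length(b$nodes) - length(shared_nodes)
      ),
      edges = tibble::tibble(
        only_a = sum(!shared_edge),
        shared = sum(shared_edge),
        only_b = length(kb) - sum(shared_edge)
      ),
      intersection = inter,
      names = c(a = a$name, b = b$name)
    ),
    class = "venn_result"
  )
}

#' @export
print.venn_result <- function(x, ...) {
  cat(sprintf("<venn_result> %s vs %s\n", x$names[["a"]], x$names[["b"]]))
  cat(sprintf("  nodes: %d only in %s | %d shared | %d only in %s\n",
              x$nodes$only_a, x$names[["a"]], x$nodes$shared,
              x$nodes$only_b, x$names[["b"]]))
  cat(sprintf("  edges: %d only in %s | %d shared | %d only in %s\n",
              x$edges$only_a, x$names[["a"]], x$edges$shared,
              x$edges$only_b, x$names[["b"]]))
  invisible(x)
}

#' @export
tidy.venn_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$nodes, what = "nodes", .before = 1),
    dplyr::mutate(x$edges, what = "edges", .before = 1)
  )
}

#' @export
glance.venn_result <- function(x, ...) {
  tibble::tibble(
    shared_nodes = x$nodes$shared,
    shared_edges = x$edges$shared,
    jaccard_nodes = x$nodes$shared / sum(unlist(x$nodes)),
    jaccard_edges = x$edges$shared / sum(unlist(x$edges))
  )
}

#' Monopartite projections of a bipartite network
#'
#' Splits a bipartite network into its two one-sided projections: within a
#' side, two nodes are connected when they share at least `min_shared`
#' neighbors on the other side, with the number of shared neighbors as edge
#' weight (e.g. a disease-disease network through common genes). Side 0 is
#' the side containing the lexicographically smallest node label, so the
#' output is deterministic. Non-bipartite input is an error naming an odd
#' cycle witness. Networks carrying a stored 2-coloring (e.g. from
#' [gen_bipartite()]) use it directly, which also fixes the side of isolated
#' nodes; otherwise the coloring is derived with [check_bipartite()].
#'
#' @param g a bipartite `netgraph`.
#' @param min_shared minimum shared-neighbor count for a projected edge.
#' @return list with elements `side0` and `side1`, both `netgraph`s whose
#'   node sets are exactly the two sides.
#' @examples
#' g <- parse_edge_list("g1\td1\ng2\td1")
#' project_bipartite(g)
#' @export
project_bipartite <- function(g, min_shared = 1) {
  if (!is.null(g$bipartite_sides)) {
    side <- g$bipartite_sides
    bad <- side[g$edges$from] == side[g$edges$to]
    if (any(bad)) {
      stop("stored bipartite sides are violated by edge ",
           g$edges$from[bad][1], " - ", g$edges$to[bad][1], call. = FALSE)
    }
  } else {
    bip <- check_bipartite(g)
    if (!bip$bipartite) {
      stop("network is not bipartite; odd cycle: ",
           paste(bip$odd_cycle, collapse = " - "), call. = FALSE)
    }
    side <- stats::setNames(bip$coloring$side, bip$coloring$node)
  }
  # side 0 = side of the lexicographically smallest label, per component-free
  # global rule
  if (side[[min(g$nodes)]] != 0L) side <- 1L - side
  project_one <- function(s) {
    members <- g$nodes[side[g$nodes] == s]
    adj <- simple_adjacency(g)
    midx <- match(members, g$nodes)
    pairs_from <- character(); pairs_to <- character(); wt <- integer()
    if (length(members) >= 2) {
      nb <- lapply(midx, function(v) adj[[v]])
      for (i in seq_along(members)[-length(members)]) {
        for (j in (i + 1):length(members)) {
          common <- sum(nb[[i]] %in% nb[[j]])
          if (common >= min_shared) {
            pairs_from <- c(pairs_from, members[i])
            pairs_to <- c(pairs_to, members[j])
            wt <- c(wt, common)
          }
        }
      }
    }
    netgraph(tibble::tibble(from = pairs_from, to = pairs_to, weight = as.numeric(wt)),
             directed = FALSE, name = paste0(g$name, "_side", s), nodes = members)
  }
  list(side0 = project_one(0L), side1 = project_one(1L))
}
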