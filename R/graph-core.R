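#' Construct a network from an edge table
#'
#' The central container of the package. Edges are given as a data frame with
#' columns `from` and `to` (character) and optionally `weight` (positive
#' numeric, default 1). For undirected networks each edge is stored under its
#' canonical key (endpoints in lexicographic order) and duplicate edges are
#' collapsed with their weights summed; the number of collapsed input rows is
#' recorded. Self-loops are retained.
#'
#' @param edges data frame with columns `from`, `to` and optionally `weight`.
#' @param directed logical; are the edges directed arcs?
#' @param name network name used in comparison tables.
#' @param max_edges capacity limit; networks with more edges (after
#'   collapsing) are rejected. Defaults to 50,000.
#' @param nodes optional character vector of node labels fixing the node
#'   order; must contain every edge endpoint. Extra labels become isolated
#'   nodes. Defaults to endpoints in order of first appearance.
#' @return An object of class `netgraph`.
#' @examples
#' g <- netgraph(data.frame(from = c("A", "B"), to = c("B", "C")))
#' g
#' @export
netgraph <- function(edges, directed = FALSE, name = "network",
                     max_edges = 50000, nodes = NULL) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) > 0 && !all(c("from", "to") %in% names(edges))) {
    stop("`edges` must have columns `from` and `to`", call. = FALSE)
  }
  from <- as.character(edges$from %||% character())
  to <- as.character(edges$to %||% character())
  weight <- if ("weight" %in% names(edges)) as.numeric(edges$weight) else rep(1, length(from))
  if (anyNA(from) || anyNA(to)) stop("edge endpoints must not be NA", call. = FALSE)
  if (anyNA(weight) || any(!is.finite(weight)) || any(weight <= 0)) {
    stop("edge weights must be finite and > 0", call. = FALSE)
  }

  endpoint_order <- unique(as.vector(rbind(from, to)))
  if (is.null(nodes)) {
    nodes <- endpoint_order
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("`nodes` contains duplicate labels", call. = FALSE)
    missing <- setdiff(endpoint_order, nodes)
    if (length(missing)) {
      stop("edge endpoints not in `nodes`: ", paste(missing, collapse = ", "), call. = FALSE)
    }
  }

  if (!directed) {
    swap <- from > to
    tmp <- from[swap]
    from[swap] <- to[swap]
    to[swap] <- tmp
  }
  key <- paste(from, to, sep = "\r")
  collapsed <- 0L
  if (anyDuplicated(key)) {
    collapsed <- length(key) - length(unique(key))
    agg <- rowsum(weight, group = factor(key, levels = unique(key)))
    first <- !duplicated(key)
    from <- from[first]
    to <- to[first]
    weight <- as.vector(agg)
  }
  if (length(from) > max_edges) {
    stop(sprintf("network has %d edges, exceeding the maximum of %d",
                 length(from), max_edges), call. = FALSE)
  }

  structure(
    list(
      name = name,
      directed = directed,
      nodes = nodes,
      edges = tibble::tibble(from = from, to = to, weight = weight),
      multiplicity_collapsed = collapsed,
      max_edges = max_edges
    ),
    class = "netgraph"
  )
}

#' @export
print.netgraph <- function(x, ...) {
  cat(sprintf("<netgraph> %s: %d nodes, %d %s edges%s\n",
              x$name, length(x$nodes), nrow(x$edges),
              if (x$directed) "directed" else "undirected",
              if (x$multiplicity_collapsed > 0)
                sprintf(" (%d duplicate input edges collapsed)", x$multiplicity_collapsed)
              else ""))
  if (nrow(x$edges)) print(utils::head(x$edges, 5))
  invisible(x)
}

#' Number of nodes / edges of a network
#' @param g a `netgraph`.
#' @return integer count.
#' @export
n_nodes <- function(g) length(g$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(g) nrow(g$edges)

#' @export
tidy.netgraph <- function(x, ...) x$edges

#' @export
glance.netgraph <- function(x, ...) {
  tibble::tibble(
    name = x$name,
    nodes = length(x$nodes),
    edges = nrow(x$edges),
    directed = x$directed,
    self_loops = count_self_loops(x),
    collapsed_duplicates = x$multiplicity_collapsed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a tab-delimited edge list
#'
#' Reads the standard two-column (optional third weight column) tab-delimited
#' edge-list format, one interaction per line, node labels as strings.
#' Duplicate undirected edges (same canonical endpoint pair) are collapsed
#' with summed weights; self-loops are kept. Empty lines and lines starting
#' with `#` are skipped. Fields are stripped of surrounding whitespace; labels
#' are otherwise matched exactly and case-sensitively.
#'
#' @param text edge list as a single string (lines separated by newlines) or a
#'   character vector of lines.
#' @param sep field separator, `"\t"` (default) or `","` for CSV export parity.
#' @inheritParams netgraph
#' @return A [netgraph].
#' @seealso [read_edge_list()] to read from a file, [write_edge_list()] for
#'   the inverse.
#' @examples
#' parse_edge_list("A\tB\nB\tC")
#' @export
parse_edge_list <- function(text, directed = FALSE, name = "network",
                            max_edges = 50000, sep = "\t") {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else as.character(text)
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (!length(lines)) {
    return(netgraph(tibble::tibble(from = character(), to = character()),
                    directed = directed, name = name, max_edges = max_edges))
  }
  fields <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad)) {
    stop(sprintf("line %d: expected 2 or 3 %s-separated fields, found %d",
                 lineno[bad[1]], if (sep == "\t") "tab" else "comma", nf[bad[1]]),
         call. = FALSE)
  }
  from <- trimws(vapply(fields, `[[`, "", 1L))
  to <- trimws(vapply(fields, `[[`, "", 2L))
  weight <- rep(1, length(from))
  has_w <- nf == 3L
  if (any(has_w)) {
    wtxt <- trimws(vapply(fields[has_w], `[[`, "", 3L))
    w <- suppressWarnings(as.numeric(wtxt))
    bad_w <- which(is.na(w) | !is.finite(w) | w <= 0)
    if (length(bad_w)) {
      stop(sprintf("line %d: weight '%s' is not a positive number",
                   lineno[has_w][bad_w[1]], wtxt[bad_w[1]]), call. = FALSE)
    }
    weight[has_w] <- w
  }
  if (any(from == "" | to == "")) {
    i <- which(from == "" | to == "")[1]
    stop(sprintf("line %d: empty node label", lineno[i]), call. = FALSE)
  }
  netgraph(tibble::tibble(from = from, to = to, weight = weight),
           directed = directed, name = name, max_edges = max_edges)
}

#' @rdname parse_edge_list
#' @param path file to read.
#' @export
read_edge_list <- function(path, directed = FALSE, name = NULL,
                           max_edges = 50000, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  parse_edge_list(readLines(path, warn = FALSE), directed = directed,
                  name = name %||% sub("\\.[^.]*$", "", basename(path)),
                  max_edges = max_edges, sep = sep)
}

#' Serialize a network as a delimited edge list
#'
#' Inverse of [parse_edge_list()]: `parse_edge_list(write_edge_list(g))`
#' reproduces `g` up to node order.
#'
#' @param g a `netgraph`.
#' @param include_weights write the weight as a third column?
#' @param sep field separator (`"\t"` or `","`).
#' @param path optional file to write to; when `NULL` the text is returned.
#' @return The edge-list text (invisibly when `path` is given).
#' @export
write_edge_list <- function(g, include_weights = FALSE, sep = "\t", path = NULL) {
  e <- g$edges
  lines <- if (include_weights) {
    paste(e$from, e$to, format(e$weight, trim = TRUE, digits = 15, scientific = FALSE), sep = sep)
  } else {
    paste(e$from, e$to, sep = sep)
  }
  text <- if (length(lines)) paste0(paste(lines, collapse = "\n"), "\n") else ""
  if (is.null(path)) return(text)
  writeLines(text, path, sep = "")
  invisible(text)
}

#' Count self-loops
#'
#' Number of edges whose two endpoints are the same node.
#'
#' @param g a `netgraph`.
#' @return nonnegative integer.
#' @export
count_self_loops <- function(g) sum(g$edges$from == g$edges$to)

# ---- internal index machinery -----------------------------------------------

# Integer endpoint indices of every edge (1-based into g$nodes).
edge_indices <- function(g) {
  idx <- match(c(g$edges$from, g$edges$to), g$nodes)
  m <- nrow(g$edges)
  list(from = idx[seq_len(m)], to = idx[m + seq_len(m)], weight = g$edges$weight)
}

# Adjacency list as a list of integer neighbor vectors.
# mode "all" ignores direction; "out"/"in" respect it.
# simple = TRUE drops self-loops and parallel entries (undirected storage is
# already parallel-free; directed graphs may hold both u->v and v->u, which
# "all" de-duplicates when simple).
adjacency_list <- function(g, mode = c("all", "out", "in"), simple = FALSE) {
  mode <- match.arg(mode)
  n <- length(g$nodes)
  ei <- edge_indices(g)
  src <- ei$from; dst <- ei$to
  if (mode == "all") {
    a <- c(src, dst); b <- c(dst, src)
  } else if (mode == "out") {
    if (g$directed) { a <- src; b <- dst } else { a <- c(src, dst); b <- c(dst, src) }
  } else { # "in"
    if (g$directed) { a <- dst; b <- src } else { a <- c(src, dst); b <- c(dst, src) }
  }
  if (simple) {
    keep <- a != b
    a <- a[keep]; b <- b[keep]
    key <- (a - 1) * n + b
    keep <- !duplicated(key)
    a <- a[keep]; b <- b[keep]
  }
  adj <- vector("list", n)
  if (length(a)) {
    ord <- order(a, b)
    a <- a[ord]; b <- b[ord]
    split_b <- split(b, factor(a, levels = seq_len(n)))
    adj <- unname(split_b)
  } else {
    adj <- rep(list(integer()), n)
  }
  adj
}

# Undirected simple view used by clustering / motifs / chordality: sorted
# neighbor vectors, no loops, no parallels.
simple_adjacency <- function(g) adjacency_list(g, mode = "all", simple = TRUE)

# ---- structural predicates --------------------------------------------------

#' Test whether a network is bipartite
#'
#' Attempts a proper 2-coloring of the underlying undirected graph by BFS,
#' component by component. Any self-loop forces a negative answer. When the
#' graph is not bipartite an odd cycle witnessing the failure is returned.
#'
#' @param g a `netgraph`.
#' @return A list with elements `bipartite` (logical), `coloring` (tibble with
#'   columns `node`, `side` in \{0,1\} when bipartite, otherwise `NULL`) and
#'   `odd_cycle` (character vector of node labels forming an odd cycle when
#'   not bipartite, otherwise `NULL`).
#' @export
check_bipartite <- function(g) {
  n <- length(g$nodes)
  if (count_self_loops(g) > 0) {
    v <- g$edges$from[g$edges$from == g$edges$to][1]
    return(list(bipartite = FALSE, coloring = NULL, odd_cycle = v))
  }
  adj <- simple_adjacency(g)
  color <- rep(NA_integer_, n)
  parent <- rep(NA_integer_, n)
  for (start in seq_len(n)) {
    if (!is.na(color[start])) next
    color[start] <- 0L
    queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.na(color[w])) {
          color[w] <- 1L - color[v]
          parent[w] <- v
          queue <- c(queue, w)
        } else if (color[w] == color[v]) {
          return(list(bipartite = FALSE, coloring = NULL,
                      odd_cycle = g$nodes[odd_cycle_from_conflict(v, w, parent)]))
        }
      }
    }
  }
  list(
    bipartite = TRUE,
    coloring = tibble::tibble(node = g$nodes, side = color),
    odd_cycle = NULL
  )
}

# Walk both conflict endpoints up the BFS tree to their lowest common
# ancestor; the two tree paths plus the conflicting edge form an odd cycle.
odd_cycle_from_conflict <- function(v, w, parent) {
  path_up <- function(x) {
    p <- x
    while (!is.na(parent[x])) { x <- parent[x]; p <- c(p, x) }
    p
  }
  pv <- path_up(v); pw <- path_up(w)
  common <- intersect(pv, pw)
  lca <- common[1]
  c(rev(pv[seq_len(match(lca, pv))]), pw[seq_len(match(lca, pw) - 1)])
}

#' Test whether a network is a directed acyclic graph
#'
#' For directed networks, checks for a topological ordering with Kahn's
#' algorithm. An undirected edge is treated as a 2-cycle, so an undirected
#' network is a DAG only when it has no edges.
#'
#' @param g a `netgraph`.
#' @return logical scalar.
#' @export
check_dag <- function(g) {
  if (!g$directed) return(nrow(g$edges) == 0L)
  n <- length(g$nodes)
  ei <- edge_indices(g)
  if (any(ei$from == ei$to)) return(FALSE)
  out_adj <- adjacency_list(g, mode = "out")
  indeg <- tabulate(ei$to, nbins = n)
  queue <- which(indeg == 0L)
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    seen <- seen + 1L
    for (w in out_adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  seen == n
}

#' Test whether a network is chordal
#'
#' A graph is chordal when every cycle of four or more nodes has a chord,
#' equivalently when it admits a perfect elimination ordering. The ordering is
#' sought with lexicographic BFS and then verified, on the underlying
#' undirected simple graph (self-loops ignored).
#'
#' @param g a `netgraph`.
#' @return logical scalar.
#' @export
check_chordal <- function(g) {
  n <- length(g$nodes)
  if (n == 0) return(TRUE)
  adj <- simple_adjacency(g)
  # LexBFS via partition refinement: maintain an ordered list of label classes.
  classes <- list(seq_len(n))
  order_out <- integer(n)
  for (i in seq_len(n)) {
    v <- classes[[1]][1]
    classes[[1]] <- classes[[1]][-1]
    if (!length(classes[[1]])) classes[[1]] <- NULL
    order_out[i] <- v
    nb <- adj[[v]]
    if (length(classes)) {
      new_classes <- list()
      for (cl in classes) {
        hit <- cl[cl %in% nb]
        miss <- cl[!cl %in% nb]
        if (length(hit)) new_classes <- c(new_classes, list(hit))
        if (length(miss)) new_classes <- c(new_classes, list(miss))
      }
      classes <- new_classes
    }
  }
  # Perfect elimination order is the reverse of the LexBFS order; verify it.
  peo <- rev(order_out)
  pos <- integer(n)
  pos[peo] <- seq_len(n)
  for (v in peo) {
    later <- adj[[v]][pos[adj[[v]]] > pos[v]]
    if (length(later) > 1) {
      u <- later[which.min(pos[later])]  # first later neighbor
      rest <- setdiff(later, u)
      if (!all(rest %in% adj[[u]])) return(FALSE)
    }
  }
  TRUE
}

#' Weakly connected components
#'
#' Direction is ignored. Component ids are 0-based and ordered by the
#' lexicographically smallest node label each component contains.
#'
#' @param g a `netgraph`.
#' @return tibble with columns `node` and `component`.
#' @export
connected_components <- function(g) {
  n <- length(g$nodes)
  comp <- component_ids(g)
  # reorder ids by smallest member label
  smallest <- vapply(split(g$nodes, comp), min, "")
  rank <- order(order(smallest))
  tibble::tibble(node = g$nodes, component = rank[comp] - 1L)
}

# integer component labels (arbitrary ids, 1-based), internal
component_ids <- function(g) {
  n <- length(g$nodes)
  adj <- adjacency_list(g, mode = "all")
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (start in seq_len(n)) {
    if (!is.na(comp[start])) next
    cid <- cid + 1L
    queue <- start
    comp[start] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[is.na(comp[nb])]
      comp[new] <- cid
      queue <- c(queue, new)
    }
  }
  comp
}
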