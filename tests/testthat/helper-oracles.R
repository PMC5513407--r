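# Independent brute-force oracles. These deliberately share no code with the
# package implementation: dense matrices, exhaustive enumeration and closed
# formulas only.

# dense adjacency (0/1) honoring direction; loops on the diagonal
oracle_adjacency <- function(g) {
  n <- length(g$nodes)
  A <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  for (e in seq_len(nrow(g$edges))) {
    i <- match(g$edges$from[e], g$nodes)
    j <- match(g$edges$to[e], g$nodes)
    A[i, j] <- 1
    if (!g$directed) A[j, i] <- 1
  }
  A
}

# all-pairs geodesic hop counts by Floyd-Warshall
oracle_floyd_warshall <- function(g) {
  A <- oracle_adjacency(g)
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  D
}

# reachability closure -> number of weakly connected components
oracle_component_count <- function(g) {
  A <- oracle_adjacency(g)
  A <- pmax(A, t(A))           # ignore direction
  R <- diag(nrow(A)) + A
  for (k in seq_len(nrow(A))) R <- sign(R %*% R)
  nrow(unique(R > 0))
}

# node betweenness by explicit enumeration of all shortest paths
oracle_betweenness_nodes <- function(g) {
  n <- length(g$nodes)
  D <- oracle_floyd_warshall(g)
  A <- oracle_adjacency(g)
  diag(A) <- 0
  # all shortest paths s->t by recursive expansion along distance-decreasing arcs
  paths_between <- function(s, t) {
    if (s == t) return(list(s))
    out <- list()
    for (v in which(A[s, ] > 0)) {
      if (D[s, t] == 1 + D[v, t]) {
        for (p in paths_between(v, t)) out <- c(out, list(c(s, p)))
      }
    }
    out
  }
  cb <- numeric(n)
  pairs <- which(is.finite(D) & D > 0, arr.ind = TRUE)
  if (!g$directed) pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  for (r in seq_len(nrow(pairs))) {
    s <- pairs[r, 1]; t <- pairs[r, 2]
    ps <- paths_between(s, t)
    for (p in ps) {
      interior <- p[-c(1, length(p))]
      cb[interior] <- cb[interior] + 1 / length(ps)
    }
  }
  stats::setNames(cb, g$nodes)
}

# closeness from the Floyd-Warshall matrix with reachable-set scaling
oracle_closeness <- function(g) {
  D <- oracle_floyd_warshall(g)
  n <- nrow(D)
  vapply(seq_len(n), function(v) {
    d <- D[v, -v]
    d <- d[is.finite(d)]
    if (!length(d)) return(0)
    (length(d) / sum(d)) * (length(d) / (n - 1))
  }, 0)
}

# principal eigenvector of the dense symmetrized weighted adjacency,
# restricted to the largest component, scaled to max 1
oracle_eigenvector <- function(g) {
  n <- length(g$nodes)
  A <- matrix(0, n, n)
  for (e in seq_len(nrow(g$edges))) {
    i <- match(g$edges$from[e], g$nodes)
    j <- match(g$edges$to[e], g$nodes)
    w <- g$edges$weight[e]
    if (i == j) A[i, i] <- A[i, i] + w
    else { A[i, j] <- A[i, j] + w; A[j, i] <- A[j, i] + w }
  }
  U <- pmax(A, t(A)) > 0
  R <- diag(n) + U
  for (k in seq_len(n)) R <- sign(R %*% R)
  comp <- match(apply(R > 0, 1, paste, collapse = ""), unique(apply(R > 0, 1, paste, collapse = "")))
  largest <- which.max(tabulate(comp))
  inside <- comp == largest
  sub <- A[inside, inside, drop = FALSE]
  ev <- eigen(sub, symmetric = TRUE)
  v <- ev$vectors[, which.max(ev$values)]
  if (max(v) < max(-v)) v <- -v
  out <- numeric(n)
  out[inside] <- v / max(v)
  stats::setNames(out, g$nodes)
}

# exhaustive 2-coloring test
oracle_bipartite <- function(g) {
  n <- length(g$nodes)
  A <- oracle_adjacency(g)
  A <- pmax(A, t(A))
  if (any(diag(A) > 0)) return(FALSE)
  for (mask in 0:(2^n - 1)) {
    color <- bitwAnd(mask %/% 2^(seq_len(n) - 1), 1) == 1
    if (!any(A[color, color] > 0) && !any(A[!color, !color] > 0)) return(TRUE)
  }
  FALSE
}

# cycle detection via adjacency-matrix powers (directed)
oracle_has_cycle <- function(g) {
  A <- oracle_adjacency(g)
  n <- nrow(A)
  P <- A
  for (k in seq_len(n)) {
    if (any(diag(P) > 0)) return(TRUE)
    P <- sign(P %*% A)
  }
  FALSE
}

# chordality by exhaustive chordless-cycle search: a node subset of size >= 4
# whose induced subgraph is a cycle IS a chordless cycle
oracle_chordal <- function(g) {
  A <- oracle_adjacency(g)
  A <- pmax(A, t(A)); diag(A) <- 0
  n <- nrow(A)
  if (n < 4) return(TRUE)
  for (k in 4:n) {
    for (sub in utils::combn(n, k, simplify = FALSE)) {
      S <- A[sub, sub]
      deg <- rowSums(S)
      if (all(deg == 2) && oracle_connected_submatrix(S)) return(FALSE)
    }
  }
  TRUE
}

oracle_connected_submatrix <- function(S) {
  k <- nrow(S)
  R <- diag(k) + S
  for (i in seq_len(k)) R <- sign(R %*% R)
  all(R > 0)
}

# brute-force motif census over all C(n, size) subsets
oracle_motifs <- function(g, size) {
  A <- oracle_adjacency(g)
  A <- pmax(A, t(A)); diag(A) <- 0
  n <- nrow(A)
  classes <- if (size == 3) c("path3", "triangle")
             else c("path4", "star4", "cycle4", "paw", "diamond", "k4")
  counts <- stats::setNames(rep(0L, length(classes)), classes)
  if (n < size) return(counts)
  for (sub in utils::combn(n, size, simplify = FALSE)) {
    S <- A[sub, sub]
    if (!oracle_connected_submatrix(S)) next
    m <- sum(S) / 2
    deg <- sort(rowSums(S))
    cls <- if (size == 3) {
      if (m == 3) "triangle" else "path3"
    } else if (m == 3) {
      if (max(deg) == 3) "star4" else "path4"
    } else if (m == 4) {
      if (max(deg) == 3) "paw" else "cycle4"
    } else if (m == 5) "diamond" else "k4"
    counts[cls] <- counts[cls] + 1L
  }
  counts
}

# minimum s-t cut by enumerating all edge subsets
oracle_st_mincut <- function(g, s, t) {
  si <- match(s, g$nodes); ti <- match(t, g$nodes)
  ed <- g$edges[g$edges$from != g$edges$to, ]
  m <- nrow(ed)
  n <- length(g$nodes)
  best <- Inf
  connected_after_removal <- function(keep) {
    A <- matrix(0, n, n)
    for (e in which(keep)) {
      i <- match(ed$from[e], g$nodes); j <- match(ed$to[e], g$nodes)
      A[i, j] <- 1
      if (!g$directed) A[j, i] <- 1
    }
    R <- diag(n) + A
    for (k in seq_len(n)) R <- sign(R %*% R)
    R[si, ti] > 0
  }
  for (mask in 0:(2^m - 1)) {
    removed <- bitwAnd(mask %/% 2^(seq_len(m) - 1), 1) == 1
    if (!connected_after_removal(!removed)) {
      best <- min(best, sum(ed$weight[removed]))
    }
  }
  best
}

# direct Newman-Girvan double sum over node pairs
oracle_modularity <- function(g, membership) {
  nodes <- g$nodes
  n <- length(nodes)
  W <- matrix(0, n, n)
  for (e in seq_len(nrow(g$edges))) {
    i <- match(g$edges$from[e], nodes); j <- match(g$edges$to[e], nodes)
    w <- g$edges$weight[e]
    if (i == j) W[i, i] <- W[i, i] + 2 * w
    else { W[i, j] <- W[i, j] + w; W[j, i] <- W[j, i] + w }
  }
  two_m <- sum(W)
  k <- rowSums(W)
  memb <- membership[nodes]
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (memb[i] == memb[j]) q <- q + W[i, j] / two_m - k[i] * k[j] / two_m^2
  }
  q
}

# does the graph contain an odd cycle? (via bipartite double cover reasoning:
# odd cycle exists iff some node reaches itself by an odd walk no longer than n)
oracle_has_odd_cycle <- function(g) {
  A <- oracle_adjacency(g)
  A <- pmax(A, t(A))
  n <- nrow(A)
  if (any(diag(A) > 0)) return(TRUE)
  diag(A) <- 0
  P <- A
  for (len in seq_len(2 * n)) {
    if (len %% 2 == 1 && any(diag(P) > 0)) return(TRUE)
    P <- sign(P %*% A)
  }
  FALSE
}
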