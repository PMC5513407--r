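#' Seeded random-graph generators
#'
#' Reproducible example networks in the four classical families: Erdős–Rényi
#' G(n, p), Barabási–Albert preferential attachment, Watts–Strogatz
#' small-world rewiring and random bipartite graphs. Every generator takes an
#' explicit integer seed and touches no global RNG state: the same call always
#' yields a byte-identical [write_edge_list()] output.
#'
#' @param n number of nodes.
#' @param p edge (or rewiring / cross-link) probability in \[0, 1\].
#' @param seed integer seed.
#' @param name network name.
#' @return A [netgraph].
#' @name generators
NULL

check_prob <- function(p, what = "p") {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    stop(sprintf("`%s` must be a probability in [0, 1]", what), call. = FALSE)
  }
}

node_labels <- function(n, prefix = "v") {
  sprintf("%s%0*d", prefix, nchar(as.character(n)), seq_len(n))
}

#' @describeIn generators G(n, p): each of the `choose(n, 2)` node pairs is an
#'   edge independently with probability `p`.
#' @export
gen_erdos_renyi <- function(n, p, seed, name = "er") {
  if (!is.numeric(n) || n < 1) stop("`n` must be a positive integer", call. = FALSE)
  check_prob(p)
  n <- as.integer(n)
  labels <- node_labels(n)
  npairs <- n * (n - 1) / 2
  withr::with_seed(seed, {
    m <- stats::rbinom(1, npairs, p)
    picks <- if (m > 0) sort(sample.int(npairs, m)) else integer()
  })
  pair <- pair_from_index(picks, n)
  netgraph(tibble::tibble(from = labels[pair$i], to = labels[pair$j]),
           directed = FALSE, name = name, nodes = labels,
           max_edges = max(npairs, 50000))
}

# Map linear indices 1..choose(n,2) to pairs (i < j), row-major over i.
pair_from_index <- function(k, n) {
  if (!length(k)) return(list(i = integer(), j = integer()))
  # cumulative pair counts after finishing row i: i*n - i*(i+1)/2
  i <- findInterval(k - 1, cumsum((n - 1):1), left.open = FALSE) + 1L
  offset <- c(0, cumsum((n - 1):1))[i]
  j <- i + (k - offset)
  list(i = i, j = as.integer(j))
}

#' @describeIn generators Barabási–Albert growth: starting from a clique on
#'   `m_a` nodes, each new node attaches to `m_a` distinct existing nodes with
#'   probability proportional to their current degree. With `m_a = 1` the
#'   result is a tree.
#' @param m_a edges added per new node, `1 <= m_a < n`.
#' @export
gen_barabasi_albert <- function(n, m_a, seed, name = "ba") {
  n <- as.integer(n); m_a <- as.integer(m_a)
  if (m_a < 1 || m_a >= n) stop("`m_a` must satisfy 1 <= m_a < n", call. = FALSE)
  labels <- node_labels(n)
  # seed clique on the first m_a nodes (a single node when m_a = 1)
  from <- integer(); to <- integer()
  if (m_a > 1) {
    pr <- utils::combn(m_a, 2)
    from <- pr[1, ]; to <- pr[2, ]
  }
  # multiset of edge endpoints drives preferential attachment
  endpoints <- c(from, to)
  if (!length(endpoints)) endpoints <- 1L  # lone seed node: first attachment is forced
  withr::with_seed(seed, {
    for (v in (m_a + 1):n) {
      targets <- integer()
      while (length(targets) < m_a) {
        cand <- endpoints[sample.int(length(endpoints), 1)]
        if (!cand %in% targets) targets <- c(targets, cand)
      }
      from <- c(from, rep(v, m_a))
      to <- c(to, targets)
      endpoints <- c(endpoints, rep(v, m_a), targets)
      if (v == m_a + 1 && m_a == 1) endpoints <- setdiff_first_placeholder(endpoints)
    }
  })
  netgraph(tibble::tibble(from = labels[from], to = labels[to]),
           directed = FALSE, name = name, nodes = labels)
}

# With m_a = 1 the lone seed node starts with a placeholder endpoint so the
# first attachment can be drawn; after the first real edge exists the
# placeholder must not double-count node 1's degree.
setdiff_first_placeholder <- function(endpoints) endpoints[-1]

#' @describeIn generators Watts–Strogatz: ring lattice where every node is
#'   joined to its `k/2` nearest neighbors on each side, then each edge is
#'   rewired independently with probability `p_r` (avoiding self-loops and
#'   duplicate edges).
#' @param k even ring degree, `k < n`.
#' @param p_r rewiring probability.
#' @export
gen_watts_strogatz <- function(n, k, p_r, seed, name = "ws") {
  n <- as.integer(n); k <- as.integer(k)
  if (k %% 2 != 0) stop("`k` must be even", call. = FALSE)
  if (k >= n) stop("`k` must be smaller than `n`", call. = FALSE)
  check_prob(p_r, "p_r")
  labels <- node_labels(n)
  from <- rep(seq_len(n), k / 2)
  to <- as.integer((rep(seq_len(n), k / 2) + rep(seq_len(k / 2), each = n) - 1) %% n + 1)
  has_edge <- new.env(hash = TRUE, size = length(from) * 2)
  ekey <- function(a, b) paste0(min(a, b), ".", max(a, b))
  for (e in seq_along(from)) assign(ekey(from[e], to[e]), TRUE, envir = has_edge)
  withr::with_seed(seed, {
    for (e in seq_along(from)) {
      if (stats::runif(1) < p_r) {
        u <- from[e]
        # degree cap: if u is adjacent to all others no rewiring is possible
        attempts <- 0L
        repeat {
          w <- sample.int(n, 1)
          attempts <- attempts + 1L
          if (w != u && !isTRUE(get0(ekey(u, w), envir = has_edge))) break
          if (attempts > 100L * n) { w <- NA_integer_; break }
        }
        if (!is.na(w)) {
          rm(list = ekey(from[e], to[e]), envir = has_edge)
          to[e] <- w
          assign(ekey(u, w), TRUE, envir = has_edge)
        }
      }
    }
  })
  netgraph(tibble::tibble(from = labels[from], to = labels[to]),
           directed = FALSE, name = name, nodes = labels)
}

#' @describeIn generators Random bipartite graph: `n1` nodes on side 0
#'   (labels `a...`) and `n2` on side 1 (labels `b...`); every cross-pair is
#'   an edge independently with probability `p`. [check_bipartite()] is true
#'   for every output.
#' @param n1,n2 side sizes.
#' @export
gen_bipartite <- function(n1, n2, p, seed, name = "bipartite") {
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (n1 < 1 || n2 < 1) stop("`n1` and `n2` must be positive", call. = FALSE)
  check_prob(p)
  a <- node_labels(n1, "a")
  b <- node_labels(n2, "b")
  npairs <- n1 * n2
  withr::with_seed(seed, {
    m <- stats::rbinom(1, npairs, p)
    picks <- if (m > 0) sort(sample.int(npairs, m)) else integer()
  })
  i <- ((picks - 1) %/% n2) + 1L
  j <- ((picks - 1) %% n2) + 1L
  g <- netgraph(tibble::tibble(from = a[i], to = b[j]),
                directed = FALSE, name = name, nodes = c(a, b),
                max_edges = max(npairs, 50000))
  # remember the construction sides: a BFS coloring cannot recover the side
  # of an isolated node, the stored 2-coloring can
  g$bipartite_sides <- stats::setNames(rep(c(0L, 1L), c(n1, n2)), c(a, b))
  g
}
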