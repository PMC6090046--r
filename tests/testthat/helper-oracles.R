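# Independent brute-force oracles used to validate the graph and counting
# code. These deliberately avoid igraph and the package's own routines.

# decode a Pruefer sequence (length n-2, labels 1..n) into a tree edge list
prufer_decode <- function(seq, n) {
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, nrow = n - 1L, ncol = 2L)
  k <- 1L
  for (s in seq) {
    leaf <- min(which(degree == 1L))
    edges[k, ] <- c(leaf, s)
    k <- k + 1L
    degree[leaf] <- degree[leaf] - 1L
    degree[s] <- degree[s] - 1L
  }
  last <- which(degree == 1L)
  edges[k, ] <- last
  edges
}

# exhaustive minimum spanning tree weight of a complete graph with weight
# matrix W, by enumerating all n^(n-2) labelled trees
mst_weight_brute <- function(W) {
  n <- nrow(W)
  stopifnot(n >= 3, n <= 7)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    ed <- prufer_decode(seqs[r, ], n)
    w <- sum(W[ed])
    if (w < best) best <- w
  }
  best
}

# betweenness centrality on a tree by enumerating the unique path of every
# pair (breadth-first parent tracing), normalized by (n-1)(n-2)/2
bc_brute <- function(edges, n) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  path_between <- function(s, t) {
    parent <- rep(NA_integer_, n)
    seen <- rep(FALSE, n)
    queue <- s; seen[s] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (!seen[w]) { seen[w] <- TRUE; parent[w] <- v; queue <- c(queue, w) }
      }
    }
    path <- t
    while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
    path
  }
  counts <- rep(0, n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      p <- path_between(s, t)
      interior <- setdiff(p, c(s, t))
      counts[interior] <- counts[interior] + 1
    }
  }
  counts / ((n - 1) * (n - 2) / 2)
}

# hypergeometric P(at least one of m marked among n draws from N) by
# exhaustive enumeration of all C(N, n) draws
chance_brute <- function(N, m, n) {
  marked <- seq_len(m)
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) any(d %in% marked)))
}

# random labelled tree via a random Pruefer sequence
random_tree <- function(n) {
  prufer_decode(sample.int(n, n - 2L, replace = TRUE), n)
}

# small helper: metric-table array with attached masks/outcomes, for tests
# that exercise the statistics layer on hand-made values
make_metric_table <- function(values, masks, outcomes = NULL) {
  structure(values,
            masks = masks,
            outcomes = outcomes,
            class = c("metric_table", "array"))
}
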