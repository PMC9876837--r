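# Independent brute-force oracles used to validate the package's
# statistical primitives on small instances.

# Step-up BH adjustment computed literally from the definition:
# adj(i) = min_{j >= rank(i)} p(j) * n / j, capped at 1.
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  sorted <- p[o]
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- min(1, min(sorted[i:n] * n / (i:n)))
  }
  adj <- numeric(n)
  adj[o] <- out
  adj
}

# Hypergeometric upper tail by direct enumeration of the probability mass.
hyperOracle <- function(k, n, K, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Unnormalized betweenness by exhaustive enumeration of all simple paths:
# for every ordered source-target pair, find all shortest paths and add
# each interior vertex's share. Undirected graphs given as a 2-column edge
# matrix of vertex indices; feasible for <= 8 vertices.
betweennessOracle <- function(edges, n_vertices) {
  adj <- vector("list", n_vertices)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  allPaths <- function(from, to) {
    paths <- list()
    walk <- function(v, seen) {
      if (v == to) {
        paths[[length(paths) + 1L]] <<- seen
        return(invisible())
      }
      for (w in adj[[v]]) {
        if (!(w %in% seen)) walk(w, c(seen, w))
      }
    }
    walk(from, from)
    paths
  }
  bc <- numeric(n_vertices)
  for (s in seq_len(n_vertices - 1L)) {
    for (t in seq(s + 1L, n_vertices)) {
      paths <- allPaths(s, t)
      if (length(paths) == 0L) next
      lens <- lengths(paths)
      shortest <- paths[lens == min(lens)]
      for (p in shortest) {
        interior <- setdiff(p, c(s, t))
        # each pair counted once for undirected betweenness
        bc[interior] <- bc[interior] + 1 / length(shortest)
      }
    }
  }
  bc
}
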