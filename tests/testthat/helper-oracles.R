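# Brute-force graph oracles working directly on adjacency matrices,
# independent of the package's (igraph-backed) implementation.

bf_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A > 0] <- 1
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

# Number of shortest paths between every pair: walks of minimal length
# are simple, so sigma(s,t) = (A^d(s,t))[s,t].
bf_shortest_path_counts <- function(A, D) {
  n <- nrow(A)
  pows <- vector("list", max(2, n))
  pows[[1]] <- A
  for (k in 2:max(2, n)) pows[[k]] <- pows[[k - 1]] %*% A
  S <- matrix(0, n, n)
  for (d in seq_len(n)) {
    hit <- which(D == d)
    if (length(hit)) S[hit] <- pows[[d]][hit]
  }
  diag(S) <- 1
  S
}

bf_betweenness <- function(A) {
  n <- nrow(A)
  D <- bf_distances(A)
  S <- bf_shortest_path_counts(A, D)
  vapply(seq_len(n), function(v) {
    on_path <- is.finite(D) & (outer(D[, v], D[v, ], "+") == D)
    contrib <- outer(S[, v], S[v, ]) / ifelse(S > 0, S, 1)
    contrib[!on_path] <- 0
    contrib[v, ] <- 0
    contrib[, v] <- 0
    diag(contrib) <- 0
    sum(contrib[upper.tri(contrib)])
  }, numeric(1))
}

bf_closeness <- function(A) {
  D <- bf_distances(A)
  vapply(seq_len(nrow(A)), function(v) {
    d <- D[v, -v]
    d <- d[is.finite(d)]
    if (length(d) == 0) NA_real_ else 1 / sum(d)
  }, numeric(1))
}

bf_kcore <- function(A) {
  n <- nrow(A)
  alive <- rep(TRUE, n)
  core <- integer(n)
  k <- 0L
  while (any(alive)) {
    repeat {
      deg <- rowSums(A[, alive, drop = FALSE])[alive]
      drop <- which(alive)[deg < k]
      if (length(drop) == 0) break
      core[drop] <- k - 1L
      alive[drop] <- FALSE
    }
    k <- k + 1L
  }
  core
}

# Burt's constraint by direct evaluation of the formula, triple loop.
bf_constraint <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  p <- function(i, j) if (deg[i] > 0) A[i, j] / deg[i] else 0
  vapply(seq_len(n), function(i) {
    if (deg[i] == 0) return(NA_real_)
    nb <- which(A[i, ] > 0)
    total <- 0
    for (j in nb) {
      indirect <- 0
      for (q in setdiff(seq_len(n), c(i, j))) {
        indirect <- indirect + p(i, q) * p(q, j)
      }
      total <- total + (p(i, j) + indirect)^2
    }
    total
  }, numeric(1))
}

random_adjacency <- function(n, p_edge) {
  A <- matrix(0, n, n)
  if (n >= 2) {
    pairs <- t(utils::combn(n, 2))
    bits <- stats::rbinom(nrow(pairs), 1, p_edge)
    A[pairs] <- bits
    A <- A + t(A)
  }
  A
}

graph_from_adj <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::set_vertex_attr(g, "name", value = paste0("v", seq_len(nrow(A))))
}
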