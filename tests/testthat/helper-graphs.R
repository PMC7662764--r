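# Shared fixtures: small graphs, random graph generator, and independent
# oracles used across the test files.

path_graph <- function(n) {
  nodes <- paste0("n", seq_len(n))
  if (n == 1L) return(skeleton_graph(nodes, matrix(integer(), 0L, 2L)))
  skeleton_graph(nodes, cbind(seq_len(n - 1L), 2:n))
}

# random connected-ish undirected graph on n nodes (every node gets at
# least the chance of isolation; self-links keep degrees positive)
random_graph <- function(n, p = 0.4) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (stats::runif(1) < p) A[i, j] <- A[j, i] <- 1L
  edges <- which(upper.tri(A) & A == 1L, arr.ind = TRUE)
  skeleton_graph(paste0("n", seq_len(n)),
                 if (nrow(edges)) edges else matrix(integer(), 0L, 2L))
}

# Brute-force graph convolution: explicit per-node sum over the D = 1
# neighbor set (self included) with weights A_norm[i, j] * W, independent
# of the matrix-product implementation.
brute_graph_conv <- function(features, graph, W) {
  V <- length(graph$nodes)
  out <- matrix(0, V, ncol(W))
  for (i in seq_len(V)) {
    nb <- which(graph$A[i, ] > 0 | seq_len(V) == i)
    for (j in nb)
      out[i, ] <- out[i, ] + graph$A_norm[i, j] * (features[j, ] %*% W)
  }
  out
}

# BFS distances oracle (independent of neighbor_set's implementation)
bfs_distances <- function(graph, start) {
  V <- length(graph$nodes)
  dist <- rep(Inf, V)
  dist[start] <- 0
  queue <- start
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    for (u in which(graph$A[v, ] > 0)) if (is.infinite(dist[u])) {
      dist[u] <- dist[v] + 1
      queue <- c(queue, u)
    }
  }
  dist
}

# quick small dataset for model tests
tiny_dataset <- function(n_per_class = 10, noise_sd = 0, seed = 99,
                         subject_sd = 0, pool = 4) {
  generate_dataset(generator_config(
    n_forehand = n_per_class, n_backhand = n_per_class, n_noshot = n_per_class,
    noise_sd = noise_sd, outlier_rate = 0, subject_sd = subject_sd,
    pool_per_phase = pool, seed = seed))
}
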