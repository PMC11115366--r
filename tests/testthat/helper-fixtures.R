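# Fixtures built in code.

# Similarity matrix from a named pair list over n cells, e.g.
# sim_from_pairs(3, list(c(1, 2, 0.9), c(1, 3, 0.7), c(2, 3, 0.4))).
sim_from_pairs <- function(n, pairs, method = "correlation") {
  v <- matrix(0, n, n)
  for (p in pairs) v[p[1], p[2]] <- v[p[2], p[1]] <- p[3]
  diag(v) <- 1
  similarity_matrix(v, method, sprintf("c%d", seq_len(n)))
}

# Random symmetric similarity matrix with distinct off-diagonal values.
random_similarity <- function(n, seed, method = "correlation") {
  set.seed(seed)
  v <- matrix(0, n, n)
  v[upper.tri(v)] <- stats::runif(n * (n - 1) / 2)
  v <- v + t(v)
  diag(v) <- 1
  similarity_matrix(v, method, sprintf("c%02d", seq_len(n)))
}

# Functional network from an adjacency matrix.
net_from_adj <- function(adj, coords = NULL) {
  n <- nrow(adj)
  ids <- sprintf("c%02d", seq_len(n))
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  functional_network(ids,
                     data.frame(cell_i = ids[idx[, 1]],
                                cell_j = ids[idx[, 2]]),
                     coords)
}

adj_from_net <- function(net) {
  n <- length(net$cell_ids)
  adj <- matrix(0L, n, n)
  i <- match(net$edges$cell_i, net$cell_ids)
  j <- match(net$edges$cell_j, net$cell_ids)
  adj[cbind(i, j)] <- 1L
  adj[cbind(j, i)] <- 1L
  adj
}

# Small, quick synthetic islet for tests that only need plumbing.
quick_islet <- function(seed = 1, ...) {
  args <- list(n_cells = 40, disc_radius_um = 80, duration_s = 300,
               seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  generate_islet(do.call(islet_sim_config, args))
}

edge_key_set <- function(net)
  sort(paste(net$edges$cell_i, net$edges$cell_j, sep = "|"))
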