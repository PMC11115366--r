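# Independent brute-force oracles, kept free of the implementation paths
# they check.

# Shannon entropy of a binary vector by direct summation over states.
oracle_entropy <- function(x) {
  h <- 0
  for (s in c(0, 1)) {
    p <- sum(x == s) / length(x)
    if (p > 0) h <- h - p * log2(p)
  }
  h
}

# Mutual information by direct summation over the four joint states.
oracle_mi <- function(x, y) {
  n <- length(x)
  mi <- 0
  for (sx in c(0, 1)) for (sy in c(0, 1)) {
    pxy <- sum(x == sx & y == sy) / n
    px <- sum(x == sx) / n
    py <- sum(y == sy) / n
    if (pxy > 0) mi <- mi + pxy * log2(pxy / (px * py))
  }
  mi
}

# All-pairs shortest paths by Floyd-Warshall on an adjacency matrix.
oracle_shortest_paths <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n))
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  d
}

# Global efficiency and largest-component mean path length from an
# adjacency matrix, via the Floyd-Warshall oracle.
oracle_eff_lavg <- function(adj) {
  d <- oracle_shortest_paths(adj)
  off <- d[row(d) != col(d)]
  eff <- mean(ifelse(is.finite(off), 1 / off, 0))
  # components from reachability
  comp_id <- integer(nrow(adj))
  cid <- 0L
  for (v in seq_len(nrow(adj))) {
    if (comp_id[v] == 0L) {
      cid <- cid + 1L
      comp_id[is.finite(d[v, ])] <- cid
    }
  }
  big <- which(comp_id == which.max(tabulate(comp_id)))
  lavg <- if (length(big) > 1) {
    dl <- d[big, big]
    mean(dl[row(dl) != col(dl)])
  } else NA_real_
  list(E = eff, L_avg = lavg, S_max = max(tabulate(comp_id)) / nrow(adj))
}

# Newman-Girvan modularity of a partition, from first principles.
oracle_modularity <- function(adj, membership) {
  m <- sum(adj) / 2
  if (m == 0) return(NA_real_)
  q <- 0
  deg <- rowSums(adj)
  for (cm in unique(membership)) {
    idx <- which(membership == cm)
    e_c <- sum(adj[idx, idx]) / 2
    d_c <- sum(deg[idx])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}
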