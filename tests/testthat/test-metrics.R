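test_that("metrics match closed forms on canonical graphs", {
  # complete graph K5
  k5 <- net_from_adj(matrix(1, 5, 5) - diag(5))
  m <- compute_metrics(k5, sw_randomizations = 0)
  expect_equal(m$k_avg, 4)
  expect_equal(m$C_avg, 1)
  expect_equal(m$E, 1)
  expect_equal(m$S_max, 1)
  expect_equal(m$L_avg, 1)
  # two disjoint triangles
  adj <- matrix(0, 6, 6)
  adj[1:3, 1:3] <- 1
  adj[4:6, 4:6] <- 1
  diag(adj) <- 0
  m2 <- compute_metrics(net_from_adj(adj), sw_randomizations = 0)
  expect_equal(m2$S_max, 0.5)
  expect_equal(m2$Q, 0.5)  # Newman-Girvan value for the two-triangle split
  # path on 3 nodes: pair distances 1, 1, 2
  p3 <- net_from_adj(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  m3 <- compute_metrics(p3, sw_randomizations = 0)
  expect_equal(m3$C_avg, 0)
  expect_equal(m3$E, 5 / 6)
  expect_equal(m3$L_avg, 4 / 3)
})

test_that("degree sum equals twice the edge count and k_avg follows", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(5:30, 1)
    adj <- matrix(rbinom(n * n, 1, 0.3), n, n)
    adj <- (adj + t(adj)) > 0
    diag(adj) <- FALSE
    net <- net_from_adj(adj)
    m <- compute_metrics(net, sw_randomizations = 0)
    expect_equal(sum(m$degree_list), 2 * nrow(net$edges))
    expect_equal(m$k_avg, 2 * nrow(net$edges) / n)
  }
})

test_that("efficiency and path lengths match a brute-force oracle on random graphs", {
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    adj <- matrix(rbinom(n * n, 1, runif(1, 0.15, 0.6)), n, n)
    adj <- 1 * ((adj + t(adj)) > 0)
    diag(adj) <- 0
    m <- compute_metrics(net_from_adj(adj), sw_randomizations = 0)
    o <- oracle_eff_lavg(adj)
    expect_equal(m$E, o$E, tolerance = 1e-12)
    expect_equal(m$L_avg, o$L_avg, tolerance = 1e-12)
    expect_equal(m$S_max, o$S_max, tolerance = 1e-12)
  }
})

test_that("reported Q is exactly the modularity of the returned partition", {
  for (seed in 1:5) {
    set.seed(seed)
    adj <- matrix(rbinom(400, 1, 0.2), 20, 20)
    adj <- 1 * ((adj + t(adj)) > 0)
    diag(adj) <- 0
    if (sum(adj) == 0) next
    net <- net_from_adj(adj)
    m <- compute_metrics(net, sw_randomizations = 0)
    expect_equal(m$Q, oracle_modularity(adj, m$membership),
                 tolerance = 1e-12)
  }
})

test_that("small-world coefficient is ~1 for random graphs and > 1 for clustered ones", {
  # Erdos-Renyi-like graphs score about 1 against their own null model
  sws <- vapply(1:20, function(seed) {
    set.seed(seed)
    adj <- matrix(0, 60, 60)
    idx <- which(upper.tri(adj))
    on <- sample(idx, 240)
    adj[on] <- 1
    adj <- adj + t(adj)
    compute_metrics(net_from_adj(adj), sw_randomizations = 10,
                    seed = seed)$SW
  }, 0)
  expect_lt(abs(mean(sws) - 1), 0.2)
  # ring lattice with a few shortcuts is small-world: SW > 1
  n <- 60
  adj <- matrix(0, n, n)
  for (v in 1:n) for (s in 1:2) {
    w <- ((v + s - 1) %% n) + 1
    adj[v, w] <- adj[w, v] <- 1
  }
  set.seed(1)
  for (r in 1:6) {
    pair <- sample(n, 2)
    adj[pair[1], pair[2]] <- adj[pair[2], pair[1]] <- 1
  }
  expect_gt(compute_metrics(net_from_adj(adj), sw_randomizations = 20,
                            seed = 3)$SW, 1)
})

test_that("SW is reproducible for a fixed seed and has a degree-preserving variant", {
  islet <- quick_islet(seed = 5)
  S <- pearson_matrix(bandpass_filter(islet$recording, filter_spec("fast")))
  net <- fixed_kavg_network(S, 6, coords = islet$recording$coords)
  a <- compute_metrics(net, sw_randomizations = 10, seed = 11)$SW
  b <- compute_metrics(net, sw_randomizations = 10, seed = 11)$SW
  expect_identical(a, b)
  dp <- compute_metrics(net, sw_randomizations = 10, seed = 11,
                        random_ref = "degree")$SW
  expect_true(is.finite(dp))
})

test_that("empty networks get defined degenerate metrics", {
  net <- functional_network(sprintf("c%d", 1:5), NULL)
  m <- compute_metrics(net, sw_randomizations = 5)
  expect_equal(m$C_avg, 0)
  expect_equal(m$E, 0)
  expect_true(is.na(m$SW))
  expect_true(is.na(m$Q))
})

test_that("edge lengths are Euclidean and normalization uses the 8-neighbor scale", {
  two <- functional_network(c("a", "b"),
                            data.frame(cell_i = "a", cell_j = "b"),
                            coords = data.frame(x_um = c(0, 10),
                                                y_um = c(0, 0)))
  expect_equal(edge_length_distribution(two), 10)
  expect_warning(rel2 <- edge_length_distribution(two, normalize = TRUE),
                 "nearest neighbors")
  expect_equal(rel2, 1)  # with one neighbor the scale is the edge itself
  # regular unit grid: the 8-neighbor mean includes diagonals sqrt(2), so a
  # nearest-neighbor edge has relative length < 1
  g <- expand.grid(x_um = 0:4, y_um = 0:4)
  ids <- sprintf("g%02d", 1:25)
  net <- functional_network(ids, data.frame(cell_i = "g01", cell_j = "g02"),
                            coords = g)
  expect_lt(edge_length_distribution(net, normalize = TRUE), 1)
  # geometric network edges never exceed the distance threshold
  islet <- quick_islet(seed = 6)
  geo <- geometric_network(islet$recording$coords, "distance", 30,
                           islet$recording$cell_ids)
  if (nrow(geo$edges) > 0)
    expect_lte(max(edge_length_distribution(geo)), 30)
})

test_that("hub identification takes the top sixth with a deterministic tie rule", {
  set.seed(12)
  adj <- matrix(rbinom(3600, 1, 0.15), 60, 60)
  adj <- 1 * ((adj + t(adj)) > 0)
  diag(adj) <- 0
  net <- net_from_adj(adj)
  hubs <- identify_hubs(net)
  expect_length(hubs, 10)  # ceil(60/6)
  deg <- igraph::degree(as_igraph(net))
  expect_gte(min(deg[hubs]), max(deg[setdiff(net$cell_ids, hubs)]))
  # star graph: the center is a hub
  star <- net_from_adj(rbind(c(0, 1, 1, 1, 1), cbind(1, matrix(0, 4, 4))))
  expect_true("c01" %in% identify_hubs(star, 1 / 5))
  # regular graph: ties broken by cell id order
  ring <- matrix(0, 6, 6)
  for (v in 1:6) ring[v, (v %% 6) + 1] <- ring[(v %% 6) + 1, v] <- 1
  expect_identical(identify_hubs(net_from_adj(ring), 1 / 3),
                   c("c01", "c02"))
})

test_that("degree-activity relation recovers designed relations", {
  set.seed(4)
  adj <- matrix(rbinom(900, 1, 0.25), 30, 30)
  adj <- 1 * ((adj + t(adj)) > 0)
  diag(adj) <- 0
  net <- net_from_adj(adj)
  deg <- igraph::degree(as_igraph(net))[net$cell_ids]
  # identical activity: flat bins, r = 0
  flat <- degree_activity_relation(net, rep(0.4, 30))
  expect_equal(flat$r, 0)
  expect_true(all(abs(flat$table$mean_activity - 0.4) < 1e-12))
  # activity equal to degree: r = 1
  prop <- degree_activity_relation(net, as.numeric(deg))
  expect_equal(prop$r, 1)
  # constant degrees: undefined sentinel
  ring <- matrix(0, 6, 6)
  for (v in 1:6) ring[v, (v %% 6) + 1] <- ring[(v %% 6) + 1, v] <- 1
  expect_true(is.na(degree_activity_relation(net_from_adj(ring),
                                             runif(6))$r))
})

test_that("duty-cycle heterogeneity induces a positive degree-activity relation", {
  islet <- generate_islet(islet_sim_config(seed = 4))
  fast <- bandpass_filter(islet$recording, filter_spec("fast"))
  bin <- binarize(fast)
  S <- coactivity_matrix(bin)
  net <- fixed_kavg_network(S, 8, coords = islet$recording$coords)
  da <- degree_activity_relation(net, relative_active_time(bin))
  expect_gt(da$r, 0)
})

test_that("pooling across islets normalizes degree and activity per islet", {
  nets <- list()
  rats <- list()
  for (s in 1:2) {
    islet <- quick_islet(seed = s)
    fast <- bandpass_filter(islet$recording, filter_spec("fast"))
    bin <- binarize(fast)
    nets[[s]] <- fixed_kavg_network(coactivity_matrix(bin), 6,
                                    coords = islet$recording$coords)
    rats[[s]] <- relative_active_time(bin)
  }
  pooled <- degree_activity_relation(nets, rats, n_bins = 8)
  expect_true(all(pooled$table$bin_center >= 0 & pooled$table$bin_center <= 1))
  expect_identical(sum(pooled$table$n), 80L)
  expect_true(is.finite(pooled$r))
})
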