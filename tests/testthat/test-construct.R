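test_that("fixed-threshold construction keeps exactly the supra-threshold pairs", {
  S <- sim_from_pairs(3, list(c(1, 2, 0.9), c(1, 3, 0.7), c(2, 3, 0.4)))
  net <- fixed_threshold_network(S, 0.75)
  expect_identical(edge_key_set(net), "c1|c2")
  # all below threshold: empty edge set
  expect_identical(nrow(fixed_threshold_network(S, 0.95)$edges), 0L)
  # threshold below every correlation: complete graph
  Sc <- random_similarity(20, seed = 8)
  full <- fixed_threshold_network(Sc, -2)
  expect_identical(nrow(full$edges), 190L)
  expect_equal(mean(igraph::degree(as_igraph(full))), 19)
})

test_that("the edge condition is strict: ties at the threshold are excluded", {
  S <- sim_from_pairs(3, list(c(1, 2, 0.8), c(1, 3, 0.5), c(2, 3, 0.2)))
  net <- fixed_threshold_network(S, 0.5)
  expect_identical(edge_key_set(net), "c1|c2")
})

test_that("threshold monotonicity gives exact edge-set containment", {
  S <- random_similarity(30, seed = 5)
  ths <- sort(runif(6, -0.5, 1))
  nets <- lapply(ths, function(th) edge_key_set(fixed_threshold_network(S, th)))
  for (k in seq_len(length(ths) - 1))
    expect_true(all(nets[[k + 1]] %in% nets[[k]]))
})

test_that("variable-threshold construction reaches the target average degree", {
  islet <- generate_islet(islet_sim_config(seed = 12))
  S <- pearson_matrix(bandpass_filter(islet$recording, filter_spec("fast")))
  net <- fixed_kavg_network(S, 8, tol = 0.2)
  k <- mean(igraph::degree(as_igraph(net)))
  expect_lte(abs(k - 8), 0.2)
  expect_equal(net$construction$achieved_kavg, k)
  # target N-1 on a sentinel-free matrix yields the complete graph
  Sc <- random_similarity(15, seed = 2)
  expect_identical(nrow(fixed_kavg_network(Sc, 14, tol = 0.1)$edges), 105L)
  # lower target -> higher (or equal) threshold
  th_lo <- fixed_kavg_network(S, 4)$construction$threshold_used
  th_hi <- fixed_kavg_network(S, 12)$construction$threshold_used
  expect_gte(th_lo, th_hi)
  # unreachable target errors and names the maximum
  expect_error(fixed_kavg_network(Sc, 30), "unreachable")
})

test_that("similarity-to-distance conversion is D = 2(1 - SC)", {
  S <- sim_from_pairs(3, list(c(1, 2, 1), c(1, 3, 0), c(2, 3, -1)))
  D <- to_distance(S)
  expect_equal(D["c1", "c2"], 0)
  expect_equal(D["c1", "c3"], 2)
  expect_equal(D["c2", "c3"], 4)
  expect_true(all(is.infinite(diag(D))))
  # sentinels map to infinite distance
  v <- matrix(c(1, 0.5, NA, 0.5, 1, 0.2, NA, 0.2, 1), 3, 3)
  Ds <- to_distance(similarity_matrix(v, "correlation"))
  expect_true(is.infinite(Ds[1, 3]))
})

test_that("a single MST has N-1 edges and four layers have 4(N-1)", {
  S50 <- random_similarity(50, seed = 21)
  expect_identical(nrow(multilayer_mst_network(S50, 1)$edges), 49L)
  S200 <- random_similarity(200, seed = 22)
  net <- multilayer_mst_network(S200, 4)
  expect_identical(nrow(net$edges), 796L)
  k <- mean(igraph::degree(as_igraph(net)))
  expect_equal(k, 7.96)
  expect_identical(round(k), 8)
})

test_that("multilayer MST layers are edge-disjoint spanning trees", {
  S <- random_similarity(40, seed = 23)
  net <- multilayer_mst_network(S, 4)
  expect_identical(anyDuplicated(edge_key_set(net)), 0L)
  for (l in 1:4) {
    sub <- net$edges[net$edges$layer == l, ]
    g <- igraph::graph_from_data_frame(sub[, c("cell_i", "cell_j")],
                                       directed = FALSE,
                                       vertices = net$cell_ids)
    expect_identical(nrow(sub), 39L)                  # N-1 edges
    expect_true(igraph::is_connected(g))              # spanning
    expect_equal(igraph::count_components(g), 1)      # hence acyclic at N-1
  }
  # every node touched by every layer: min degree >= n_layers
  expect_gte(min(igraph::degree(as_igraph(net))), 4)
  expect_true(igraph::is_connected(as_igraph(net)))
})

test_that("layer 1 matches an independent MST implementation in total weight", {
  S <- random_similarity(60, seed = 24)
  D <- to_distance(S)
  net <- multilayer_mst_network(S, 1)
  i <- match(net$edges$cell_i, S$cell_ids)
  j <- match(net$edges$cell_j, S$cell_ids)
  w_mine <- sum(D[cbind(i, j)])
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  w_ref <- sum(igraph::E(igraph::mst(g))$weight)
  expect_equal(w_mine, w_ref, tolerance = 1e-10)
})

test_that("MST edge sets are invariant under monotone transforms of the distance", {
  for (seed in 1:50) {
    S <- random_similarity(15, seed = 100 + seed)
    a <- multilayer_mst_network(S, 2)
    # sqrt is strictly increasing on non-negative distances, so Kruskal
    # order and hence the chosen edges are unchanged
    S2 <- S
    S2$values <- 1 - sqrt(2 * (1 - S$values)) / 2  # D' = sqrt(2(1-SC))
    b <- multilayer_mst_network(S2, 2)
    expect_identical(edge_key_set(a), edge_key_set(b))
  }
})

test_that("residual-graph disconnection is reported with the completed layer count", {
  # N = 4 supports at most 2 edge-disjoint spanning trees (6 edges total)
  S <- random_similarity(4, seed = 3)
  expect_error(multilayer_mst_network(S, 3), "completed 2 full layer")
})

test_that("geometric networks follow plain geometry", {
  sq <- data.frame(x_um = c(0, 1, 1, 0), y_um = c(0, 0, 1, 1))
  net <- geometric_network(sq, mode = "distance", value = 1.0)
  expect_identical(nrow(net$edges), 4L)   # sides only, no diagonals
  lens <- edge_length_distribution(net)
  expect_true(all(abs(lens - 1) < 1e-12))
  # threshold at the max pairwise distance: complete graph
  full <- geometric_network(sq, mode = "distance", value = sqrt(2))
  expect_identical(nrow(full$edges), 6L)
  # target average degree on a simulated layout
  islet <- generate_islet(islet_sim_config(seed = 13))
  geo <- geometric_network(islet$recording$coords, mode = "target_kavg",
                           value = 8, cell_ids = islet$recording$cell_ids)
  expect_lte(abs(mean(igraph::degree(as_igraph(geo))) - 8), 0.2)
  expect_error(geometric_network(sq, mode = "target_kavg", value = 10),
               "unreachable")
})

test_that("interval carry-over fixes the threshold on the first interval", {
  S <- random_similarity(50, seed = 41)
  same <- interval_carryover_networks(S, S, 8)
  expect_equal(nsi(same$interval1, same$interval2), 1)
  # stronger coupling in interval 2 raises similarities -> denser network
  i1 <- generate_islet(islet_sim_config(seed = 6, wave_speed_um_per_s = 30))
  i2 <- generate_islet(islet_sim_config(seed = 6, wave_speed_um_per_s = 100))
  S1 <- pearson_matrix(bandpass_filter(i1$recording, filter_spec("fast")))
  S2 <- pearson_matrix(bandpass_filter(i2$recording, filter_spec("fast")))
  up <- interval_carryover_networks(S1, S2, 8)
  expect_gt(nrow(up$interval2$edges), nrow(up$interval1$edges))
  # and weaker coupling lowers them
  down <- interval_carryover_networks(S2, S1, 8)
  expect_lt(nrow(down$interval2$edges), nrow(down$interval1$edges))
  # cell-set mismatch errors
  expect_error(interval_carryover_networks(S, S1, 8), "different cell sets|cover")
})

test_that("fixed-threshold density grows with coupling strength", {
  k <- vapply(c(20, 50, 120), function(ws) {
    isl <- generate_islet(islet_sim_config(seed = 6,
                                           wave_speed_um_per_s = ws))
    S <- pearson_matrix(bandpass_filter(isl$recording, filter_spec("fast")))
    mean(igraph::degree(as_igraph(fixed_threshold_network(S, 0.8))))
  }, 0)
  expect_true(all(diff(k) > 0))
})

test_that("asynchronous cells stay isolated under thresholding but not under MST", {
  islet <- generate_islet(islet_sim_config(seed = 3, n_async_cells = 5))
  S <- pearson_matrix(bandpass_filter(islet$recording, filter_spec("fast")))
  th <- fixed_threshold_network(S, 0.7)
  ml <- multilayer_mst_network(S, 4)
  deg_th <- igraph::degree(as_igraph(th))[islet$async_ids]
  deg_ml <- igraph::degree(as_igraph(ml))[islet$async_ids]
  expect_true(all(deg_th == 0))
  expect_true(all(deg_ml >= 4))
})

test_that("functional networks reject malformed edges", {
  expect_error(functional_network("a", data.frame(cell_i = "a", cell_j = "a")),
               "self-loops")
  expect_error(functional_network(c("a", "b"),
                                  data.frame(cell_i = c("a", "b"),
                                             cell_j = c("b", "a"))),
               "duplicate")
  expect_error(functional_network("a", data.frame(cell_i = "a", cell_j = "z")),
               "endpoint")
})

test_that("edge-list CSV round trip reconstructs an identical network", {
  islet <- quick_islet(seed = 9)
  S <- pearson_matrix(bandpass_filter(islet$recording, filter_spec("fast")))
  net <- fixed_kavg_network(S, 6, coords = islet$recording$coords)
  d <- withr::local_tempdir()
  p <- file.path(d, "edges.csv")
  write_edges_csv(net, p)
  back <- read_edges_csv(p)
  expect_identical(edge_key_set(back), edge_key_set(net))
  expect_identical(back$cell_ids, net$cell_ids)
  expect_equal(back$construction$threshold_used,
               net$construction$threshold_used)
  expect_equal(nsi(back, net), 1)
})
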