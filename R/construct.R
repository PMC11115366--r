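#' Functional network on imaged cells
#'
#' Simple undirected graph whose nodes are cells (at their physical
#' positions, when coordinates are known) and whose edges denote similarity
#' of their activity. Carries a construction record: method, the similarity
#' threshold actually used, target average degree and/or layer count.
#'
#' @param cell_ids character vector of node labels.
#' @param edges data frame with character columns `cell_i`, `cell_j` and an
#'   optional numeric `similarity`; self-loops and duplicate (unordered)
#'   edges are rejected.
#' @param coords optional data frame `x_um`, `y_um`, one row per cell.
#' @param construction list recording how the network was built.
#' @return An object of class `functional_network`.
#' @export
functional_network <- function(cell_ids, edges, coords = NULL,
                               construction = list(method = "manual")) {
  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids", call. = FALSE)
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0) {
    edges <- data.frame(cell_i = character(0), cell_j = character(0),
                        similarity = numeric(0))
  } else {
    edges <- as.data.frame(edges)
    if (!all(c("cell_i", "cell_j") %in% names(edges)))
      stop("edges need columns cell_i, cell_j", call. = FALSE)
    edges$cell_i <- as.character(edges$cell_i)
    edges$cell_j <- as.character(edges$cell_j)
    if (!all(c(edges$cell_i, edges$cell_j) %in% cell_ids))
      stop("edge endpoint not among cell_ids", call. = FALSE)
    if (any(edges$cell_i == edges$cell_j))
      stop("self-loops are not allowed", call. = FALSE)
    # canonical orientation, reject duplicates
    swap <- edges$cell_i > edges$cell_j
    tmp <- edges$cell_i[swap]
    edges$cell_i[swap] <- edges$cell_j[swap]
    edges$cell_j[swap] <- tmp
    if (anyDuplicated(paste(edges$cell_i, edges$cell_j, sep = "|")))
      stop("duplicate edges", call. = FALSE)
    if (is.null(edges$similarity)) edges$similarity <- NA_real_
    edges <- edges[order(edges$cell_i, edges$cell_j),
                   c("cell_i", "cell_j", "similarity")]
    rownames(edges) <- NULL
  }
  if (!is.null(coords)) {
    coords <- as.data.frame(coords)
    if (nrow(coords) != length(cell_ids))
      stop("coords must have one row per cell", call. = FALSE)
    rownames(coords) <- cell_ids
  }
  structure(list(cell_ids = cell_ids, edges = edges, coords = coords,
                 construction = construction),
            class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  n <- length(x$cell_ids)
  m <- nrow(x$edges)
  cat(sprintf("<functional_network> %d cells, %d edges (k_avg = %.2f), method: %s\n",
              n, m, kavg_of(m, n),
              x$construction$method %||% "manual"))
  if (!is.null(x$construction$threshold_used))
    cat(sprintf("  threshold_used = %.4f\n", x$construction$threshold_used))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.functional_network <- function(object, ...) {
  m <- compute_metrics(object, sw_randomizations = 0)
  print(object)
  cat(sprintf("  C_avg = %.3f, Q = %.3f, E = %.3f, S_max = %.3f, L_avg = %.2f\n",
              m$C_avg, m$Q, m$E, m$S_max, m$L_avg))
  invisible(m)
}

#' Convert a functional network to an igraph graph
#'
#' @param net a [functional_network()].
#' @return An undirected `igraph` graph with all cells as vertices.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  igraph::graph_from_data_frame(net$edges[, c("cell_i", "cell_j")],
                                directed = FALSE,
                                vertices = data.frame(name = net$cell_ids))
}

#' @export
plot.functional_network <- function(x, node_cex = 1, ...) {
  if (is.null(x$coords)) stop("no coordinates to plot", call. = FALSE)
  graphics::plot(x$coords$x_um, x$coords$y_um, asp = 1, pch = 16,
                 cex = node_cex, col = "grey30",
                 xlab = "x (µm)", ylab = "y (µm)", ...)
  if (nrow(x$edges) > 0) {
    i <- match(x$edges$cell_i, x$cell_ids)
    j <- match(x$edges$cell_j, x$cell_ids)
    graphics::segments(x$coords$x_um[i], x$coords$y_um[i],
                       x$coords$x_um[j], x$coords$y_um[j],
                       col = grDevices::adjustcolor("grey60", 0.7))
    graphics::points(x$coords$x_um, x$coords$y_um, pch = 16, cex = node_cex,
                     col = "grey30")
  }
  invisible(x)
}

# Finite off-diagonal upper-triangle entries as an edge candidate list.
offdiag_pairs <- function(S) {
  n <- S$n_cells
  ut <- which(upper.tri(S$values), arr.ind = TRUE)
  val <- S$values[ut]
  keep <- !is.na(val)
  list(i = ut[keep, 1], j = ut[keep, 2], val = val[keep], n = n)
}

#' Fixed-threshold network construction
#'
#' Connects cells i and j whenever their similarity strictly exceeds the
#' pre-set threshold. Undefined (`NA`) pairs are never connected, so a
#' negative threshold on a correlation matrix yields the complete graph over
#' well-defined cells only.
#'
#' @param S a [similarity_matrix()].
#' @param sc_th similarity threshold.
#' @param coords optional per-cell coordinates (`x_um`, `y_um`).
#' @return A [functional_network()] with `construction$method =
#'   "fixed_threshold"`.
#' @export
fixed_threshold_network <- function(S, sc_th, coords = NULL) {
  stopifnot(inherits(S, "similarity_matrix"))
  stop_if_not_scalar_number(sc_th, "sc_th")
  p <- offdiag_pairs(S)
  keep <- p$val > sc_th
  edges <- data.frame(cell_i = S$cell_ids[p$i[keep]],
                      cell_j = S$cell_ids[p$j[keep]],
                      similarity = p$val[keep])
  functional_network(S$cell_ids, edges, coords,
                     list(method = "fixed_threshold", threshold_used = sc_th))
}

#' Variable-threshold construction to a target average degree
#'
#' Bisects the similarity threshold until the network's average node degree
#' is within `tol` of the target (default 8, mimicking realistic beta cell
#' connectivity). When ties among similarity values make the tolerance
#' unreachable, the threshold whose average degree is nearest the target is
#' returned. The threshold actually used is recorded in the construction
#' record so it can be carried over to other intervals.
#'
#' @param S a [similarity_matrix()].
#' @param target_kavg target average node degree (defaults to 8).
#' @param tol tolerance on the achieved average degree.
#' @param max_iter bisection iteration cap.
#' @param coords optional coordinates.
#' @return A [functional_network()] with `construction$method = "fixed_kavg"`.
#' @export
fixed_kavg_network <- function(S, target_kavg = 8, tol = 0.1, max_iter = 60,
                               coords = NULL) {
  stopifnot(inherits(S, "similarity_matrix"))
  p <- offdiag_pairs(S)
  n <- p$n
  if (length(p$val) == 0)
    stop("no defined similarity values", call. = FALSE)
  max_kavg <- kavg_of(length(p$val), n)
  if (target_kavg > max_kavg + 1e-9)
    stop(sprintf("target k_avg %.2f unreachable; maximum achievable is %.2f",
                 target_kavg, max_kavg), call. = FALSE)
  kavg_at <- function(th) kavg_of(sum(p$val > th), n)
  lo <- min(p$val) - 1   # complete graph over defined pairs
  hi <- max(p$val)       # empty graph (strict threshold)
  best_th <- lo
  best_gap <- abs(kavg_at(lo) - target_kavg)
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    k <- kavg_at(mid)
    gap <- abs(k - target_kavg)
    if (gap < best_gap - 1e-12) {
      best_gap <- gap
      best_th <- mid
    }
    if (gap <= tol) { best_th <- mid; best_gap <- gap; break }
    if (k > target_kavg) lo <- mid else hi <- mid
  }
  net <- fixed_threshold_network(S, best_th, coords)
  net$construction <- list(method = "fixed_kavg", threshold_used = best_th,
                           target_kavg = target_kavg,
                           achieved_kavg = kavg_of(nrow(net$edges), n))
  net
}

#' Similarity-to-distance conversion
#'
#' Recomputes similarity coefficients into the abstract distance
#' `D = 2 (1 - SC)` used for minimum-spanning-tree construction; undefined
#' pairs map to `Inf`. Any strictly decreasing transform of similarity
#' yields the same spanning trees when weights are distinct.
#'
#' @param S a [similarity_matrix()].
#' @return A symmetric numeric matrix of distances with `Inf` on the
#'   diagonal and at undefined pairs.
#' @export
to_distance <- function(S) {
  stopifnot(inherits(S, "similarity_matrix"))
  D <- 2 * (1 - S$values)
  D[is.na(D)] <- Inf
  dimnames(D) <- dimnames(S$values)
  D
}

# Kruskal MST with union-find over a pre-sorted edge list; `excluded` is a
# logical mask over the candidate edges. Returns indices of chosen edges or
# signals how many layers completed.
kruskal_tree <- function(ord_i, ord_j, n, excluded) {
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  chosen <- integer(0)
  need <- n - 1L
  for (e in seq_along(ord_i)) {
    if (excluded[e]) next
    ra <- find(ord_i[e])
    rb <- find(ord_j[e])
    if (ra != rb) {
      parent[ra] <- rb
      chosen <- c(chosen, e)
      if (length(chosen) == need) break
    }
  }
  chosen
}

#' Multilayer minimum spanning tree construction
#'
#' Converts similarity to the abstract distance `D = 2 (1 - SC)` and builds
#' `n_layers` edge-disjoint minimum spanning trees sequentially: each layer
#' is a Kruskal MST over all cell pairs not used by previous layers. A
#' single MST has `N - 1` edges (average degree close to 2); every further
#' layer contributes another `N - 1`, so four layers yield an average degree
#' of about 8 without any explicit similarity threshold. Note the method
#' forces at least `n_layers` connections onto every cell, including cells
#' whose dynamics are unrelated to the rest of the population.
#'
#' Ties in distance are broken lexicographically on the (row, column) index
#' pair, making the result deterministic even with degenerate weights.
#'
#' @param S a [similarity_matrix()].
#' @param n_layers number of edge-disjoint MST layers (default 4).
#' @param coords optional coordinates.
#' @return A [functional_network()] with `construction$method =
#'   "multilayer_mst"` and per-edge `layer` column.
#' @export
multilayer_mst_network <- function(S, n_layers = 4, coords = NULL) {
  stopifnot(inherits(S, "similarity_matrix"))
  if (n_layers < 1) stop("n_layers must be >= 1", call. = FALSE)
  D <- to_distance(S)
  n <- S$n_cells
  ut <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[ut]
  fin <- is.finite(d)
  i <- ut[fin, 1]; j <- ut[fin, 2]; d <- d[fin]
  o <- order(d, i, j)            # deterministic Kruskal order
  i <- i[o]; j <- j[o]; d <- d[o]
  excluded <- logical(length(d))
  layer_of <- integer(0)
  chosen_all <- integer(0)
  for (layer in seq_len(n_layers)) {
    chosen <- kruskal_tree(i, j, n, excluded)
    if (length(chosen) < n - 1L)
      stop(sprintf(
        "residual graph disconnected: completed %d full layer(s) of %d",
        layer - 1L, n_layers), call. = FALSE)
    excluded[chosen] <- TRUE
    chosen_all <- c(chosen_all, chosen)
    layer_of <- c(layer_of, rep.int(layer, length(chosen)))
  }
  edges <- data.frame(cell_i = S$cell_ids[pmin(i[chosen_all], j[chosen_all])],
                      cell_j = S$cell_ids[pmax(i[chosen_all], j[chosen_all])],
                      similarity = 1 - d[chosen_all] / 2,
                      layer = layer_of)
  net <- functional_network(S$cell_ids, edges[, c("cell_i", "cell_j",
                                                 "similarity")],
                            coords,
                            list(method = "multilayer_mst",
                                 n_layers = n_layers))
  # re-attach layer labels in the canonical edge order
  key_new <- paste(net$edges$cell_i, net$edges$cell_j, sep = "|")
  key_old <- edge_keys(edges$cell_i, edges$cell_j)
  net$edges$layer <- edges$layer[match(key_new, key_old)]
  net
}

#' Geometric (structural) reference network
#'
#' Connects physically nearby cells, standing in for the structural
#' (gap-junctional) adjacency of the tissue. Either a plain Euclidean
#' distance threshold (`mode = "distance"`, edges for pairs at most `value`
#' micrometers apart) or a distance threshold bisected to reach a target
#' average degree (`mode = "target_kavg"`, default target 8 to match the
#' functional networks).
#'
#' @param coords data frame or matrix of per-cell positions (`x_um`,
#'   `y_um`).
#' @param mode `"distance"` or `"target_kavg"`.
#' @param value distance threshold in micrometers, or the target average
#'   degree.
#' @param cell_ids node labels (default `cell_1 ...`).
#' @param tol tolerance on the achieved average degree in `target_kavg`
#'   mode.
#' @return A [functional_network()] with `construction$method = "geometric"`.
#' @export
geometric_network <- function(coords, mode = c("target_kavg", "distance"),
                              value = 8, cell_ids = NULL, tol = 0.1) {
  mode <- match.arg(mode)
  coords <- as.data.frame(coords)
  if (!all(c("x_um", "y_um") %in% names(coords)))
    names(coords)[1:2] <- c("x_um", "y_um")
  n <- nrow(coords)
  if (n < 2) stop("need at least 2 cells", call. = FALSE)
  if (!all(is.finite(as.matrix(coords[, c("x_um", "y_um")]))))
    stop("coordinates must be finite", call. = FALSE)
  if (is.null(cell_ids)) cell_ids <- rownames(coords) %||% sprintf("cell_%d", 1:n)
  cell_ids <- as.character(cell_ids)
  dm <- as.matrix(stats::dist(coords[, c("x_um", "y_um")]))
  ut <- which(upper.tri(dm), arr.ind = TRUE)
  dv <- dm[ut]
  build <- function(th) {
    keep <- dv <= th
    data.frame(cell_i = cell_ids[ut[keep, 1]], cell_j = cell_ids[ut[keep, 2]],
               similarity = NA_real_)
  }
  if (mode == "distance") {
    th <- value
  } else {
    if (value > n - 1 + 1e-9)
      stop(sprintf("target k_avg %.2f unreachable with %d cells", value, n),
           call. = FALSE)
    kavg_at <- function(th) kavg_of(sum(dv <= th), n)
    lo <- 0
    hi <- max(dv)
    best_th <- hi; best_gap <- abs(kavg_at(hi) - value)
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      gap <- abs(kavg_at(mid) - value)
      if (gap < best_gap - 1e-12) { best_gap <- gap; best_th <- mid }
      if (gap <= tol) { best_th <- mid; best_gap <- gap; break }
      if (kavg_at(mid) > value) hi <- mid else lo <- mid
    }
    th <- best_th
  }
  net <- functional_network(cell_ids, build(th), coords,
                            list(method = "geometric", threshold_used = th,
                                 mode = mode,
                                 target_kavg = if (mode == "target_kavg")
                                   value else NULL))
  net
}

#' Threshold carry-over between protocol intervals
#'
#' For multi-phase experiments: fixes the variable threshold on the first
#' interval (target average degree, default 8) and applies that same
#' threshold to the second interval's similarity matrix, so changes in
#' network density between intervals reflect changes in synchronicity
#' rather than re-normalization.
#'
#' @param S1,S2 [similarity_matrix()] objects over the same cells.
#' @param target_kavg target average degree for the first interval.
#' @param coords optional coordinates.
#' @return List of two [functional_network()]s, `interval1` and `interval2`.
#' @export
interval_carryover_networks <- function(S1, S2, target_kavg = 8,
                                        coords = NULL) {
  stopifnot(inherits(S1, "similarity_matrix"),
            inherits(S2, "similarity_matrix"))
  if (!identical(S1$cell_ids, S2$cell_ids))
    stop("similarity matrices cover different cell sets", call. = FALSE)
  net1 <- fixed_kavg_network(S1, target_kavg, coords = coords)
  net2 <- fixed_threshold_network(S2, net1$construction$threshold_used,
                                  coords = coords)
  net2$construction$carryover_from <- "interval1"
  list(interval1 = net1, interval2 = net2)
}

#' Write / read a network edge list as CSV
#'
#' Columns `cell_i`, `cell_j`, `similarity`, `distance_um` (when coordinates
#' exist); the construction record and node set go to a JSON sidecar
#' `<path>.json` so the round trip reconstructs an identical network.
#'
#' @param net a [functional_network()].
#' @param path CSV path.
#' @return `path` (write) or a `functional_network` (read).
#' @export
write_edges_csv <- function(net, path) {
  stopifnot(inherits(net, "functional_network"))
  tab <- net$edges
  if (!is.null(net$coords) && nrow(tab) > 0) {
    i <- match(tab$cell_i, net$cell_ids)
    j <- match(tab$cell_j, net$cell_ids)
    tab$distance_um <- sqrt((net$coords$x_um[i] - net$coords$x_um[j])^2 +
                              (net$coords$y_um[i] - net$coords$y_um[j])^2)
  }
  utils::write.csv(tab, path, row.names = FALSE)
  side <- list(cell_ids = net$cell_ids, construction = net$construction)
  if (!is.null(net$coords))
    side$coords <- list(x_um = net$coords$x_um, y_um = net$coords$y_um)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_edges_csv
#' @export
read_edges_csv <- function(path) {
  tab <- utils::read.csv(path, colClasses = c(cell_i = "character",
                                              cell_j = "character"))
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  coords <- if (!is.null(side$coords))
    data.frame(x_um = side$coords$x_um, y_um = side$coords$y_um) else NULL
  functional_network(side$cell_ids,
                     tab[, intersect(c("cell_i", "cell_j", "similarity"),
                                     names(tab))],
                     coords, as.list(side$construction))
}
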