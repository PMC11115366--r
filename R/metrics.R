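#' Graph-theoretical metrics of a functional network
#'
#' Computes the standard metric set for cellular connectivity analyses:
#' average node degree `k_avg`, average clustering coefficient `C_avg`
#' (triangle-based, isolates and degree-1 nodes contribute 0), modularity
#' `Q` of a greedy modularity-maximization partition, global efficiency `E`
#' (mean over ordered pairs of inverse shortest-path length, disconnected
#' pairs contributing 0), relative largest component `S_max`, average
#' shortest path length `L_avg` on the largest component, and the
#' small-world coefficient `SW = (C_avg / C_rand) / (L_avg / L_rand)`
#' against an ensemble of random reference graphs with matched node and
#' edge counts.
#'
#' @param net a [functional_network()].
#' @param sw_randomizations number of random reference graphs for `SW`
#'   (default 20; 0 skips `SW`).
#' @param seed seed for the random reference ensemble.
#' @param random_ref `"density"` for Erdős–Rényi G(N, m) references
#'   (default) or `"degree"` for degree-sequence-preserving references.
#' @return An object of class `network_metrics`: list with scalars `k_avg`,
#'   `C_avg`, `Q`, `E`, `S_max`, `L_avg`, `SW` and vectors `degree_list`,
#'   `clustering_list`, plus `edge_lengths_um` and `edge_lengths_relative`
#'   when coordinates are available.
#' @examples
#' net <- functional_network(letters[1:5],
#'   data.frame(cell_i = c("a", "a", "b"), cell_j = c("b", "c", "c")))
#' compute_metrics(net, sw_randomizations = 0)
#' @export
compute_metrics <- function(net, sw_randomizations = 20, seed = 1,
                            random_ref = c("density", "degree")) {
  stopifnot(inherits(net, "functional_network"))
  random_ref <- match.arg(random_ref)
  n <- length(net$cell_ids)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  g <- as_igraph(net)
  m <- nrow(net$edges)
  deg <- igraph::degree(g)
  clus <- igraph::transitivity(g, type = "local", isolates = "zero")
  clus[is.nan(clus)] <- 0
  names(clus) <- net$cell_ids
  k_avg <- mean(deg)
  c_avg <- mean(clus)
  if (m > 0) {
    comm <- igraph::cluster_fast_greedy(g)
    membership <- igraph::membership(comm)
    q <- igraph::modularity(g, membership)
  } else {
    membership <- stats::setNames(seq_len(n), net$cell_ids)
    q <- NA_real_
  }
  d <- igraph::distances(g)
  off <- d[row(d) != col(d)]
  eff <- mean(ifelse(is.finite(off), 1 / off, 0))
  comp <- igraph::components(g)
  s_max <- max(comp$csize) / n
  lcc <- which(comp$membership == which.max(comp$csize))
  l_avg <- if (length(lcc) > 1) {
    dl <- d[lcc, lcc]
    mean(dl[row(dl) != col(dl)])
  } else NA_real_
  sw <- NA_real_
  if (sw_randomizations > 0 && m > 0 && is.finite(l_avg) && l_avg > 0) {
    ref <- with_seed(seed, {
      vapply(seq_len(sw_randomizations), function(r) {
        gr <- if (random_ref == "density") igraph::sample_gnm(n, m)
        else igraph::sample_degseq(deg, method = "fast.heur.simple")
        cr <- igraph::transitivity(gr, type = "local", isolates = "zero")
        cr[is.nan(cr)] <- 0
        dr <- igraph::distances(gr)
        compr <- igraph::components(gr)
        lccr <- which(compr$membership == which.max(compr$csize))
        lr <- if (length(lccr) > 1) {
          dd <- dr[lccr, lccr]
          mean(dd[row(dd) != col(dd)])
        } else NA_real_
        c(mean(cr), lr)
      }, numeric(2))
    })
    c_rand <- mean(ref[1, ], na.rm = TRUE)
    l_rand <- mean(ref[2, ], na.rm = TRUE)
    if (is.finite(c_rand) && c_rand > 0 && is.finite(l_rand) && l_rand > 0)
      sw <- (c_avg / c_rand) / (l_avg / l_rand)
  }
  out <- list(k_avg = k_avg, C_avg = c_avg, Q = q, E = eff, S_max = s_max,
              L_avg = l_avg, SW = sw,
              degree_list = deg, clustering_list = clus,
              membership = membership, n_cells = n, n_edges = m)
  if (!is.null(net$coords) && m > 0) {
    out$edge_lengths_um <- edge_length_distribution(net, normalize = FALSE)
    out$edge_lengths_relative <- edge_length_distribution(net,
                                                          normalize = TRUE)
  }
  class(out) <- "network_metrics"
  out
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf("<network_metrics> N = %d, edges = %d\n", x$n_cells, x$n_edges))
  cat(sprintf("  k_avg = %.3f  C_avg = %.3f  Q = %.3f  E = %.3f\n",
              x$k_avg, x$C_avg, x$Q, x$E))
  cat(sprintf("  S_max = %.3f  L_avg = %.3f  SW = %.3f\n",
              x$S_max, x$L_avg, x$SW))
  invisible(x)
}

#' Physical lengths of network edges
#'
#' Euclidean edge lengths in micrometers. With `normalize = TRUE` lengths
#' are divided by the islet's local inter-cell scale: the mean over cells of
#' the average distance to their 8 nearest neighbors, which makes length
#' distributions comparable across islets of different cell density.
#'
#' @param net a [functional_network()] with coordinates.
#' @param normalize divide by the 8-nearest-neighbor distance scale.
#' @return Numeric vector, one length per edge (possibly empty).
#' @export
edge_length_distribution <- function(net, normalize = FALSE) {
  stopifnot(inherits(net, "functional_network"))
  if (is.null(net$coords)) stop("network has no coordinates", call. = FALSE)
  if (nrow(net$edges) == 0) return(numeric(0))
  i <- match(net$edges$cell_i, net$cell_ids)
  j <- match(net$edges$cell_j, net$cell_ids)
  len <- sqrt((net$coords$x_um[i] - net$coords$x_um[j])^2 +
                (net$coords$y_um[i] - net$coords$y_um[j])^2)
  if (!normalize) return(len)
  n <- length(net$cell_ids)
  kkn <- 8L
  if (n - 1 < kkn) {
    warning(sprintf("fewer than 9 cells; normalizing with %d nearest neighbors",
                    n - 1L), call. = FALSE)
    kkn <- n - 1L
  }
  dm <- as.matrix(stats::dist(net$coords[, c("x_um", "y_um")]))
  nn_mean <- vapply(seq_len(n), function(a) {
    mean(sort(dm[a, -a])[seq_len(kkn)])
  }, 0)
  len / mean(nn_mean)
}

#' Identify hub cells
#'
#' The top `fraction` (default 1/6) most connected cells. Returns exactly
#' `ceiling(fraction * N)` cells; ties at the degree cutoff are broken by
#' cell-id order, so the result is deterministic.
#'
#' @param net a [functional_network()].
#' @param fraction fraction of cells to label as hubs, in (0, 1).
#' @return Character vector of hub cell ids.
#' @export
identify_hubs <- function(net, fraction = 1 / 6) {
  stopifnot(inherits(net, "functional_network"))
  if (fraction <= 0 || fraction >= 1)
    stop("`fraction` must be in (0, 1)", call. = FALSE)
  n <- length(net$cell_ids)
  n_hub <- ceiling(fraction * n)
  deg <- igraph::degree(as_igraph(net))[net$cell_ids]
  ord <- order(-deg, net$cell_ids)
  net$cell_ids[ord[seq_len(n_hub)]]
}

#' Relation between node degree and cellular activity
#'
#' Bins cells by normalized node degree (k divided by the islet's maximum
#' degree, or by its average degree with `norm = "kavg"`) and reports the
#' mean relative active time per bin with standard errors, plus the Pearson
#' correlation between degree and activity. When given lists of networks
#' and activity vectors, islets are pooled after per-islet normalization of
#' both degree and activity (activity divided by the islet mean), which
#' keeps inter-islet heterogeneity from masking the relation.
#'
#' @param net a [functional_network()] or list of them.
#' @param rat per-cell relative active time (named or in node order), or a
#'   list of such vectors matching `net`.
#' @param n_bins number of equal-width bins over the normalized degree
#'   range `[0, 1]`.
#' @param norm `"kmax"` (default) or `"kavg"` degree normalization.
#' @return List with `table` (data frame: `bin_center`, `mean_activity`,
#'   `se`, `n`; empty bins omitted) and `r` (Pearson correlation of degree
#'   vs activity; `NA` when degrees are constant).
#' @export
degree_activity_relation <- function(net, rat, n_bins = 10,
                                     norm = c("kmax", "kavg")) {
  norm <- match.arg(norm)
  nets <- if (inherits(net, "functional_network")) list(net) else net
  rats <- if (is.list(rat)) rat else list(rat)
  if (length(nets) != length(rats))
    stop("`net` and `rat` lists must have equal length", call. = FALSE)
  pooled <- length(nets) > 1
  kn <- numeric(0)
  act <- numeric(0)
  for (s in seq_along(nets)) {
    nt <- nets[[s]]
    deg <- igraph::degree(as_igraph(nt))[nt$cell_ids]
    a <- rats[[s]]
    if (!is.null(names(a))) a <- a[nt$cell_ids]
    if (length(a) != length(deg) || anyNA(a))
      stop("activity vector must cover all nodes", call. = FALSE)
    denom <- if (norm == "kmax") max(deg) else mean(deg)
    kk <- if (denom > 0) deg / denom else deg
    if (pooled) {
      mu <- mean(a)
      a <- if (mu > 0) a / mu else a
    }
    kn <- c(kn, kk)
    act <- c(act, a)
  }
  r <- if (stats::sd(kn) == 0) NA_real_       # constant degrees: undefined
  else if (stats::sd(act) == 0) 0              # constant activity: no relation
  else stats::cor(kn, act)
  brks <- seq(0, max(1, max(kn)), length.out = n_bins + 1)
  bin <- cut(kn, brks, include.lowest = TRUE)
  tab <- do.call(rbind, lapply(split(seq_along(kn), bin), function(idx) {
    if (length(idx) == 0) return(NULL)
    data.frame(mean_activity = mean(act[idx]),
               se = stats::sd(act[idx]) / sqrt(length(idx)),
               n = length(idx))
  }))
  centers <- (brks[-length(brks)] + brks[-1]) / 2
  keep <- as.integer(table(bin)) > 0
  tab <- cbind(bin_center = centers[keep], tab)
  rownames(tab) <- NULL
  list(table = tab, r = r)
}
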