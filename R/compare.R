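#' Network similarity index (Jaccard edge overlap)
#'
#' Similarity of two networks over the same cells as the Jaccard
#' coefficient of their edge sets: the number of shared edges divided by
#' the number of edges in the union. 0 means no common edges, 1 means
#' identical networks. Two empty networks are defined as identical (1) with
#' a warning.
#'
#' @param a,b [functional_network()] objects over the same cell set.
#' @return NSI in `[0, 1]`.
#' @export
nsi <- function(a, b) {
  check_same_nodes(a, b)
  ka <- edge_keys(a$edges$cell_i, a$edges$cell_j)
  kb <- edge_keys(b$edges$cell_i, b$edges$cell_j)
  if (length(ka) == 0 && length(kb) == 0) {
    warning("both networks are empty; NSI defined as 1", call. = FALSE)
    return(1)
  }
  length(intersect(ka, kb)) / length(union(ka, kb))
}

check_same_nodes <- function(a, b) {
  stopifnot(inherits(a, "functional_network"),
            inherits(b, "functional_network"))
  if (!identical(sort(a$cell_ids), sort(b$cell_ids)))
    stop("networks are defined over different cell sets", call. = FALSE)
  invisible(TRUE)
}

#' Hub overlap between two networks
#'
#' Fraction of shared hub cells, with hubs taken as the top `fraction`
#' (default 1/6) most connected cells in each network and the overlap
#' normalized by the hub-set size (equal in both networks by construction).
#'
#' @param a,b [functional_network()] objects over the same cell set.
#' @param fraction hub fraction, see [identify_hubs()].
#' @return Overlap fraction in `[0, 1]`.
#' @export
hub_overlap <- function(a, b, fraction = 1 / 6) {
  check_same_nodes(a, b)
  ha <- identify_hubs(a, fraction)
  hb <- identify_hubs(b, fraction)
  length(intersect(ha, hb)) / length(ha)
}

#' Per-cell degree pairing between two networks
#'
#' Pairs each cell's degree in network `a` with its degree in network `b`,
#' fits the least-squares line, and reports the R-squared of the relation —
#' a per-node complement to the edge-set overlap of [nsi()].
#'
#' @param a,b [functional_network()] objects over the same cell set.
#' @return List with `degree_pairs` (data frame: `cell_id`, `degree_a`,
#'   `degree_b`), `slope`, `intercept`, and `r_squared` (`NA` when either
#'   degree sequence is constant).
#' @export
degree_pairing <- function(a, b) {
  check_same_nodes(a, b)
  ids <- sort(a$cell_ids)
  da <- igraph::degree(as_igraph(a))[ids]
  db <- igraph::degree(as_igraph(b))[ids]
  pairs <- data.frame(cell_id = ids, degree_a = as.numeric(da),
                      degree_b = as.numeric(db))
  if (stats::sd(da) == 0 || stats::sd(db) == 0)
    return(list(degree_pairs = pairs, slope = NA_real_,
                intercept = NA_real_, r_squared = NA_real_))
  fit <- stats::lm(degree_b ~ degree_a, data = pairs)
  # identical networks give an exact fit; the perfect-fit warning is moot
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(degree_pairs = pairs,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}

#' Pairwise NSI matrix across a set of networks
#'
#' @param nets named list of [functional_network()] objects over the same
#'   cells.
#' @return Symmetric matrix of pairwise NSI values with unit diagonal.
#' @export
nsi_matrix <- function(nets) {
  k <- length(nets)
  out <- matrix(1, k, k, dimnames = list(names(nets), names(nets)))
  if (k < 2) return(out)
  for (a in 1:(k - 1)) for (b in (a + 1):k) {
    v <- nsi(nets[[a]], nets[[b]])
    out[a, b] <- v
    out[b, a] <- v
  }
  out
}
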