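#' Cell-pair similarity matrix
#'
#' Symmetric N x N matrix of pairwise similarity values with a method tag.
#' The diagonal and any undefined pairs (zero-variance, all-inactive, or
#' zero-entropy cells) are set to `NA` and are excluded from all downstream
#' edge logic.
#'
#' @param values symmetric numeric matrix; diagonal is forced to `NA`.
#' @param method one of `"correlation"`, `"coactivity"`,
#'   `"mutual_information"`.
#' @param cell_ids per-cell labels; defaults to the matrix dimnames.
#' @param source optional provenance record (band, interval, binarization
#'   parameters).
#' @return An object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(values,
                              method = c("correlation", "coactivity",
                                         "mutual_information"),
                              cell_ids = NULL, source = NULL) {
  method <- match.arg(method)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("similarity matrix must be square", call. = FALSE)
  if (!isTRUE(all.equal(unname(values), unname(t(values)))))
    stop("similarity matrix must be symmetric", call. = FALSE)
  values <- (values + t(values)) / 2  # exact symmetry
  diag(values) <- NA_real_
  if (is.null(cell_ids)) {
    cell_ids <- rownames(values)
    if (is.null(cell_ids)) cell_ids <- sprintf("cell_%d", seq_len(nrow(values)))
  }
  dimnames(values) <- list(cell_ids, cell_ids)
  structure(list(values = values, method = method, n_cells = nrow(values),
                 cell_ids = as.character(cell_ids), source = source),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("<similarity_matrix> %s, %d cells; off-diagonal range [%.3f, %.3f], %d undefined pair(s)\n",
              x$method, x$n_cells,
              suppressWarnings(min(off, na.rm = TRUE)),
              suppressWarnings(max(off, na.rm = TRUE)), sum(is.na(off))))
  invisible(x)
}

#' Pearson correlation similarity matrix
#'
#' Pairwise sample Pearson correlation of the (typically filtered) traces.
#' Ranges over `[-1, 1]`: 1 for identical, -1 for perfectly anticorrelated
#' time courses. Cells with zero variance get an undefined (`NA`) row and
#' column.
#'
#' @param rec a [calcium_recording()] (raw or filtered component).
#' @return A [similarity_matrix()] with `method = "correlation"`.
#' @export
pearson_matrix <- function(rec) {
  stopifnot(inherits(rec, "calcium_recording"))
  if (nrow(rec$traces) < 3)
    stop("need at least 3 frames", call. = FALSE)
  sds <- apply(rec$traces, 2, stats::sd)
  bad <- sds == 0
  vals <- suppressWarnings(stats::cor(rec$traces))
  if (any(bad)) {
    warning(sprintf("%d zero-variance cell(s) set to undefined", sum(bad)),
            call. = FALSE)
    vals[bad, ] <- NA_real_
    vals[, bad] <- NA_real_
  }
  similarity_matrix(vals, "correlation", rec$cell_ids,
                    source = list(kind = "pearson"))
}

#' Coactivity similarity matrix
#'
#' Degree of simultaneous activity between binarized cell pairs: the dot
#' product of the two binary state vectors, normalized by the geometric mean
#' of their active-frame counts (the dot product of the unit-normalized
#' vectors). Ranges over `[0, 1]`: 0 when activity never overlaps, 1 when
#' the cells are perfectly coactive. `literal = TRUE` instead divides by the
#' plain product of active-frame counts (no radical), a variant whose upper
#' end depends on the activity level.
#'
#' @param bin a [binarize()] result or 0/1 matrix (frames x cells).
#' @param literal use the plain-product denominator instead of the
#'   unit-normalized form.
#' @return A [similarity_matrix()] with `method = "coactivity"`.
#' @export
coactivity_matrix <- function(bin, literal = FALSE) {
  states <- if (inherits(bin, "binarized_activity")) bin$states else
    as.matrix(bin)
  ids <- if (inherits(bin, "binarized_activity")) bin$cell_ids else
    colnames(states)
  counts <- colSums(states)
  co <- crossprod(states)  # pairwise overlap counts
  denom <- if (literal) outer(counts, counts) else sqrt(outer(counts, counts))
  vals <- co / denom
  bad <- counts == 0
  if (any(bad)) {
    warning(sprintf("%d all-inactive cell(s) set to undefined", sum(bad)),
            call. = FALSE)
    vals[bad, ] <- NA_real_
    vals[, bad] <- NA_real_
  }
  similarity_matrix(vals, "coactivity", ids,
                    source = list(literal = literal))
}

#' Shannon entropy of a binary state vector
#'
#' `H = -sum_s p(s) log2 p(s)` over the two states, with probabilities from
#' frequency counts and the convention `0 log 0 = 0`. Units: bits.
#'
#' @param x binary vector (0/1).
#' @return Entropy in bits, in `[0, 1]`.
#' @examples
#' binary_entropy(c(1, 1, 0, 0))  # 1 bit
#' @export
binary_entropy <- function(x) {
  if (length(x) == 0) stop("empty vector", call. = FALSE)
  p <- mean(x == 1)
  pr <- c(p, 1 - p)
  pr <- pr[pr > 0]
  -sum(pr * log2(pr))
}

# Joint entropy of two binary vectors from the 2x2 frequency table.
joint_entropy2 <- function(x, y) {
  n <- length(x)
  n11 <- sum(x == 1 & y == 1)
  n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1)
  n00 <- n - n11 - n10 - n01
  pr <- c(n11, n10, n01, n00) / n
  pr <- pr[pr > 0]
  -sum(pr * log2(pr))
}

#' Normalized mutual information similarity matrix
#'
#' Mutual information between binarized cell pairs,
#' `MI = H(x_i) + H(x_j) - H(x_i, x_j)` with base-2 logarithms, the joint
#' distribution estimated by frequency counts over the four state
#' combinations. Each entry is normalized by the geometric mean
#' `sqrt(H_i H_j)` so identical series score 1 and independent series score
#' 0. Pairs involving a zero-entropy cell (constant state) are undefined
#' (`NA`). `literal = TRUE` normalizes by the plain product `H_i H_j`
#' instead.
#'
#' @param bin a [binarize()] result or 0/1 matrix (frames x cells).
#' @param literal use the plain-product denominator.
#' @return A [similarity_matrix()] with `method = "mutual_information"`.
#' @export
nmi_matrix <- function(bin, literal = FALSE) {
  states <- if (inherits(bin, "binarized_activity")) bin$states else
    as.matrix(bin)
  ids <- if (inherits(bin, "binarized_activity")) bin$cell_ids else
    colnames(states)
  n <- nrow(states)
  nc <- ncol(states)
  counts <- colSums(states)
  h <- vapply(seq_len(nc), function(i) binary_entropy(states[, i]), 0)
  # vectorized joint counts across all pairs
  n11 <- crossprod(states)
  n10 <- outer(counts, rep(1, nc)) - n11       # i active, j inactive
  n01 <- t(n10)
  n00 <- n - n11 - n10 - n01
  plogp <- function(m) {
    p <- m / n
    out <- matrix(0, nc, nc)
    pos <- p > 0
    out[pos] <- p[pos] * log2(p[pos])
    out
  }
  hj <- -(plogp(n11) + plogp(n10) + plogp(n01) + plogp(n00))
  mi <- outer(h, h, "+") - hj
  denom <- if (literal) outer(h, h) else sqrt(outer(h, h))
  vals <- mi / denom
  bad <- h == 0
  if (any(bad)) {
    warning(sprintf("%d zero-entropy cell(s) set to undefined", sum(bad)),
            call. = FALSE)
    vals[bad, ] <- NA_real_
    vals[, bad] <- NA_real_
  }
  vals[!is.na(vals)] <- pmin(pmax(vals[!is.na(vals)], 0), 1)  # clip rounding
  similarity_matrix(vals, "mutual_information", ids,
                    source = list(literal = literal))
}

#' Mutual information between two binary vectors
#'
#' Convenience scalar form of the matrix computation; see [nmi_matrix()].
#'
#' @param x,y binary vectors of equal length.
#' @param normalized divide by `sqrt(H(x) H(y))`.
#' @return MI in bits, or normalized MI in `[0, 1]` (`NA` when a marginal
#'   entropy is zero).
#' @export
mutual_information <- function(x, y, normalized = FALSE) {
  stopifnot(length(x) == length(y), length(x) > 0)
  mi <- binary_entropy(x) + binary_entropy(y) - joint_entropy2(x, y)
  if (!normalized) return(max(mi, 0))
  d <- binary_entropy(x) * binary_entropy(y)
  if (d == 0) return(NA_real_)
  min(max(mi / sqrt(d), 0), 1)
}

#' Write / read a similarity matrix as square CSV
#'
#' The CSV carries cell ids as header row and first column; the method tag
#' is stored in a JSON sidecar `<path>.json`.
#'
#' @param S a [similarity_matrix()].
#' @param path CSV path.
#' @return `path` (write), or a `similarity_matrix` (read).
#' @export
write_similarity_csv <- function(S, path) {
  stopifnot(inherits(S, "similarity_matrix"))
  tab <- data.frame(cell_id = S$cell_ids,
                    as.data.frame(S$values, check.names = FALSE),
                    check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  jsonlite::write_json(list(method = S$method, source = S$source),
                       paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_similarity_csv
#' @export
read_similarity_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  ids <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  meta_path <- paste0(path, ".json")
  method <- "correlation"
  src <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::fromJSON(meta_path)
    method <- meta$method
    src <- meta$source
  }
  vals[is.na(vals)] <- NA_real_
  # restore exact symmetry lost to decimal round-trip
  vals[lower.tri(vals)] <- t(vals)[lower.tri(vals)]
  similarity_matrix(vals, method, ids, src)
}
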