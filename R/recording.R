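#' Calcium imaging recording
#'
#' Container for ROI-averaged fluorescence traces: a frames x cells matrix
#' together with the sampling frequency, per-cell planar coordinates
#' (micrometers) and optional named protocol intervals.
#'
#' @param traces numeric matrix, rows = frames, columns = cells. All values
#'   must be finite.
#' @param fs sampling frequency in Hz (> 0).
#' @param coords data frame or matrix with columns `x_um`, `y_um`, one row per
#'   cell, or `NULL` when positions are unknown.
#' @param cell_ids character vector of stable per-cell labels; defaults to
#'   column names of `traces` or `cell_1 ... cell_N`.
#' @param intervals optional data frame with columns `name`, `start_s`,
#'   `end_s`; every interval must satisfy `0 <= start_s < end_s <= duration`.
#'
#' @return An object of class `calcium_recording` with elements `traces`,
#'   `fs`, `coords`, `cell_ids`, `intervals`.
#' @examples
#' tr <- matrix(rnorm(200), 100, 2)
#' rec <- calcium_recording(tr, fs = 10)
#' rec
#' @export
calcium_recording <- function(traces, fs, coords = NULL, cell_ids = NULL,
                              intervals = NULL) {
  traces <- as.matrix(traces)
  storage.mode(traces) <- "double"
  rownames(traces) <- NULL
  if (!all(is.finite(traces)))
    stop("all trace values must be finite", call. = FALSE)
  stop_if_not_scalar_number(fs, "fs")
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  n <- ncol(traces)
  if (is.null(cell_ids)) {
    cell_ids <- colnames(traces)
    if (is.null(cell_ids)) cell_ids <- sprintf("cell_%d", seq_len(n))
  }
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != n || anyDuplicated(cell_ids))
    stop("`cell_ids` must be unique and match the number of trace columns",
         call. = FALSE)
  colnames(traces) <- cell_ids
  if (!is.null(coords)) {
    coords <- as.data.frame(coords)
    if (!all(c("x_um", "y_um") %in% names(coords))) {
      if (ncol(coords) >= 2) names(coords)[1:2] <- c("x_um", "y_um")
      else stop("`coords` needs columns x_um, y_um", call. = FALSE)
    }
    coords <- coords[, c("x_um", "y_um")]
    if (nrow(coords) != n)
      stop("number of coordinate rows must equal number of cells",
           call. = FALSE)
    if (!all(is.finite(as.matrix(coords))))
      stop("coordinates must be finite", call. = FALSE)
    rownames(coords) <- cell_ids
  }
  duration <- nrow(traces) / fs
  if (!is.null(intervals)) {
    intervals <- as.data.frame(intervals)
    req <- c("name", "start_s", "end_s")
    if (!all(req %in% names(intervals)))
      stop("`intervals` needs columns name, start_s, end_s", call. = FALSE)
    ok <- intervals$start_s >= 0 & intervals$start_s < intervals$end_s &
      intervals$end_s <= duration + 1e-9
    if (!all(ok))
      stop("every interval must satisfy 0 <= start < end <= duration",
           call. = FALSE)
  }
  structure(
    list(traces = traces, fs = fs, coords = coords, cell_ids = cell_ids,
         intervals = intervals),
    class = "calcium_recording"
  )
}

#' @export
print.calcium_recording <- function(x, ...) {
  cat(sprintf("<calcium_recording> %d frames x %d cells, fs = %g Hz (%.1f s)\n",
              nrow(x$traces), ncol(x$traces), x$fs, nrow(x$traces) / x$fs))
  if (!is.null(x$coords)) cat("  coordinates: present (um)\n")
  if (!is.null(x$intervals))
    cat(sprintf("  intervals: %s\n", paste(x$intervals$name, collapse = ", ")))
  invisible(x)
}

#' @export
dim.calcium_recording <- function(x) dim(x$traces)

#' Extract the frames of a named protocol interval
#'
#' @param rec a [calcium_recording()].
#' @param name interval name present in `rec$intervals`, or a numeric vector
#'   `c(start_s, end_s)`.
#' @return A `calcium_recording` restricted to the frames of that interval
#'   (intervals are dropped from the result).
#' @export
subset_interval <- function(rec, name) {
  stopifnot(inherits(rec, "calcium_recording"))
  if (is.character(name)) {
    if (is.null(rec$intervals) || !name %in% rec$intervals$name)
      stop(sprintf("no interval named '%s'", name), call. = FALSE)
    row <- rec$intervals[match(name, rec$intervals$name), ]
    win <- c(row$start_s, row$end_s)
  } else {
    win <- as.numeric(name)
    if (length(win) != 2 || win[1] < 0 || win[1] >= win[2])
      stop("numeric interval must be c(start_s, end_s)", call. = FALSE)
  }
  idx <- which((seq_len(nrow(rec$traces)) - 1) / rec$fs >= win[1] &
                 (seq_len(nrow(rec$traces)) - 1) / rec$fs < win[2])
  if (length(idx) == 0) stop("interval contains no frames", call. = FALSE)
  calcium_recording(rec$traces[idx, , drop = FALSE], rec$fs, rec$coords,
                    rec$cell_ids)
}

#' Read a recording from CSV files
#'
#' The trace CSV has time (seconds) or frame index in the first column and one
#' column per cell with cell ids in the header. The optional coordinate CSV
#' has columns `cell_id`, `x_um`, `y_um`.
#'
#' @param traces_csv path to the trace table.
#' @param fs sampling frequency in Hz; when `NULL` it is inferred from the
#'   median spacing of the first column.
#' @param coords_csv optional coordinate table path.
#' @param intervals optional path to a YAML or JSON file holding a list of
#'   `{name, start_s, end_s}` records.
#' @return A [calcium_recording()].
#' @export
read_recording_csv <- function(traces_csv, fs = NULL, coords_csv = NULL,
                               intervals = NULL) {
  tab <- utils::read.csv(traces_csv, check.names = FALSE)
  if (ncol(tab) < 2) stop("trace CSV needs a time column plus cells",
                          call. = FALSE)
  tvec <- tab[[1]]
  traces <- as.matrix(tab[, -1, drop = FALSE])
  if (is.null(fs)) {
    dt <- stats::median(diff(tvec))
    if (!is.finite(dt) || dt <= 0)
      stop("cannot infer fs from the time column; pass `fs`", call. = FALSE)
    fs <- if (dt == 1 && all(tvec == round(tvec))) 1 else 1 / dt
  }
  coords <- NULL
  if (!is.null(coords_csv)) {
    ct <- utils::read.csv(coords_csv)
    ct <- ct[match(colnames(traces), as.character(ct$cell_id)), ]
    if (anyNA(ct$x_um)) stop("coordinate table is missing cells",
                             call. = FALSE)
    coords <- ct[, c("x_um", "y_um")]
  }
  ints <- if (!is.null(intervals)) read_intervals(intervals) else NULL
  calcium_recording(traces, fs, coords, colnames(traces), ints)
}

#' Write a recording to CSV
#'
#' Inverse of [read_recording_csv()]: writes `<path>` with a `time_s` column,
#' and `<path_coords>` (when coordinates exist) with `cell_id`, `x_um`, `y_um`.
#'
#' @param rec a [calcium_recording()].
#' @param path output CSV path for traces.
#' @param coords_path optional output path for coordinates.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path, coords_path = NULL) {
  stopifnot(inherits(rec, "calcium_recording"))
  tab <- data.frame(time_s = (seq_len(nrow(rec$traces)) - 1) / rec$fs)
  tab <- cbind(tab, as.data.frame(rec$traces, check.names = FALSE))
  utils::write.csv(tab, path, row.names = FALSE)
  if (!is.null(coords_path) && !is.null(rec$coords)) {
    ct <- data.frame(cell_id = rec$cell_ids, x_um = rec$coords$x_um,
                     y_um = rec$coords$y_um)
    utils::write.csv(ct, coords_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read protocol intervals from YAML or JSON
#'
#' @param path file holding a list of `{name, start_s, end_s}` records.
#' @return data frame with columns `name`, `start_s`, `end_s`.
#' @export
read_intervals <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  out <- do.call(rbind, lapply(lst, function(x)
    data.frame(name = as.character(x$name), start_s = as.numeric(x$start_s),
               end_s = as.numeric(x$end_s))))
  out
}
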