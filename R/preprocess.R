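#' Band-pass filter specification
#'
#' Named frequency bands for separating the oscillatory components of
#' calcium traces. The defaults follow common practice for islet recordings:
#' the fast electrical-bursting component at 0.05--2.0 Hz, the slow
#' metabolic component at 0.001--0.07 Hz, and a broad oscillatory band at
#' 0.005--0.25 Hz for isolated-islet recordings.
#'
#' @param band_name one of `"fast"`, `"slow"`, `"oscillatory"`, `"raw"`, or a
#'   custom label when both cutoffs are supplied.
#' @param low_cut,high_cut cutoff frequencies in Hz; when missing they are
#'   taken from the named band.
#' @return An object of class `filter_spec` with fields `band_name`,
#'   `low_cut`, `high_cut`.
#' @examples
#' filter_spec("fast")
#' filter_spec("custom", 0.01, 0.5)
#' @export
filter_spec <- function(band_name = c("fast", "slow", "oscillatory", "raw"),
                        low_cut = NULL, high_cut = NULL) {
  defaults <- list(fast = c(0.05, 2.0), slow = c(0.001, 0.07),
                   oscillatory = c(0.005, 0.25))
  if (is.null(low_cut) || is.null(high_cut)) {
    band_name <- match.arg(band_name)
    if (band_name == "raw")
      return(structure(list(band_name = "raw", low_cut = NA_real_,
                            high_cut = NA_real_), class = "filter_spec"))
    cuts <- defaults[[band_name]]
    low_cut <- cuts[1]; high_cut <- cuts[2]
  } else {
    band_name <- as.character(band_name)[1]
  }
  stop_if_not_scalar_number(low_cut, "low_cut")
  stop_if_not_scalar_number(high_cut, "high_cut")
  if (low_cut < 0 || low_cut >= high_cut)
    stop("need 0 <= low_cut < high_cut", call. = FALSE)
  structure(list(band_name = band_name, low_cut = low_cut,
                 high_cut = high_cut), class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  if (x$band_name == "raw") cat("<filter_spec> raw (no filtering)\n")
  else cat(sprintf("<filter_spec> %s: %g-%g Hz\n", x$band_name, x$low_cut,
                   x$high_cut))
  invisible(x)
}

# Mirror (odd) extension a la scipy.signal.filtfilt: reflect the trace about
# its end points so the filter starts near steady state.
odd_pad <- function(x, npad) {
  n <- length(x)
  npad <- min(npad, n - 1L)
  if (npad <= 0) return(list(x = x, npad = 0L))
  head_ext <- 2 * x[1] - x[(npad + 1L):2L]
  tail_ext <- 2 * x[n] - x[(n - 1L):(n - npad)]
  list(x = c(head_ext, x, tail_ext), npad = npad)
}

#' Zero-phase band-pass filtering of calcium traces
#'
#' Applies a second-order Butterworth band-pass forward and backward
#' (effective fourth order), giving exactly zero phase lag: the
#' cross-correlation between an in-band input sinusoid and its filtered
#' version peaks at lag 0. The per-trace mean is removed first and the trace
#' is mirror-padded at both ends to suppress filter start-up transients.
#'
#' @param rec a [calcium_recording()].
#' @param spec a [filter_spec()]; `band_name = "raw"` returns the recording
#'   unchanged.
#' @return A `calcium_recording` with filtered traces (same shape).
#' @examples
#' t <- seq(0, 60, by = 0.1)
#' rec <- calcium_recording(cbind(sin(2 * pi * 0.5 * t)), fs = 10)
#' out <- bandpass_filter(rec, filter_spec("fast"))
#' @export
bandpass_filter <- function(rec, spec) {
  stopifnot(inherits(rec, "calcium_recording"), inherits(spec, "filter_spec"))
  if (spec$band_name == "raw") return(rec)
  nyq <- rec$fs / 2
  if (!(spec$low_cut >= 0 && spec$low_cut < spec$high_cut &&
        spec$high_cut < nyq))
    stop(sprintf(
      "invalid filter: cutoffs [%g, %g] Hz incompatible with fs = %g Hz",
      spec$low_cut, spec$high_cut, rec$fs), call. = FALSE)
  n <- nrow(rec$traces)
  # settling scale of the slow edge of the band, in frames
  settle <- ceiling(rec$fs / spec$low_cut)
  if (n < 3 * min(settle, n)) {
    if (n < 30)
      stop("trace too short for the requested band", call. = FALSE)
  }
  bf <- signal::butter(1, c(spec$low_cut, spec$high_cut) / nyq, type = "pass")
  npad <- min(n - 1L, as.integer(ceiling(3 * rec$fs / spec$low_cut)))
  out <- apply(rec$traces, 2, function(x) {
    x <- x - mean(x)
    if (all(x == 0)) return(x)
    p <- odd_pad(x, npad)
    y <- signal::filtfilt(bf, p$x)
    if (p$npad > 0) y <- y[(p$npad + 1L):(p$npad + length(x))]
    y
  })
  out <- matrix(out, nrow = n, dimnames = dimnames(rec$traces))
  calcium_recording(out, rec$fs, rec$coords, rec$cell_ids, rec$intervals)
}

#' Adjacency-averaging smoother
#'
#' Centered moving average with an odd window; at the trace ends the window
#' shrinks symmetrically rather than padding with fabricated values.
#'
#' @param traces numeric matrix (frames x cells) or vector.
#' @param window positive odd integer window length, at most the trace length.
#' @return Smoothed traces, same shape as the input.
#' @examples
#' smooth_traces(c(0, 0, 1, 0, 0), 3)
#' @export
smooth_traces <- function(traces, window) {
  if (!is.numeric(window) || length(window) != 1 || window < 1 ||
      window %% 2 == 0)
    stop("`window` must be a positive odd integer", call. = FALSE)
  vec <- is.null(dim(traces))
  m <- if (vec) matrix(traces, ncol = 1) else as.matrix(traces)
  if (window > nrow(m))
    stop("`window` exceeds the trace length", call. = FALSE)
  if (window == 1) return(traces)
  h <- (window - 1L) %/% 2L
  n <- nrow(m)
  cs <- apply(m, 2, function(x) cumsum(c(0, x)))
  idx <- seq_len(n)
  lo <- pmax(idx - h, 1L)
  hi <- pmin(idx + h, n)
  # shrink symmetrically at the edges so the window stays centered
  half <- pmin(idx - lo, hi - idx)
  lo <- idx - half
  hi <- idx + half
  out <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
    (hi - lo + 1L)
  dimnames(out) <- dimnames(m)
  if (vec) drop(out) else out
}

# Robust per-trace noise scale from first differences (insensitive to the
# oscillation itself, which changes slowly relative to the frame rate).
noise_scale <- function(x) {
  d <- diff(x)
  stats::median(abs(d - stats::median(d))) / (sqrt(2) * 0.6744898)
}

#' Binarize oscillatory traces into active / inactive states
#'
#' Per cell, a robust amplitude scale is set from the 10th-percentile
#' baseline and 95th-percentile peak of the trace. A frame becomes active
#' when the signal rises above `baseline + on_frac * (peak - baseline)` and
#' remains active until it falls below `baseline + off_frac * (peak -
#' baseline)` (hysteresis, so the active state tracks whole elevations of
#' the calcium signal rather than threshold chatter). Events shorter than
#' `min_duration` seconds are discarded. Cells whose amplitude does not
#' exceed `noise_floor` times a robust estimate of the frame-to-frame noise
#' are marked all-inactive with a warning.
#'
#' @param rec a [calcium_recording()] holding a filtered oscillatory
#'   component (see [bandpass_filter()]).
#' @param on_frac,off_frac activation / deactivation levels as fractions of
#'   the baseline-to-peak amplitude; require `0 < off_frac < on_frac < 1`.
#' @param min_duration minimum event duration in seconds (default two
#'   frames).
#' @param noise_floor minimal amplitude in units of the estimated noise SD
#'   for a cell to be considered oscillating at all.
#' @return An object of class `binarized_activity`: list with `states`
#'   (0/1 matrix, frames x cells), `params`, `source_band`, `fs`, `cell_ids`.
#' @examples
#' t <- seq(0, 100, by = 0.5)
#' sq <- ifelse(t %% 20 < 8, 1, 0)   # 40% duty cycle
#' rec <- calcium_recording(cbind(sq), fs = 2)
#' b <- binarize(rec)
#' relative_active_time(b)
#' @export
binarize <- function(rec, on_frac = 0.5, off_frac = 0.3, min_duration = NULL,
                     noise_floor = 4) {
  stopifnot(inherits(rec, "calcium_recording"))
  if (!(off_frac > 0 && off_frac < on_frac && on_frac < 1))
    stop("need 0 < off_frac < on_frac < 1", call. = FALSE)
  if (is.null(min_duration)) min_duration <- 2 / rec$fs
  min_frames <- max(1L, as.integer(round(min_duration * rec$fs)))
  n <- nrow(rec$traces)
  states <- matrix(0L, n, ncol(rec$traces), dimnames = dimnames(rec$traces))
  flat <- character(0)
  for (c_idx in seq_len(ncol(rec$traces))) {
    x <- rec$traces[, c_idx]
    base <- stats::quantile(x, 0.10, names = FALSE)
    peak <- stats::quantile(x, 0.95, names = FALSE)
    amp <- peak - base
    if (amp <= noise_floor * noise_scale(x) || amp <= 0) {
      flat <- c(flat, rec$cell_ids[c_idx])
      next
    }
    on_th <- base + on_frac * amp
    off_th <- base + off_frac * amp
    s <- integer(n)
    active <- FALSE
    for (t_idx in seq_len(n)) {
      if (!active && x[t_idx] >= on_th) active <- TRUE
      else if (active && x[t_idx] < off_th) active <- FALSE
      s[t_idx] <- as.integer(active)
    }
    # drop events shorter than the minimum duration
    if (min_frames > 1L) {
      r <- rle(s)
      r$values[r$values == 1L & r$lengths < min_frames] <- 0L
      s <- inverse.rle(r)
    }
    states[, c_idx] <- s
  }
  if (length(flat) > 0)
    warning(sprintf("%d cell(s) below the amplitude noise floor, marked inactive: %s",
                    length(flat), paste(utils::head(flat, 5), collapse = ", ")),
            call. = FALSE)
  structure(
    list(states = states,
         params = list(on_frac = on_frac, off_frac = off_frac,
                       min_duration = min_duration, noise_floor = noise_floor),
         source_band = attr(rec, "band"), fs = rec$fs,
         cell_ids = rec$cell_ids),
    class = "binarized_activity"
  )
}

#' @export
print.binarized_activity <- function(x, ...) {
  cat(sprintf("<binarized_activity> %d frames x %d cells, mean active fraction %.3f\n",
              nrow(x$states), ncol(x$states), mean(x$states)))
  invisible(x)
}

#' Relative active time per cell
#'
#' Fraction of frames each cell spends in the active state (its duty cycle);
#' the standard per-cell activity statistic for binarized calcium traces.
#'
#' @param bin a [binarize()] result, or a plain 0/1 matrix (frames x cells).
#' @return Named numeric vector of per-cell fractions in `[0, 1]`.
#' @export
relative_active_time <- function(bin) {
  states <- if (inherits(bin, "binarized_activity")) bin$states else
    as.matrix(bin)
  if (!all(states %in% c(0, 1)))
    stop("states must be 0/1", call. = FALSE)
  colMeans(states)
}

#' Automated signal-to-noise screen for artifact-laden cells
#'
#' Flags cells whose oscillation amplitude (10th-to-95th percentile range of
#' the filtered trace) falls below `min_snr` times the robust frame-to-frame
#' noise SD. An automated stand-in for manual trace curation.
#'
#' @param rec a filtered [calcium_recording()].
#' @param min_snr amplitude-to-noise floor (default 3).
#' @return Logical vector, `TRUE` for cells that pass the screen.
#' @export
snr_screen <- function(rec, min_snr = 3) {
  stopifnot(inherits(rec, "calcium_recording"))
  vapply(seq_len(ncol(rec$traces)), function(i) {
    x <- rec$traces[, i]
    amp <- diff(stats::quantile(x, c(0.10, 0.95), names = FALSE))
    ns <- noise_scale(x)
    ns == 0 || amp > min_snr * ns
  }, logical(1))
}
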