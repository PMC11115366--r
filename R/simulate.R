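#' Synthetic islet simulation configuration
#'
#' Parameters of the synthetic multicellular calcium recording generator.
#' Defaults emulate islet recordings: fast bursting at about 3 per minute
#' propagating as intercellular waves from peripheral initiator cells at
#' tens of micrometers per second, slow oscillations at about 0.15 per
#' minute with long-range phase coherence, heterogeneous per-cell duty
#' cycles, a fast-decaying calcium-indicator kernel, and photon noise.
#'
#' @param n_cells number of cells.
#' @param disc_radius_um islet (disc) radius in micrometers.
#' @param min_spacing_um minimum inter-cell spacing in micrometers.
#' @param fs sampling frequency in Hz.
#' @param duration_s recording length in seconds.
#' @param fast_period_s inter-burst interval of the fast component in
#'   seconds (20 s corresponds to 3 bursts per minute).
#' @param burst_jitter_frac SD of burst-time jitter as a fraction of the
#'   burst period.
#' @param wave_speed_um_per_s intercellular wave propagation speed.
#' @param n_initiators number of wave-initiator cells, drawn from the outer
#'   20% radial band.
#' @param duty_mean,duty_sd mean and SD of the per-cell duty cycle
#'   (fraction of the burst period spent active).
#' @param slow_period_s period of the slow component in seconds (400 s
#'   corresponds to 0.15 per minute).
#' @param slow_phase_corr_len_um correlation length of the smooth spatial
#'   phase field of the slow component.
#' @param slow_phase_sd SD (radians) of the smooth phase field across the
#'   islet.
#' @param slow_phase_jitter_sd SD (radians) of independent per-cell phase
#'   jitter added on top of the smooth field.
#' @param amp_fast,amp_slow amplitudes of the fast and slow components
#'   (fluorescence units; baseline is 1).
#' @param slow_drift_frac amplitude of cell-intrinsic irregular slow drift
#'   (low-pass filtered noise) as a fraction of `amp_slow`; captures the
#'   cell-to-cell waveform variability of metabolic oscillations.
#' @param kernel_tau_s calcium-indicator decay time constant in seconds
#'   (typical for fast synthetic dyes).
#' @param noise_sd SD of additive Gaussian noise.
#' @param n_async_cells number of asynchronous contaminant cells with
#'   events at independent random times (emulating, e.g., alpha cells).
#' @param seed integer seed; the whole simulation is a deterministic
#'   function of the configuration.
#' @return An object of class `islet_sim_config` (a validated list).
#' @export
islet_sim_config <- function(n_cells = 100, disc_radius_um = 120,
                             min_spacing_um = 15, fs = 5, duration_s = 600,
                             fast_period_s = 20, burst_jitter_frac = 0.05,
                             wave_speed_um_per_s = 50, n_initiators = 3,
                             duty_mean = 0.30, duty_sd = 0.08,
                             slow_period_s = 400,
                             slow_phase_corr_len_um = 100,
                             slow_phase_sd = 0.5,
                             slow_phase_jitter_sd = 0.3,
                             amp_fast = 1, amp_slow = 0.5,
                             slow_drift_frac = 0.7,
                             kernel_tau_s = 0.5, noise_sd = 0.05,
                             n_async_cells = 0, seed = 1) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_cells >= 2, disc_radius_um > 0, min_spacing_um > 0,
              fs > 0, duration_s > 0, fast_period_s > 0,
              wave_speed_um_per_s > 0, n_initiators >= 1,
              duty_mean > 0, duty_mean < 1, duty_sd >= 0,
              slow_period_s > 0, kernel_tau_s > 0, noise_sd >= 0,
              n_async_cells >= 0, n_async_cells < n_cells)
    if (fs * duration_s < 100)
      stop("need at least 100 frames (fs * duration_s)", call. = FALSE)
  })
  class(cfg) <- "islet_sim_config"
  cfg
}

# Dart-throwing placement of n points in a disc with minimum spacing.
place_cells <- function(n, radius, min_spacing, max_tries = 400 * n) {
  xs <- numeric(n)
  ys <- numeric(n)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop(sprintf(
        "cannot place %d cells at %.1f um spacing in a %.1f um disc",
        n, min_spacing, radius), call. = FALSE)
    r <- radius * sqrt(stats::runif(1))
    a <- stats::runif(1, 0, 2 * pi)
    x <- r * cos(a)
    y <- r * sin(a)
    if (placed == 0L ||
        min((xs[1:placed] - x)^2 + (ys[1:placed] - y)^2) >= min_spacing^2) {
      placed <- placed + 1L
      xs[placed] <- x
      ys[placed] <- y
    }
  }
  data.frame(x_um = xs, y_um = ys)
}

#' Generate a synthetic islet recording with ground truth
#'
#' Cells are placed in a disc by seeded dart-throwing. Fast activity:
#' bursts recur every `fast_period_s` (with jitter); each burst starts at a
#' wave-initiator cell (rotating among initiators across bursts, all drawn
#' from the outer 20% radial band) and reaches every cell after a delay
#' equal to its distance from that initiator divided by the wave speed;
#' each cell then stays active for its own duty cycle times the burst
#' period. Slow activity: a sinusoid whose per-cell phase follows a
#' spatially smooth random field (kernel-smoothed Gaussian noise with the
#' configured correlation length) plus small independent jitter, giving
#' long-range but imperfect coherence. The fluorescence trace is baseline
#' 1 plus the event train convolved with an exponential indicator kernel,
#' plus the slow sinusoid and Gaussian noise. Asynchronous contaminant
#' cells receive events at independent random times and a random slow
#' phase.
#'
#' @param cfg an [islet_sim_config()].
#' @return An object of class `synthetic_islet`: list with `recording`
#'   (a [calcium_recording()]), `truth_events` (0/1 frames x cells),
#'   `truth_duty` (per-cell configured duty cycle), `initiator_ids`,
#'   `async_ids`, and `config`.
#' @examples
#' islet <- generate_islet(islet_sim_config(n_cells = 30, duration_s = 120,
#'                                          seed = 7))
#' islet
#' @export
generate_islet <- function(cfg) {
  stopifnot(inherits(cfg, "islet_sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_cells
    coords <- place_cells(n, cfg$disc_radius_um, cfg$min_spacing_um)
    cell_ids <- sprintf("cell_%03d", seq_len(n))
    rownames(coords) <- cell_ids
    radial <- sqrt(coords$x_um^2 + coords$y_um^2)
    # initiators from the outer 20% radial band (outermost cells if sparse)
    band <- which(radial >= 0.8 * cfg$disc_radius_um)
    if (length(band) < cfg$n_initiators)
      band <- order(radial, decreasing = TRUE)[seq_len(max(cfg$n_initiators,
                                                           3L))]
    initiators <- sort(sample(band, cfg$n_initiators))
    async <- integer(0)
    if (cfg$n_async_cells > 0)
      async <- sort(sample(setdiff(seq_len(n), initiators),
                           cfg$n_async_cells))
    duty <- pmin(pmax(stats::rnorm(n, cfg$duty_mean, cfg$duty_sd), 0.05),
                 0.9)
    n_frames <- as.integer(round(cfg$fs * cfg$duration_s))
    dmat <- as.matrix(stats::dist(coords))
    # burst schedule with jitter; initiators rotate across bursts
    n_bursts <- floor(cfg$duration_s / cfg$fast_period_s)
    t_burst <- (seq_len(n_bursts) - 1) * cfg$fast_period_s +
      cfg$fast_period_s / 2 +
      stats::rnorm(n_bursts, 0, cfg$burst_jitter_frac * cfg$fast_period_s)
    burst_init <- initiators[(seq_len(n_bursts) - 1) %% length(initiators) +
                               1]
    events <- matrix(0L, n_frames, n, dimnames = list(NULL, cell_ids))
    sync_cells <- setdiff(seq_len(n), async)
    for (b in seq_len(n_bursts)) {
      delays <- dmat[, burst_init[b]] / cfg$wave_speed_um_per_s
      on_t <- t_burst[b] + delays
      off_t <- on_t + duty * cfg$fast_period_s
      for (cc in sync_cells) {
        i0 <- max(1L, as.integer(round(on_t[cc] * cfg$fs)) + 1L)
        i1 <- min(n_frames, as.integer(round(off_t[cc] * cfg$fs)))
        if (i0 <= i1) events[i0:i1, cc] <- 1L
      }
    }
    # async contaminants: independent event times, same duty statistics
    for (cc in async) {
      starts <- sort(stats::runif(n_bursts, 0, cfg$duration_s))
      for (s in starts) {
        i0 <- max(1L, as.integer(round(s * cfg$fs)) + 1L)
        i1 <- min(n_frames,
                  as.integer(round((s + duty[cc] * cfg$fast_period_s) *
                                     cfg$fs)))
        if (i0 <= i1) events[i0:i1, cc] <- 1L
      }
    }
    # slow component: smooth spatial phase field + per-cell jitter
    z <- stats::rnorm(n)
    w <- exp(-dmat^2 / (2 * cfg$slow_phase_corr_len_um^2))
    phase <- as.numeric(w %*% z)
    phase <- phase - mean(phase)
    if (stats::sd(phase) > 0)
      phase <- phase * cfg$slow_phase_sd / stats::sd(phase)
    phase <- phase + stats::rnorm(n, 0, cfg$slow_phase_jitter_sd)
    if (length(async) > 0)
      phase[async] <- stats::runif(length(async), -pi, pi)
    slow_amp <- pmax(stats::rnorm(n, 1, 0.2), 0.2)
    tvec <- (seq_len(n_frames) - 1) / cfg$fs
    slow <- sin(outer(2 * pi * tvec / cfg$slow_period_s, phase, "+"))
    slow <- sweep(slow, 2, slow_amp, "*")
    if (cfg$slow_drift_frac > 0) {
      # cell-intrinsic irregular slow drift: white noise through a
      # second-order low-pass so its power stays below the fast band
      a_dr <- exp(-6 / (cfg$fs * cfg$slow_period_s))
      drift <- apply(matrix(stats::rnorm(n_frames * n), n_frames, n), 2,
                     function(x) {
                       y <- stats::filter(x, a_dr, method = "recursive")
                       stats::filter(y, a_dr, method = "recursive")
                     })
      drift <- scale(drift)  # unit variance per cell
      attributes(drift) <- list(dim = dim(drift))
      slow <- slow + cfg$slow_drift_frac * drift
    }
    # indicator kernel: first-order (exponential) response to the events
    a <- exp(-1 / (cfg$fs * cfg$kernel_tau_s))
    fast <- apply(events, 2, function(x)
      stats::filter((1 - a) * x, a, method = "recursive"))
    traces <- 1 + cfg$amp_fast * fast + cfg$amp_slow * slow +
      matrix(stats::rnorm(n_frames * n, 0, cfg$noise_sd), n_frames, n)
    rec <- calcium_recording(traces, cfg$fs, coords, cell_ids)
    structure(
      list(recording = rec, truth_events = events, truth_duty = duty,
           initiator_ids = cell_ids[initiators],
           async_ids = cell_ids[async], config = cfg),
      class = "synthetic_islet"
    )
  })
}

#' @export
print.synthetic_islet <- function(x, ...) {
  cat(sprintf("<synthetic_islet> %d cells, %.0f s at %g Hz, %d initiator(s), %d async cell(s)\n",
              length(x$recording$cell_ids),
              nrow(x$recording$traces) / x$recording$fs, x$recording$fs,
              length(x$initiator_ids), length(x$async_ids)))
  invisible(x)
}

#' Geometric structural network of a synthetic islet
#'
#' The ground-truth structural reference for a simulated islet: the
#' geometric network on the simulated coordinates (see
#' [geometric_network()]), by default thresholded to an average degree of 8
#' to match the functional networks.
#'
#' @param islet a [generate_islet()] result.
#' @param target_kavg target average degree.
#' @return A [functional_network()].
#' @export
reference_geometric_truth <- function(islet, target_kavg = 8) {
  stopifnot(inherits(islet, "synthetic_islet"))
  geometric_network(islet$recording$coords, mode = "target_kavg",
                    value = target_kavg,
                    cell_ids = islet$recording$cell_ids)
}

#' Write a synthetic islet to the pipeline's file formats
#'
#' Writes the recording and coordinates as CSV (the same formats
#' [read_recording_csv()] reads), the ground-truth event matrix and duty
#' cycles as CSV, and the configuration as YAML.
#'
#' @param islet a [generate_islet()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_islet <- function(islet, dir) {
  stopifnot(inherits(islet, "synthetic_islet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_recording_csv(islet$recording, file.path(dir, "traces.csv"),
                      file.path(dir, "coords.csv"))
  utils::write.csv(as.data.frame(islet$truth_events),
                   file.path(dir, "truth_events.csv"), row.names = FALSE)
  utils::write.csv(data.frame(cell_id = islet$recording$cell_ids,
                              duty = islet$truth_duty,
                              initiator = islet$recording$cell_ids %in%
                                islet$initiator_ids,
                              async = islet$recording$cell_ids %in%
                                islet$async_ids),
                   file.path(dir, "truth_cells.csv"), row.names = FALSE)
  cfg <- islet$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
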