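# Preprocessing: uniform resampling, zero-phase filtering, cycle segmentation.

#' Default filtering configuration
#'
#' Butterworth low-pass settings per channel class. The hardware's
#' per-sensor filter table is not published, so these are package defaults,
#' fully configurable and echoed into the provenance of every downstream
#' result. Angle and position channels use a 50 Hz cutoff: the gait-event
#' detectors threshold the angle *gradient*, and a lower cutoff (e.g. 20 Hz)
#' smears the touch-down transient over more than 2 percent of a 1 s gait
#' cycle, degrading event localisation well below the repeatability the
#' hardware achieves. Currents carry mostly sub-10 Hz power content.
#'
#' @param rate sampling rate of the uniform grid, Hz.
#' @param order filter order (of the one-pass prototype).
#' @param cutoff_angles,cutoff_currents cutoffs in Hz for angle/position
#'   channels and for current channels.
#' @return named list with per-channel `order` and `cutoff`.
#' @export
default_filtering <- function(rate = 1000, order = 2,
                              cutoff_angles = 50, cutoff_currents = 10) {
  ang <- c("hip_L", "hip_R", "knee_L", "knee_R", "ankle_L", "ankle_R",
           "slider_x", "fourbar")
  cur <- c("I_hip_L", "I_hip_R", "I_knee_L", "I_knee_R")
  cutoffs <- c(stats::setNames(rep(cutoff_angles, length(ang)), ang),
               stats::setNames(rep(cutoff_currents, length(cur)), cur))
  list(rate = rate, order = order, cutoff = cutoffs)
}

#' Resample a non-uniform log onto a uniform grid
#'
#' Linear interpolation of every channel onto a uniform grid at `rate` Hz
#' spanning the recorded time range. No extrapolation beyond the endpoints.
#'
#' @param log a [gait_log()].
#' @param rate target rate, Hz (default 1000).
#' @return a `gait_log` on a uniform grid, with `metadata$uniform_rate` set.
#' @export
resample_uniform <- function(log, rate = 1000) {
  stopifnot(inherits(log, "gait_log"), rate > 0)
  ts <- log$timestamps
  if (length(ts) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(diff(ts) == 0)) stop("duplicate timestamps in log", call. = FALSE)
  grid <- seq(ts[1], ts[length(ts)], by = 1 / rate)
  ch <- lapply(log$channels, function(x) {
    approx(ts, x, xout = grid, method = "linear", rule = 1)$y
  })
  md <- log$metadata
  md$uniform_rate <- rate
  gait_log(grid, ch, md)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Designs a Butterworth low-pass of the given order (via
#' [signal::butter()], realised in second-order sections) and applies it
#' forward and backward, so the effective magnitude response is the squared
#' single-pass response and the phase shift is zero. Edge artifacts are
#' suppressed by even-reflection padding of six characteristic lengths
#' (`6 * rate / cutoff` samples) before filtering, enough for the start-up
#' transient to settle below 1e-9; the padding is discarded afterwards.
#'
#' @param series numeric vector of uniform samples.
#' @param rate sampling rate, Hz.
#' @param order filter order (>= 1).
#' @param cutoff -3 dB cutoff of the one-pass prototype, Hz; must be below
#'   the Nyquist frequency.
#' @return filtered numeric vector, same length as `series`.
#' @export
lowpass_zero_phase <- function(series, rate, order = 2, cutoff = 50) {
  stopifnot(is.numeric(series), rate > 0, order >= 1)
  if (!(cutoff > 0 && cutoff < rate / 2)) {
    stop("cutoff must lie strictly between 0 and the Nyquist frequency",
         call. = FALSE)
  }
  n <- length(series)
  npad <- min(n - 1, max(3 * order, ceiling(6 * rate / cutoff)))
  if (n <= npad || n < 3 * (order + 1)) {
    stop("series too short for the filter's padding requirement", call. = FALSE)
  }
  bf <- signal::butter(order, 2 * cutoff / rate, type = "low")
  # even reflection about the first/last sample
  pre <- 2 * series[1] - series[(npad + 1):2]
  post <- 2 * series[n] - series[(n - 1):(n - npad)]
  x <- c(pre, series, post)
  y <- signal::filter(bf, x)
  y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
  y[(npad + 1):(npad + n)]
}

#' Apply the per-channel filter configuration to a uniform log
#'
#' @param ulog uniform `gait_log` (see [resample_uniform()]).
#' @param filtering list as returned by [default_filtering()].
#' @return filtered `gait_log`; filter settings recorded in
#'   `metadata$filtering`.
#' @export
filter_log <- function(ulog, filtering = default_filtering()) {
  stopifnot(inherits(ulog, "gait_log"))
  rate <- ulog$metadata$uniform_rate
  if (is.null(rate)) stop("log is not uniformly resampled", call. = FALSE)
  ch <- ulog$channels
  for (nm in names(ch)) {
    co <- filtering$cutoff[[nm]]
    if (is.null(co) || is.na(co)) next
    ch[[nm]] <- lowpass_zero_phase(ch[[nm]], rate, filtering$order, co)
  }
  md <- ulog$metadata
  md$filtering <- filtering
  gait_log(ulog$timestamps, ch, md)
}

#' Detect touch-downs from the swing plateau of an ankle trace
#'
#' Touch-down is the moment the ankle angle starts to change after its
#' approximately constant value during swing. A plateau qualifies when the
#' absolute angle gradient stays below the quiescence threshold for at least
#' the dwell time; the touch-down is the first subsequent sample whose
#' absolute gradient exceeds the activity threshold.
#'
#' @param ankle_angle filtered ankle angle, rad, on a uniform grid.
#' @param rate sampling rate, Hz.
#' @param activity_threshold gradient magnitude marking activity, rad/s.
#' @param quiescence_threshold gradient magnitude bounding the plateau,
#'   rad/s.
#' @param dwell minimum plateau duration, s.
#' @return numeric vector of touch-down times in seconds (relative to the
#'   first sample).
#' @export
detect_touchdowns <- function(ankle_angle, rate,
                              activity_threshold = 1,
                              quiescence_threshold = 0.2,
                              dwell = 0.1) {
  stopifnot(is.numeric(ankle_angle), rate > 0)
  g <- time_gradient(ankle_angle, rate)
  quiet <- abs(g) < quiescence_threshold
  need <- max(2L, as.integer(round(dwell * rate)))
  # run-length scan: inside a qualifying plateau once `need` quiet samples
  # have accrued; fire on the first active sample after that
  n <- length(g)
  run <- 0L
  armed <- FALSE
  hits <- integer(0)
  for (i in seq_len(n)) {
    if (quiet[i]) {
      run <- run + 1L
      if (run >= need) armed <- TRUE
    } else {
      run <- 0L
      if (armed && abs(g[i]) > activity_threshold) {
        hits <- c(hits, i)
        armed <- FALSE
      }
    }
  }
  if (!length(hits)) {
    stop("no departure from a swing plateau found in the ankle channel",
         call. = FALSE)
  }
  (hits - 1L) / rate
}

#' Segment a uniform log into gait cycles and ensemble-average
#'
#' Splits the log at the given cycle boundaries, keeps the first `n_keep`
#' complete cycles, resamples each onto a common percent-GC grid and
#' computes per-channel ensemble means and standard deviations.
#'
#' @param ulog filtered uniform `gait_log`.
#' @param boundaries touch-down times in seconds (see
#'   [detect_touchdowns()]).
#' @param n_keep number of cycles to keep (default 120).
#' @param n_grid number of points of the percent-GC grid (default 1000).
#' @return object of class `cycle_ensemble`: list with `pct` (the grid),
#'   `cycles` (list per channel of n_keep x n_grid matrices), `mean`, `sd`,
#'   `periods` (s), `starts` (s) and `provenance`.
#' @export
segment_cycles <- function(ulog, boundaries, n_keep = 120, n_grid = 1000) {
  stopifnot(inherits(ulog, "gait_log"))
  rate <- ulog$metadata$uniform_rate
  if (is.null(rate)) stop("log is not uniformly resampled", call. = FALSE)
  if (length(boundaries) < n_keep + 1) {
    stop(sprintf("requested %d cycles but only %d are available",
                 n_keep, max(0, length(boundaries) - 1)), call. = FALSE)
  }
  t0 <- ulog$timestamps[1]
  ts <- ulog$timestamps - t0
  pct <- seq(0, 100, length.out = n_grid + 1)[1:n_grid]
  starts <- boundaries[seq_len(n_keep)]
  ends <- boundaries[seq_len(n_keep) + 1]
  periods <- ends - starts
  cyc <- lapply(ulog$channels, function(x) {
    m <- matrix(NA_real_, n_keep, n_grid)
    for (k in seq_len(n_keep)) {
      tt <- starts[k] + pct / 100 * periods[k]
      m[k, ] <- approx(ts, x, xout = tt, rule = 2)$y
    }
    m
  })
  ens_mean <- lapply(cyc, colMeans)
  ens_sd <- lapply(cyc, function(m) apply(m, 2, sd))
  structure(list(
    pct = pct, cycles = cyc, mean = ens_mean, sd = ens_sd,
    periods = periods, starts = starts,
    provenance = list(rate = rate, n_keep = n_keep, n_grid = n_grid,
                      filtering = ulog$metadata$filtering,
                      condition = ulog$metadata$condition)
  ), class = "cycle_ensemble")
}

#' @export
print.cycle_ensemble <- function(x, ...) {
  cat(sprintf("<cycle_ensemble> %d cycles, %d-point %%GC grid, mean period %.3f s\n",
              length(x$periods), length(x$pct), mean(x$periods)))
  invisible(x)
}
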