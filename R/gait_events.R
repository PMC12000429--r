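# Kinematic gait-event detectors operating on cycle-segmented angle traces.
#
# All detectors take a single cycle's trace on the common percent-GC grid
# together with the cycle period, threshold *gradients* in rad/s, and return
# event times in percent GC. Ties and threshold crossings are resolved
# deterministically: crossing = first strict inequality, ties -> earliest
# sample.

#' Time gradient by central differences
#'
#' Central differences in the interior, one-sided differences at the edges.
#' Exact for affine signals.
#'
#' @param series numeric vector of uniform samples.
#' @param rate sampling rate, Hz (samples per second).
#' @return numeric vector of the same length, units/s.
#' @export
time_gradient <- function(series, rate) {
  n <- length(series)
  if (n < 3) stop("need at least 3 samples for a gradient", call. = FALSE)
  g <- numeric(n)
  g[1] <- (series[2] - series[1]) * rate
  g[n] <- (series[n] - series[n - 1]) * rate
  g[2:(n - 1)] <- (series[3:n] - series[1:(n - 2)]) * rate / 2
  g
}

.pct_to_idx <- function(pct_grid, p) {
  # last grid index at or before p (grid is uniform starting at 0)
  step <- pct_grid[2] - pct_grid[1]
  min(length(pct_grid), max(1L, 1L + as.integer(floor(p / step + 1e-9))))
}

#' Detect the start of ankle plantarflexion (SAPF)
#'
#' The trailing ankle steadily dorsiflexes through stance and reverses into
#' plantarflexion at push-off; in the dorsiflexion-positive convention the
#' event is the stance-phase maximum of the ankle angle. The search is
#' restricted to a stance window to avoid touch-down transients. Plateau
#' maxima are resolved to the earliest sample.
#'
#' @param trailing_ankle one cycle of the trailing ankle angle, rad, on the
#'   percent-GC grid.
#' @param pct_grid the percent-GC grid.
#' @param stance_window search window in percent GC, default `c(10, 90)`.
#' @return t_SAPF in percent GC.
#' @export
detect_sapf <- function(trailing_ankle, pct_grid, stance_window = c(10, 90)) {
  sel <- which(pct_grid >= stance_window[1] & pct_grid <= stance_window[2])
  win <- trailing_ankle[sel]
  imax <- sel[which.max(win)]
  # a maximum on the window edge means the trace is monotone there
  if (imax == sel[1] || imax == sel[length(sel)]) {
    stop("no dorsiflexion reversal found in the stance window", call. = FALSE)
  }
  pct_grid[imax]
}

#' Detect toe-off (TO)
#'
#' Locates the most negative ankle-angle gradient after SAPF, then returns
#' the time of the minimum ankle angle within the following 40 ms window
#' (truncated at the cycle end). Equal minima resolve to the earliest
#' sample.
#'
#' @param trailing_ankle one cycle of the trailing ankle angle, rad.
#' @param pct_grid percent-GC grid.
#' @param period cycle period, s.
#' @param t_sapf SAPF time, percent GC.
#' @param window length of the search window after the gradient peak, s.
#' @return t_TO in percent GC.
#' @export
detect_to <- function(trailing_ankle, pct_grid, period, t_sapf,
                      window = 0.040) {
  rate <- length(pct_grid) / period
  g <- time_gradient(trailing_ankle, rate)
  i0 <- .pct_to_idx(pct_grid, t_sapf)
  after <- i0:length(pct_grid)
  gmin <- min(g[after])
  if (gmin >= 0) {
    stop("no negative ankle-gradient peak after SAPF", call. = FALSE)
  }
  ipk <- after[which.min(g[after])]
  nwin <- as.integer(round(window * rate))
  iend <- min(length(pct_grid), ipk + nwin)
  seg <- trailing_ankle[ipk:iend]
  imin <- ipk + which.min(seg) - 1L
  pct_grid[imin]
}

#' Detect leading-leg touch-down (LLTD)
#'
#' The leading ankle is approximately constant during its swing; contact
#' shows as a burst of ankle-angle activity. Scanning backward from TO, the
#' event is the last sample whose absolute instantaneous gradient exceeds
#' the threshold (printed default 1 rad/s).
#'
#' @param leading_ankle one cycle of the contralateral ankle angle, rad, on
#'   the trailing leg's cycle clock.
#' @param pct_grid percent-GC grid.
#' @param period cycle period, s.
#' @param t_to toe-off time of the trailing leg, percent GC.
#' @param threshold gradient threshold, rad/s.
#' @return t_LLTD in percent GC.
#' @export
detect_lltd <- function(leading_ankle, pct_grid, period, t_to, threshold = 1) {
  rate <- length(pct_grid) / period
  g <- time_gradient(leading_ankle, rate)
  iend <- .pct_to_idx(pct_grid, t_to)
  hits <- which(abs(g[1:iend]) > threshold)
  if (!length(hits)) {
    stop("no ankle-gradient crossing before TO on the leading leg",
         call. = FALSE)
  }
  pct_grid[hits[length(hits)]]
}

#' Detect the start of hip flexion (SHF)
#'
#' First crossing of the hip angle gradient above `+threshold`, searching
#' from the moment of peak hip extension (the hip angle minimum in the
#' flexion-positive convention) to the cycle end.
#'
#' @param hip one cycle of the hip angle, rad.
#' @param pct_grid percent-GC grid.
#' @param period cycle period, s.
#' @param threshold gradient threshold, rad/s.
#' @return t_SHF in percent GC.
#' @export
detect_shf <- function(hip, pct_grid, period, threshold = 1) {
  rate <- length(pct_grid) / period
  g <- time_gradient(hip, rate)
  ipk <- which.min(hip)
  hits <- which(g[ipk:length(pct_grid)] > threshold)
  if (!length(hits)) {
    stop("no hip-gradient crossing after peak hip extension", call. = FALSE)
  }
  pct_grid[ipk + hits[1] - 1L]
}

#' Detect the start of knee flexion (SKF)
#'
#' First sample with knee gradient above `+threshold` inside the window
#' from 0.2 s before to 0.1 s after SHF (clamped to the cycle).
#'
#' @param knee one cycle of the knee angle, rad.
#' @param pct_grid percent-GC grid.
#' @param period cycle period, s.
#' @param t_shf SHF time, percent GC.
#' @param threshold gradient threshold, rad/s.
#' @param before,after window extent around SHF, s.
#' @return t_SKF in percent GC.
#' @export
detect_skf <- function(knee, pct_grid, period, t_shf, threshold = 1,
                       before = 0.2, after = 0.1) {
  rate <- length(pct_grid) / period
  g <- time_gradient(knee, rate)
  ic <- .pct_to_idx(pct_grid, t_shf)
  i1 <- max(1L, ic - as.integer(round(before * rate)))
  i2 <- min(length(pct_grid), ic + as.integer(round(after * rate)))
  hits <- which(g[i1:i2] > threshold)
  if (!length(hits)) {
    stop("no knee-gradient crossing in the SKF search window", call. = FALSE)
  }
  pct_grid[i1 + hits[1] - 1L]
}

#' Extract all gait events from a cycle ensemble
#'
#' Runs the five detectors (SAPF, TO, LLTD, SHF, SKF) on every cycle of a
#' [segment_cycles()] ensemble, using the reference (trailing) leg's hip,
#' knee and ankle channels and the contralateral ankle on the same cycle
#' clock. Cycles where any detector fails are reported and excluded from
#' the summary, never silently dropped.
#'
#' @param ensemble a `cycle_ensemble`.
#' @param trailing_side `"L"` or `"R"`: which leg's touch-down starts the
#'   cycle.
#' @param threshold gradient threshold shared by the LLTD/SHF/SKF detectors,
#'   rad/s.
#' @param stance_window SAPF search window, percent GC.
#' @param max_failure_fraction abort if more than this fraction of cycles
#'   fails any detector.
#' @return object of class `gait_events`: list with `per_cycle` (data.frame:
#'   cycle, t_SKF, t_SHF, t_SAPF, t_LLTD, t_TO, delta_SAPF_LLTD, all percent
#'   GC), `summary` (mean/SD per event), `excluded` (integer cycle indices)
#'   and `failures` (messages per excluded cycle).
#' @export
extract_events <- function(ensemble, trailing_side = c("L", "R"),
                           threshold = 1, stance_window = c(10, 90),
                           max_failure_fraction = 0.1) {
  stopifnot(inherits(ensemble, "cycle_ensemble"))
  trailing_side <- match.arg(trailing_side)
  leading_side <- if (trailing_side == "L") "R" else "L"
  pct <- ensemble$pct
  nC <- length(ensemble$periods)
  ankle_t <- ensemble$cycles[[paste0("ankle_", trailing_side)]]
  ankle_l <- ensemble$cycles[[paste0("ankle_", leading_side)]]
  hip_t <- ensemble$cycles[[paste0("hip_", trailing_side)]]
  knee_t <- ensemble$cycles[[paste0("knee_", trailing_side)]]

  out <- data.frame(cycle = seq_len(nC), t_SKF = NA_real_, t_SHF = NA_real_,
                    t_SAPF = NA_real_, t_LLTD = NA_real_, t_TO = NA_real_)
  failures <- character(0)
  excluded <- integer(0)
  for (k in seq_len(nC)) {
    res <- tryCatch({
      per <- ensemble$periods[k]
      sapf <- detect_sapf(ankle_t[k, ], pct, stance_window)
      to <- detect_to(ankle_t[k, ], pct, per, sapf)
      lltd <- detect_lltd(ankle_l[k, ], pct, per, to, threshold)
      shf <- detect_shf(hip_t[k, ], pct, per, threshold)
      skf <- detect_skf(knee_t[k, ], pct, per, shf, threshold)
      c(skf, shf, sapf, lltd, to)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded <- c(excluded, k)
      failures <- c(failures, sprintf("cycle %d: %s", k, conditionMessage(res)))
    } else {
      out[k, 2:6] <- res
    }
  }
  if (length(excluded) > max_failure_fraction * nC) {
    stop(sprintf("event detection failed on %d of %d cycles:\n%s",
                 length(excluded), nC,
                 paste(head(failures, 5), collapse = "\n")), call. = FALSE)
  }
  out$delta_SAPF_LLTD <- out$t_SAPF - out$t_LLTD
  ok <- setdiff(seq_len(nC), excluded)
  ev_cols <- c("t_SKF", "t_SHF", "t_SAPF", "t_LLTD", "t_TO", "delta_SAPF_LLTD")
  summary <- data.frame(
    event = ev_cols,
    mean = vapply(ev_cols, function(cn) mean(out[[cn]][ok]), 1),
    sd = vapply(ev_cols, function(cn) sd(out[[cn]][ok]), 1),
    row.names = NULL
  )
  structure(list(per_cycle = out, summary = summary,
                 excluded = excluded, failures = failures,
                 trailing_side = trailing_side,
                 provenance = c(ensemble$provenance,
                                list(threshold = threshold,
                                     stance_window = stance_window))),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d cycles (%d excluded)\n",
              nrow(x$per_cycle), length(x$excluded)))
  print(transform(x$summary, mean = round(mean, 2), sd = round(sd, 3)))
  invisible(x)
}
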