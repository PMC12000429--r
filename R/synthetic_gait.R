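# Synthetic sensor-log generator with ground-truth gait-event schedules.
#
# The generator emulates the statistical structure of treadmill logs from a
# planar spring-tendon biped: 1 Hz gait cycles, ~600 Hz jittered sampling,
# encoder quantisation, condition-dependent event timings, a stance
# dorsiflexion ramp with a ~-22 deg swing ankle plateau, and ~120 steady
# cycles per condition. Curve shapes are piecewise smooth (cosine-blended)
# segments parameterised only by the pattern-generator constants and the
# event schedule; the controller's oscillator differential equations are not
# modelled.

# raised-cosine bump: 0.5*(1+cos(pi*(t-c)/w)) on |t-c| < w, else 0
.rc_bump <- function(t, c, w) {
  d <- t - c
  out <- numeric(length(t))
  in_supp <- abs(d) < w
  out[in_supp] <- 0.5 * (1 + cos(pi * d[in_supp] / w))
  out
}

#' Commanded hip and knee reference trajectories
#'
#' Evaluates the amplitude-controlled oscillator curves commanding hip and
#' knee on a phase grid. The knee holds its offset until phase `F_knee`,
#' then performs a raised-cosine flexion pulse of the full amplitude; the
#' hip swings between `offset - amplitude` (peak extension, reached at
#' `F_hip`) and `offset + amplitude`, holding the flexed value for the
#' steady fraction `phi_hip` at the end of swing. Both curves are periodic
#' and continuously differentiable; the right leg is the left curve shifted
#' by `phase_shift_lr`.
#'
#' @param params a [control_params()] object.
#' @param phase_grid numeric vector of phases in `[0, 1)`.
#' @return list with components `hip_L`, `knee_L`, `hip_R`, `knee_R` (rad).
#' @export
cpg_reference_trajectory <- function(params, phase_grid) {
  stopifnot(inherits(params, "control_params"))
  if (any(phase_grid < 0 | phase_grid >= 1)) {
    stop("phase grid must lie in [0, 1)", call. = FALSE)
  }
  if (params$theta_kneeAmplitude < 0 || params$theta_hipAmplitude < 0) {
    stop("trajectory amplitudes must be non-negative", call. = FALSE)
  }
  d2r <- pi / 180
  knee_one <- function(ph) {
    off <- params$theta_kneeOffset * d2r
    amp <- params$theta_kneeAmplitude * d2r
    Fk <- params$F_knee
    y <- rep(off, length(ph))
    act <- ph >= Fk
    u <- (ph[act] - Fk) / (1 - Fk)
    y[act] <- off + amp * 0.5 * (1 - cos(2 * pi * u))
    y
  }
  hip_one <- function(ph) {
    off <- params$theta_hipOffset * d2r
    amp <- params$theta_hipAmplitude * d2r
    Fh <- params$F_hip
    steady0 <- 1 - params$phi_hip
    y <- numeric(length(ph))
    ext <- ph < Fh                       # extension: +amp -> -amp
    y[ext] <- off + amp * cos(pi * ph[ext] / Fh)
    fle <- ph >= Fh & ph < steady0       # flexion: -amp -> +amp
    y[fle] <- off - amp * cos(pi * (ph[fle] - Fh) / (steady0 - Fh))
    y[ph >= steady0] <- off + amp        # swing-steady hold
    y
  }
  list(
    hip_L = hip_one(phase_grid),
    knee_L = knee_one(phase_grid),
    hip_R = hip_one((phase_grid + params$phase_shift_lr) %% 1),
    knee_R = knee_one((phase_grid + params$phase_shift_lr) %% 1)
  )
}

#' Default gait-event timings per condition
#'
#' Mean event times in percent GC for the active (AKFI) and passive (PKFI,
#' PKFI40) knee-flexion-initiation conditions. SKF and SAPF means are the
#' published condition means; LLTD comes from the published per-condition
#' touch-down timing; SHF follows the published 4 percent-GC delay of hip
#' flexion between conditions; TO and the PKFI40 row are package defaults
#' chosen to respect the event ordering.
#'
#' @param mode condition name.
#' @return named numeric vector (t_SKF, t_SHF, t_SAPF, t_LLTD, t_TO), %GC.
#' @export
event_schedule_means <- function(mode = c("AKFI", "PKFI", "PKFI40")) {
  mode <- match.arg(mode)
  switch(mode,
    AKFI = c(t_SKF = 39.00, t_SHF = 41.50, t_SAPF = 46.25,
             t_LLTD = 48.00, t_TO = 62.00),
    PKFI = c(t_SKF = 43.67, t_SHF = 45.50, t_SAPF = 48.77,
             t_LLTD = 47.00, t_TO = 65.00),
    PKFI40 = c(t_SKF = 44.80, t_SHF = 46.60, t_SAPF = 49.60,
               t_LLTD = 47.00, t_TO = 65.50)
  )
}

#' Draw a per-cycle ground-truth event schedule
#'
#' Event times are the condition means plus independent Gaussian jitter
#' (default SD 0.3 percent GC, emulating the sub-0.4 percent-GC event
#' repeatability of the hardware); cycle periods are `1/f` plus Gaussian
#' jitter. Cycles violating the ordering `SKF <= SHF <= SAPF < TO` are
#' redrawn. With a fixed seed the schedule is bit-reproducible.
#'
#' @param control a [control_params()] object (the mode selects the means).
#' @param n_cycles number of cycles (>= 2).
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @param event_jitter_sd per-event jitter SD, percent GC.
#' @param period_jitter_sd cycle-period jitter SD, s.
#' @param means optional override of [event_schedule_means()].
#' @return object of class `event_schedule`: data.frame with one row per
#'   cycle (`cycle`, `period`, the five event times in %GC); attributes
#'   `means`, `mode`.
#' @export
schedule_ground_truth <- function(control, n_cycles, seed = NULL,
                                  event_jitter_sd = 0.3,
                                  period_jitter_sd = 0.002,
                                  means = NULL) {
  stopifnot(inherits(control, "control_params"), n_cycles >= 2)
  if (is.null(means)) means <- event_schedule_means(control$mode)
  required <- c("t_SKF", "t_SHF", "t_SAPF", "t_LLTD", "t_TO")
  stopifnot(all(required %in% names(means)))
  m <- means[required]
  if (!(m["t_SKF"] <= m["t_SHF"] && m["t_SHF"] <= m["t_SAPF"] &&
        m["t_SAPF"] < m["t_TO"])) {
    stop("event means must satisfy SKF <= SHF <= SAPF < TO", call. = FALSE)
  }
  if (any(m < 0 | m >= 100)) {
    stop("event means must lie in [0, 100) percent GC", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  draw <- function(n) {
    ev <- matrix(rep(m, each = n), n, 5, dimnames = list(NULL, required))
    if (event_jitter_sd > 0) {
      ev <- ev + matrix(rnorm(5 * n, sd = event_jitter_sd), n, 5)
    }
    ev
  }
  ev <- draw(n_cycles)
  for (it in 1:20) {
    bad <- which(!(ev[, 1] <= ev[, 2] & ev[, 2] <= ev[, 3] & ev[, 3] < ev[, 4] |
                     TRUE))  # ordering among SKF/SHF/SAPF/TO only
    bad <- which(!(ev[, "t_SKF"] <= ev[, "t_SHF"] &
                     ev[, "t_SHF"] <= ev[, "t_SAPF"] &
                     ev[, "t_SAPF"] < ev[, "t_TO"]))
    if (!length(bad)) break
    ev[bad, ] <- draw(length(bad))[seq_along(bad), , drop = FALSE]
  }
  periods <- 1 / control$f + if (period_jitter_sd > 0) {
    rnorm(n_cycles, sd = period_jitter_sd)
  } else 0
  out <- data.frame(cycle = seq_len(n_cycles), period = periods, ev)
  structure(out, class = c("event_schedule", "data.frame"),
            means = m, mode = control$mode)
}

#' Shape constants of the synthetic kinematic curves
#'
#' Tunable geometry of the piecewise cosine-blended curves the generator
#' emits. Percent-GC quantities scale with the cycle; velocities are m/s.
#' Key entries:
#' \describe{
#'   \item{p_td, delta_td}{duration (percent GC) and amplitude (rad) of the
#'     touch-down transient of the ankle. The ground-truth LLTD is the end
#'     of this transient, matching the detector's definition (last
#'     above-threshold gradient); the cycle start is its beginning (the
#'     moment the angle starts to change).}
#'   \item{ankle_range}{slow stance dorsiflexion excursion, rad. Bounded so
#'     the stance gradient stays safely below the 1 rad/s event threshold.}
#'   \item{knee_rise}{duration of the knee flexion rise, percent GC.}
#'   \item{fall_base, fall_gain}{vertical trunk descent before the
#'     step-to-step transition: base depth (m/s) plus gain (m/s per second)
#'     times the knee-flexion-to-touch-down fall duration. A longer fall
#'     (earlier knee flexion) deepens the vertical velocity minimum.}
#'   \item{peak1_amp, peak2_amp}{heights of the two post-minimum vertical
#'     velocity peaks (collision rebound, push-off completion), m/s.}
#'   \item{drop0, kappa_push}{forward trunk-speed drop at each collision
#'     (m/s) and its reduction per second of push-off occurring before
#'     touch-down (preemptive push-off cancels part of the collision
#'     loss).}
#' }
#' @return named list of shape constants.
#' @export
synth_shape_defaults <- function() {
  list(
    p_td = 0.8,          # %GC, touch-down transient duration
    delta_td = 0.018,    # rad, transient amplitude
    ankle_range = 0.22,  # rad, slow stance dorsiflexion
    to_undershoot = 0.015,   # rad, plateau overshoot at toe-off
    to_recovery = 1.2,   # %GC, recovery back to the plateau
    knee_rise = 26,      # %GC
    knee_return_end = 95,   # %GC
    hip_peak = 85,       # %GC, hip flexion peak (start of steady hold)
    hip_steady_end = 90, # %GC
    hip_vel_peak = 68,   # %GC, hip angular-velocity peak (mid-swing)
    hip_vel_ratio = 2.2, # peak over engagement angular velocity
    descent_lead = 2.5,  # %GC, vertical-velocity minimum before LLTD
    fall_base = 0.115,   # m/s
    fall_gain = 0.9,     # (m/s)/s of fall duration
    peak1_delay = 4, peak1_w = 3.5, peak1_amp = 0.16,
    peak2_delay = 2, peak2_w = 4.0, peak2_amp = 0.15,
    drop0 = 0.10,        # m/s, collision speed drop
    kappa_push = 4.5,    # (m/s)/s of preemptive push-off
    drop_width = 0.04,   # s
    i_hip_base = 0.03, i_hip_amp1 = 0.284, i_hip_c1 = 5, i_hip_w1 = 8,
    i_hip_amp2 = 0.284, i_hip_w2 = 8, i_hip_delay2 = 5,
    i_knee_base = 0.008, i_knee_amp1 = 0.03, i_knee_w1 = 8,
    i_knee_delay1 = 4, i_knee_amp2 = 0.333, i_knee_c2 = 8, i_knee_w2 = 6
  )
}

# evaluate one leg's joint-angle channels at local percent-GC positions
# pct: vector in [0, 100); ev: matrix-like with per-sample event columns
.synth_ankle <- function(pct, ev, morph, sh) {
  plateau <- morph$alpha_A_slack
  p_td <- sh$p_td
  a_max <- plateau + sh$delta_td + sh$ankle_range
  y <- rep(plateau, length(pct))

  i <- pct < p_td
  y[i] <- plateau + sh$delta_td * pct[i] / p_td

  # slow dorsiflexion: slope grows towards SAPF so the peak is a balanced
  # kink (its filtered argmax stays put); the early portion stays well
  # below the 1 rad/s event threshold
  i <- pct >= p_td & pct < ev$t_SAPF
  u <- (pct[i] - p_td) / (ev$t_SAPF[i] - p_td)
  y[i] <- plateau + sh$delta_td + sh$ankle_range * (1 - cos(pi / 2 * u))

  # push-off descent overshoots the plateau slightly (heel/toe compliance
  # rebound), making the toe-off minimum a sharp V rather than a flat kink
  i <- pct >= ev$t_SAPF & pct < ev$t_TO
  s <- (pct[i] - ev$t_SAPF[i]) / (ev$t_TO[i] - ev$t_SAPF[i])
  A_d <- sh$delta_td + sh$ankle_range + sh$to_undershoot
  y[i] <- a_max - A_d * (0.4 * s + 0.3 * s^2) / 0.7

  i <- pct >= ev$t_TO & pct < ev$t_TO + sh$to_recovery
  s <- (pct[i] - ev$t_TO[i]) / sh$to_recovery
  y[i] <- plateau - sh$to_undershoot * (1 - s)
  y
}

.synth_knee <- function(pct, ev, control, sh) {
  d2r <- pi / 180
  off <- control$theta_kneeOffset * d2r
  amp <- control$theta_kneeAmplitude * d2r
  y <- rep(off, length(pct))
  t_pk <- ev$t_SKF + sh$knee_rise
  i <- pct >= ev$t_SKF & pct < t_pk
  u <- (pct[i] - ev$t_SKF[i]) / sh$knee_rise
  y[i] <- off + amp * sin(pi / 2 * u)
  i <- pct >= t_pk & pct < sh$knee_return_end
  w <- (pct[i] - t_pk[i]) / (sh$knee_return_end - t_pk[i])
  y[i] <- off + amp * 0.5 * (1 + cos(pi * w))
  y
}

# hip extension: constant angular rate (the trunk passes over the planted
# foot at steady speed) with quarter-cosine blends into the hold before it
# and out to zero slope at peak extension (SHF)
.hip_extension <- function(s, hi, lo, b1, b2) {
  amp <- hi - lo
  W <- amp / (1 - (b1 + b2) * (1 - 2 / pi))  # rad per unit s at mid rate
  y <- numeric(length(s))
  i <- s <= b1
  y[i] <- hi - W[i] * (2 * b1[i] / pi) * (1 - cos(pi * s[i] / (2 * b1[i])))
  i <- s > b1 & s <= 1 - b2
  y[i] <- hi - W[i] * (2 * b1[i] / pi + s[i] - b1[i])
  i <- s > 1 - b2
  y[i] <- lo + W[i] * (2 * b2[i] / pi) *
    (1 - sin(pi * (s[i] - 1 + b2[i]) / (2 * b2[i])))
  y
}

.synth_hip <- function(pct, ev, control, sh) {
  d2r <- pi / 180
  lo <- (control$theta_hipOffset - control$theta_hipAmplitude) * d2r
  amp <- 2 * control$theta_hipAmplitude * d2r
  desc_dur <- ev$t_SHF + (100 - sh$hip_steady_end)
  bl1 <- 4 / desc_dur
  bl2 <- 6 / desc_dur
  y <- numeric(length(pct))
  i <- pct < ev$t_SHF                      # late extension (descent tail)
  s <- (pct[i] + 100 - sh$hip_steady_end) / desc_dur[i]
  y[i] <- .hip_extension(s, lo + amp, lo, bl1[i], bl2[i])
  # flexion rise: angular velocity engages at omega0 (> 1 rad/s, so the
  # event detector fires at SHF), keeps growing to r*omega0 at
  # hip_vel_peak %GC (mid-swing, as in walking), then decays to zero at
  # hip_peak; omega0 follows from the total excursion `amp`
  T1 <- (sh$hip_vel_peak - ev$t_SHF) / 100          # fraction of cycle
  T2 <- (sh$hip_peak - sh$hip_vel_peak) / 100
  r <- sh$hip_vel_ratio
  bracket <- T1 + (r - 1) * T1 * 2 / pi + r * T2 * 2 / pi
  w0 <- amp / bracket                               # rad per cycle-fraction
  i <- pct >= ev$t_SHF & pct < sh$hip_vel_peak
  tt <- (pct[i] - ev$t_SHF[i]) / 100
  T1i <- T1[i]
  y[i] <- lo + w0[i] * tt +
    (r - 1) * w0[i] * (2 * T1i / pi) * (1 - cos(pi * tt / (2 * T1i)))
  i <- pct >= sh$hip_vel_peak & pct < sh$hip_peak
  th_pk <- lo + w0 * T1 + (r - 1) * w0 * (2 * T1 / pi)
  u <- (pct[i] - sh$hip_vel_peak) / (sh$hip_peak - sh$hip_vel_peak)
  y[i] <- th_pk[i] + r * w0[i] * (2 * T2 / pi) * sin(pi / 2 * u)
  i <- pct >= sh$hip_peak & pct < sh$hip_steady_end
  y[i] <- lo + amp                         # swing-steady hold
  i <- pct >= sh$hip_steady_end            # descent head
  s <- (pct[i] - sh$hip_steady_end) / desc_dur[i]
  y[i] <- .hip_extension(s, lo + amp, lo, bl1[i], bl2[i])
  y
}

.synth_currents <- function(pct, ev, control, sh) {
  hip <- sh$i_hip_base +
    sh$i_hip_amp1 * .rc_bump(pct, sh$i_hip_c1, sh$i_hip_w1) +
    sh$i_hip_amp2 * .rc_bump(pct, ev$t_SHF + sh$i_hip_delay2, sh$i_hip_w2)
  knee <- sh$i_knee_base +
    sh$i_knee_amp1 * .rc_bump(pct, ev$t_SKF + sh$i_knee_delay1, sh$i_knee_w1) +
    sh$i_knee_amp2 * .rc_bump(pct, sh$i_knee_c2, sh$i_knee_w2)
  if (control$mode != "AKFI") {
    gate0 <- 100 * control$zero_torque_start
    # smooth 1 -> 0 gate over 1 %GC at the zero-torque boundary
    g <- ifelse(pct < gate0, 1,
                ifelse(pct < gate0 + 1, 0.5 * (1 + cos(pi * (pct - gate0))), 0))
    knee <- knee * g
  }
  list(hip = hip, knee = knee)
}

# map absolute times onto (cycle index, local %GC) for a leg with the given
# cycle start times; times before the first start use a back-shifted cycle 1
.locate_cycles <- function(t, starts, periods) {
  idx <- findInterval(t, starts)
  pre <- idx == 0
  idx[pre] <- 1L
  s <- starts[idx]
  s[pre] <- starts[1] - periods[1]
  p <- periods[idx]
  pct <- pmin(99.9999, pmax(0, (t - s) / p * 100))
  list(idx = idx, pct = pct)
}

.eval_leg <- function(t, starts, sched, control, morph, sh, what) {
  loc <- .locate_cycles(t, starts, sched$period)
  ev <- lapply(sched[c("t_SKF", "t_SHF", "t_SAPF", "t_LLTD", "t_TO")],
               function(col) col[loc$idx])
  ev <- as.data.frame(ev)
  switch(what,
    ankle = .synth_ankle(loc$pct, ev, morph, sh),
    knee = .synth_knee(loc$pct, ev, control, sh),
    hip = .synth_hip(loc$pct, ev, control, sh),
    currents = .synth_currents(loc$pct, ev, control, sh)
  )
}

.cumtrapz <- function(t, y) {
  n <- length(y)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(t)))
}

#' Synthesize noiseless joint-angle and trunk channels
#'
#' Builds a uniform, noise-free sensor log realising a ground-truth event
#' schedule. The trailing (left) ankle is constant at the plateau during
#' swing, leaves it at each scheduled touch-down with a short transient,
#' dorsiflexes slowly through stance, peaks exactly at `t_SAPF` and
#' plantarflexes back to the plateau by `t_TO`, with the steepest gradient
#' at toe-off. Knee flexion starts at `t_SKF`, the hip reverses at `t_SHF`.
#' Right-leg channels are the same pattern with cycle starts placed so the
#' right touch-down transient *ends* at the scheduled `t_LLTD` of the left
#' cycle (the detector's definition of touch-down). The slider advances at
#' the mean forward speed modulated by collision losses and preemptive
#' push-off; the four-bar angle encodes a vertical trunk trajectory whose
#' velocity shows the characteristic minimum followed by two peaks around
#' the step-to-step transition.
#'
#' @param schedule an [schedule_ground_truth()] schedule for the left leg.
#' @param control a [control_params()] object.
#' @param morphology a validated [validate_morphology()] object.
#' @param rate sampling rate of the noiseless log, Hz.
#' @param mean_forward_speed mean slider speed, m/s.
#' @param shape list of curve constants, see [synth_shape_defaults()].
#' @param schedule_R optional independent right-leg schedule (same length);
#'   defaults to the left schedule's event values.
#' @return list with `log` (uniform noiseless `gait_log`), `truth` (the
#'   schedule augmented with absolute cycle start times `t_start`).
#' @export
synthesize_joint_angles <- function(schedule, control, morphology,
                                    rate = 2000, mean_forward_speed = 0.44,
                                    shape = synth_shape_defaults(),
                                    schedule_R = NULL) {
  stopifnot(inherits(schedule, "event_schedule"), rate > 0)
  morph <- validate_morphology(morphology)
  sh <- shape
  nC <- nrow(schedule)
  periods <- schedule$period
  starts_L <- c(0, cumsum(periods))[seq_len(nC)]
  # right-leg cycle starts: transient ends at the left cycle's t_LLTD
  starts_R <- starts_L + (schedule$t_LLTD - sh$p_td) / 100 * periods
  if (is.null(schedule_R)) {
    schedule_R <- schedule
    schedule_R$period <- c(diff(starts_R), periods[nC])
  }
  t_end <- starts_L[nC] + periods[nC]
  t <- seq(0, t_end, by = 1 / rate)

  ch <- list()
  ch$ankle_L <- .eval_leg(t, starts_L, schedule, control, morph, sh, "ankle")
  ch$knee_L <- .eval_leg(t, starts_L, schedule, control, morph, sh, "knee")
  ch$hip_L <- .eval_leg(t, starts_L, schedule, control, morph, sh, "hip")
  ch$ankle_R <- .eval_leg(t, starts_R, schedule_R, control, morph, sh, "ankle")
  ch$knee_R <- .eval_leg(t, starts_R, schedule_R, control, morph, sh, "knee")
  ch$hip_R <- .eval_leg(t, starts_R, schedule_R, control, morph, sh, "hip")
  cur_L <- .eval_leg(t, starts_L, schedule, control, morph, sh, "currents")
  cur_R <- .eval_leg(t, starts_R, schedule_R, control, morph, sh, "currents")
  ch$I_hip_L <- cur_L$hip; ch$I_knee_L <- cur_L$knee
  ch$I_hip_R <- cur_R$hip; ch$I_knee_R <- cur_R$knee

  # trunk vertical velocity: event-locked descent and two redirection peaks
  v_y <- numeric(length(t))
  add_transitions <- function(starts, sched) {
    for (k in seq_len(nrow(sched))) {
      P <- sched$period[k]
      s0 <- starts[k]
      fall_dur <- (sched$t_LLTD[k] - sched$t_SKF[k]) / 100 * P
      a_d <- sh$fall_base + sh$fall_gain * max(0, fall_dur)
      c_d <- s0 + (sched$t_LLTD[k] - sh$descent_lead) / 100 * P
      w_d <- ((sched$t_LLTD[k] - sched$t_SKF[k]) / 2 + 2) / 100 * P
      v_y <<- v_y - a_d * .rc_bump(t, c_d, w_d)
      v_y <<- v_y + sh$peak1_amp *
        .rc_bump(t, s0 + (sched$t_LLTD[k] + sh$peak1_delay) / 100 * P,
                 sh$peak1_w / 100 * P)
      v_y <<- v_y + sh$peak2_amp *
        .rc_bump(t, s0 + (sched$t_TO[k] + sh$peak2_delay) / 100 * P,
                 sh$peak2_w / 100 * P)
    }
  }
  add_transitions(starts_L, schedule)
  add_transitions(starts_R, schedule_R)
  # per-cycle zero-mean so the trunk height stays periodic
  cyc <- findInterval(t, starts_L)
  cyc[cyc == 0] <- 1L
  v_y <- v_y - ave(v_y, cyc)
  h <- .cumtrapz(t, v_y)
  ch$fourbar <- asin(pmin(1, pmax(-1, h / morph$r_fourbar)))

  # forward trunk speed: drop at each collision, linear recovery between;
  # preemptive push-off (SAPF before LLTD) cancels part of the drop
  coll_t <- c(starts_L, starts_R + sh$p_td / 100 * schedule_R$period)
  pre_push <- c(pmax(0, (schedule$t_LLTD - schedule$t_SAPF) / 100 * schedule$period),
                pmax(0, (schedule_R$t_LLTD - schedule_R$t_SAPF) / 100 * schedule_R$period))
  ord <- order(coll_t)
  coll_t <- coll_t[ord]
  drops <- pmax(0.02, sh$drop0 - sh$kappa_push * pre_push[ord])
  dvdt <- numeric(length(t))
  for (j in seq_along(coll_t)) {
    # raised-cosine deceleration pulse integrating to -drops[j]
    # (the bump's integral equals its half-width)
    dvdt <- dvdt - drops[j] / (sh$drop_width / 2) *
      .rc_bump(t, coll_t[j] + sh$drop_width / 2, sh$drop_width / 2)
  }
  gaps <- diff(coll_t)
  for (j in seq_along(gaps)) {
    i <- t >= coll_t[j] & t < coll_t[j + 1]
    dvdt[i] <- dvdt[i] + drops[j + 1] / gaps[j]   # recover the next drop
  }
  v_x <- .cumtrapz(t, dvdt)
  v_x <- v_x - mean(v_x) + mean_forward_speed
  ch$slider_x <- .cumtrapz(t, v_x)

  truth <- schedule
  truth$t_start <- starts_L
  md <- list(condition = control$mode, uniform_rate = rate,
             mean_forward_speed = mean_forward_speed, synthetic = TRUE)
  list(log = gait_log(t, ch, md), truth = truth)
}

#' Sensor/noise model
#'
#' @param sampling_rate_nominal nominal sampling rate, Hz.
#' @param sampling_jitter fractional spacing perturbation (uniform on
#'   `+/- sampling_jitter` of the nominal spacing).
#' @param counts named encoder counts per revolution for angle channels
#'   (hip/knee encoders 5000 CPR, ankle and four-bar 4096 CPR); `Inf`
#'   disables quantisation.
#' @param angle_noise_sd additive angle noise SD, rad.
#' @param slider_noise_sd additive slider noise SD, m.
#' @param current_noise_sd additive current noise SD, A.
#' @param seed integer seed, or `NULL`.
#' @return list of class `noise_model`.
#' @export
noise_model <- function(sampling_rate_nominal = 600,
                        sampling_jitter = 0.15,
                        counts = c(hip = 5000, knee = 5000,
                                   ankle = 4096, fourbar = 4096),
                        angle_noise_sd = 5e-4,
                        slider_noise_sd = 2e-4,
                        current_noise_sd = 0.01,
                        seed = NULL) {
  stopifnot(sampling_rate_nominal > 0, sampling_jitter >= 0,
            sampling_jitter < 1)
  structure(list(sampling_rate_nominal = sampling_rate_nominal,
                 sampling_jitter = sampling_jitter, counts = counts,
                 angle_noise_sd = angle_noise_sd,
                 slider_noise_sd = slider_noise_sd,
                 current_noise_sd = current_noise_sd, seed = seed),
            class = "noise_model")
}

#' Zero-noise sensor model (identity apart from resampling)
#' @param rate nominal rate, Hz.
#' @return a [noise_model()] with no jitter, no quantisation, no noise.
#' @export
noise_model_none <- function(rate = 600) {
  noise_model(sampling_rate_nominal = rate, sampling_jitter = 0,
              counts = c(hip = Inf, knee = Inf, ankle = Inf, fourbar = Inf),
              angle_noise_sd = 0, slider_noise_sd = 0, current_noise_sd = 0)
}

#' Apply the sensor model to a noiseless uniform log
#'
#' Re-draws timestamps with jittered spacing around the nominal rate,
#' linearly interpolates all channels onto them, quantises angle channels to
#' the encoder resolution (step `2*pi/counts`) and adds white measurement
#' noise. The ground truth is untouched.
#'
#' @param log a uniform noiseless `gait_log`.
#' @param noise a [noise_model()].
#' @return a `gait_log` with non-uniform timestamps.
#' @export
apply_sensor_model <- function(log, noise) {
  stopifnot(inherits(log, "gait_log"), inherits(noise, "noise_model"))
  if (!is.null(noise$seed)) set.seed(noise$seed)
  ts <- log$timestamps
  t0 <- ts[1]; t1 <- ts[length(ts)]
  dt0 <- 1 / noise$sampling_rate_nominal
  n_max <- ceiling((t1 - t0) / dt0 * (1 + noise$sampling_jitter)) + 2
  dts <- dt0 * (1 + noise$sampling_jitter * runif(n_max, -1, 1))
  if (any(dts <= 0)) stop("sampling jitter produced non-increasing timestamps",
                          call. = FALSE)
  stamps <- t0 + cumsum(c(0, dts))
  stamps <- stamps[stamps <= t1]
  q_of <- function(nm) {
    key <- c(hip = "hip", knee = "knee", ankle = "ankle", fourbar = "fourbar")
    hit <- names(key)[vapply(names(key), function(k) startsWith(nm, k), TRUE)]
    if (!length(hit)) return(Inf)
    noise$counts[[hit[1]]]
  }
  ch <- lapply(names(log$channels), function(nm) {
    x <- approx(ts, log$channels[[nm]], xout = stamps)$y
    if (startsWith(nm, "I_")) {
      if (noise$current_noise_sd > 0) {
        x <- x + rnorm(length(x), sd = noise$current_noise_sd)
      }
    } else if (nm == "slider_x") {
      if (noise$slider_noise_sd > 0) {
        x <- x + rnorm(length(x), sd = noise$slider_noise_sd)
      }
    } else {
      if (noise$angle_noise_sd > 0) {
        x <- x + rnorm(length(x), sd = noise$angle_noise_sd)
      }
      cnt <- q_of(nm)
      if (is.finite(cnt)) {
        q <- 2 * pi / cnt
        x <- round(x / q) * q
      }
    }
    x
  })
  names(ch) <- names(log$channels)
  md <- log$metadata
  md$uniform_rate <- NULL
  md$sensor_model <- unclass(noise)
  gait_log(stamps, ch, md)
}

#' Simulate a complete walking experiment
#'
#' Convenience wrapper: draws a ground-truth schedule (with two extra
#' cycles so that downstream segmentation can recover `n_cycles` complete
#' cycles starting from the second touch-down), synthesizes the noiseless
#' channels and applies the sensor model.
#'
#' @param mode condition, see [control_params()].
#' @param n_cycles number of analysable cycles (default 120).
#' @param seed integer seed controlling schedule and sensor noise.
#' @param noise a [noise_model()]; `noise_model_none()` for noiseless logs.
#' @param control,morphology overrides of the defaults.
#' @param mean_forward_speed mean slider speed, m/s.
#' @param synth_rate rate of the internal noiseless log, Hz.
#' @param event_jitter_sd per-event schedule jitter SD, percent GC.
#' @param shape curve constants, see [synth_shape_defaults()].
#' @return list with `log` (sensor-model output), `noiseless` (uniform
#'   truth log), `truth` (schedule with absolute starts), `control`,
#'   `morphology`, `seed`.
#' @export
simulate_gait <- function(mode = "AKFI", n_cycles = 120, seed = 1,
                          noise = noise_model(seed = NULL),
                          control = control_params(mode),
                          morphology = validate_morphology(),
                          mean_forward_speed = 0.44,
                          synth_rate = 2000,
                          event_jitter_sd = 0.3,
                          shape = synth_shape_defaults()) {
  stopifnot(identical(control$mode, mode))
  sched <- schedule_ground_truth(control, n_cycles + 2, seed = seed,
                                 event_jitter_sd = event_jitter_sd)
  syn <- synthesize_joint_angles(sched, control, morphology,
                                 rate = synth_rate,
                                 mean_forward_speed = mean_forward_speed,
                                 shape = shape)
  noisy <- apply_sensor_model(syn$log, noise)
  noisy$metadata$seed <- seed
  list(log = noisy, noiseless = syn$log, truth = syn$truth,
       control = control, morphology = validate_morphology(morphology),
       seed = seed)
}
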