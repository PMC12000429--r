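# Planar forward kinematics of the 7-segment body, segmental momenta,
# trailing-leg / remaining-body / CoM partition, step-to-step transition
# window, impulses, velocity redirection and kinetic energy.
#
# Coordinates: x forward, y up. The trunk is rotation-locked; its pose
# follows the four-bar slider (x) and the lower four-bar rod angle (y).

.seg_names <- c("foot_L", "shank_L", "thigh_L", "foot_R", "shank_R",
                "thigh_R", "trunk")

#' Forward kinematics: segment centre-of-mass positions
#'
#' Computes the planar CoM position of all seven segments (two feet, two
#' shanks, two thighs, trunk) from the joint angles, slider position and
#' four-bar rod angle. The hip joint sits at
#' `(slider_x, hip_height + r_fourbar * sin(fourbar))`; the thigh hangs
#' from it rotated forward by the hip flexion angle, the shank from the
#' knee rotated back by the knee flexion angle, and the foot extends
#' forward from the ankle, horizontal when the leg is straight and the
#' ankle at its slack pose. Each segment's CoM lies at its configured
#' fraction along the segment.
#'
#' @param channels named list of numeric vectors (`hip_L`, `knee_L`,
#'   `ankle_L`, same for `_R`, `slider_x`, `fourbar`), rad / m.
#' @param morphology a validated [validate_morphology()].
#' @return list of 7 matrices (n x 2, columns x/y), named as in
#'   `segment_masses()`.
#' @export
forward_kinematics <- function(channels, morphology) {
  m <- validate_morphology(morphology)
  need <- c("hip_L", "knee_L", "ankle_L", "hip_R", "knee_R", "ankle_R",
            "slider_x", "fourbar")
  miss <- setdiff(need, names(channels))
  if (length(miss)) {
    stop("forward kinematics is missing channels: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  hip_x <- channels$slider_x
  hip_y <- m$hip_height + m$r_fourbar * sin(channels$fourbar)
  cf <- m$segment_com_fractions
  l_foot <- m$l_heel + m$l_toe
  leg <- function(side) {
    thH <- channels[[paste0("hip_", side)]]
    thK <- channels[[paste0("knee_", side)]]
    al <- channels[[paste0("ankle_", side)]]
    thigh_dir <- cbind(sin(thH), -cos(thH))
    shank_ang <- thH - thK
    shank_dir <- cbind(sin(shank_ang), -cos(shank_ang))
    knee <- cbind(hip_x, hip_y) + m$l_thigh * thigh_dir
    ankle <- knee + m$l_shank * shank_dir
    foot_ang <- shank_ang + (al - m$alpha_A_slack)
    foot_dir <- cbind(cos(foot_ang), sin(foot_ang))
    list(
      thigh = cbind(hip_x, hip_y) + cf[["thigh"]] * m$l_thigh * thigh_dir,
      shank = knee + cf[["shank"]] * m$l_shank * shank_dir,
      foot = ankle + cf[["foot"]] * l_foot * foot_dir
    )
  }
  L <- leg("L"); R <- leg("R")
  list(
    foot_L = L$foot, shank_L = L$shank, thigh_L = L$thigh,
    foot_R = R$foot, shank_R = R$shank, thigh_R = R$thigh,
    trunk = cbind(hip_x, hip_y + m$trunk_com_offset)
  )
}

#' Segment masses from the morphology's mass fractions
#' @param morphology a validated morphology.
#' @return named numeric vector of the 7 segment masses, kg.
#' @export
segment_masses <- function(morphology) {
  m <- validate_morphology(morphology)
  m$segment_mass_fractions[.seg_names] * m$total_mass
}

#' Linear momentum of a segment
#'
#' Componentwise product `p = m * v`, exact.
#'
#' @param m_i segment mass, kg (> 0).
#' @param v_i velocity: length-2 vector or n x 2 matrix, m/s.
#' @return momentum with the shape of `v_i`, kg m/s.
#' @export
segment_momentum <- function(m_i, v_i) {
  stopifnot(is.numeric(m_i), length(m_i) == 1, m_i > 0)
  m_i * v_i
}

#' Partition segment momenta into trailing leg, remaining body and CoM
#'
#' The trailing leg (TL) is the foot, shank and thigh of the trailing side;
#' the remaining body (RB) is the other leg plus the trunk; the CoM
#' aggregate is their sum, with `v_CoM = p_CoM / total_mass`.
#'
#' @param momenta named list of 7 momentum matrices/vectors (names as in
#'   `segment_masses()`).
#' @param trailing_side `"L"` or `"R"`.
#' @param total_mass total body mass, kg.
#' @return list with `p_TL`, `p_RB`, `p_CoM`, `v_CoM`.
#' @export
partition_momentum <- function(momenta, trailing_side = c("L", "R"),
                               total_mass) {
  trailing_side <- match.arg(trailing_side)
  if (!setequal(names(momenta), .seg_names)) {
    stop("momenta must be named: ", paste(.seg_names, collapse = ", "),
         call. = FALSE)
  }
  tl_names <- paste0(c("foot_", "shank_", "thigh_"), trailing_side)
  rb_names <- setdiff(.seg_names, tl_names)
  add <- function(nms) Reduce(`+`, momenta[nms])
  p_TL <- add(tl_names)
  p_RB <- add(rb_names)
  p_CoM <- p_TL + p_RB
  list(p_TL = p_TL, p_RB = p_RB, p_CoM = p_CoM, v_CoM = p_CoM / total_mass)
}

#' Aggregate linear kinetic energy of a body part
#'
#' Default (`form = "aggregate"`): the translational energy of the part
#' moving as a whole, `|p|^2 / (2 m)` — the form that tracks the CoM
#' velocity vector. `form = "segment_sum"` instead sums each segment's
#' `m v^2 / 2` (requires `segments`, a list of `(m, v)` pairs).
#'
#' @param p momentum of the part: length-2 vector or n x 2 matrix.
#' @param m_part mass of the part, kg.
#' @param form energy definition.
#' @param segments for `"segment_sum"`: list of lists with elements `m`
#'   and `v`.
#' @return kinetic energy, J (scalar or vector).
#' @export
kinetic_energy <- function(p, m_part, form = c("aggregate", "segment_sum"),
                           segments = NULL) {
  form <- match.arg(form)
  if (form == "aggregate") {
    if (is.matrix(p)) rowSums(p^2) / (2 * m_part) else sum(p^2) / (2 * m_part)
  } else {
    stopifnot(!is.null(segments))
    Reduce(`+`, lapply(segments, function(s) {
      if (is.matrix(s$v)) s$m * rowSums(s$v^2) / 2 else s$m * sum(s$v^2) / 2
    }))
  }
}

#' Momentum series of the whole log
#'
#' Runs the forward kinematics over a filtered uniform log, differentiates
#' segment CoM positions by central differences, and assembles TL/RB/CoM
#' momentum, CoM velocity and aggregate kinetic-energy series.
#'
#' @param ulog filtered uniform `gait_log`.
#' @param morphology validated morphology.
#' @param trailing_side `"L"` or `"R"`.
#' @return object of class `momentum_series`: list with `time`, `p_TL`,
#'   `p_RB`, `p_CoM`, `v_CoM` (n x 2 matrices), `E_TL`, `E_RB`, `E_CoM`
#'   (vectors, J) and masses.
#' @export
momentum_series <- function(ulog, morphology, trailing_side = c("L", "R")) {
  trailing_side <- match.arg(trailing_side)
  m <- validate_morphology(morphology)
  rate <- ulog$metadata$uniform_rate
  if (is.null(rate)) stop("log is not uniformly resampled", call. = FALSE)
  pos <- forward_kinematics(ulog$channels, m)
  masses <- segment_masses(m)
  momenta <- lapply(.seg_names, function(nm) {
    v <- cbind(time_gradient(pos[[nm]][, 1], rate),
               time_gradient(pos[[nm]][, 2], rate))
    segment_momentum(masses[[nm]], v)
  })
  names(momenta) <- .seg_names
  part <- partition_momentum(momenta, trailing_side, m$total_mass)
  tl_names <- paste0(c("foot_", "shank_", "thigh_"), trailing_side)
  m_TL <- sum(masses[tl_names])
  m_RB <- m$total_mass - m_TL
  structure(c(part, list(
    time = ulog$timestamps - ulog$timestamps[1],
    E_TL = kinetic_energy(part$p_TL, m_TL),
    E_RB = kinetic_energy(part$p_RB, m_RB),
    E_CoM = kinetic_energy(part$p_CoM, m$total_mass),
    m_TL = m_TL, m_RB = m_RB, m_total = m$total_mass,
    trailing_side = trailing_side
  )), class = "momentum_series")
}

#' Find the step-to-step transition window on a vertical-velocity trace
#'
#' The transition runs from the minimum vertical CoM velocity to the
#' *second* local maximum after it. The minimum is the global minimum
#' within the push-off search window; candidate maxima after it must rise
#' above the preceding valley by at least `prominence_frac` of the
#' post-minimum range.
#'
#' @param v_y vertical CoM velocity over one cycle, m/s.
#' @param pct_grid percent-GC grid.
#' @param search window (percent GC) in which the minimum is sought.
#' @param prominence_frac prominence floor, fraction of the post-minimum
#'   range.
#' @param allow_single if `TRUE`, fall back to the first peak when only one
#'   qualifies (default `FALSE`: error).
#' @return named numeric `c(t_vmin, t_vmax)`, percent GC.
#' @export
find_transition_window <- function(v_y, pct_grid, search = c(30, 80),
                                   prominence_frac = 0.1,
                                   allow_single = FALSE) {
  sel <- which(pct_grid >= search[1] & pct_grid <= search[2])
  imin <- sel[which.min(v_y[sel])]
  after <- imin:length(pct_grid)
  y <- v_y[after]
  rng <- max(y) - y[1]
  if (!(rng > 0)) stop("no rise after the vertical-velocity minimum",
                       call. = FALSE)
  floor_p <- prominence_frac * rng
  # hysteresis peak detection: a candidate maximum is confirmed only once
  # the series drops at least floor_p below it; while unconfirmed, a higher
  # sample replaces the candidate (strictly higher, so ties keep the
  # earliest sample). A new candidate opens once the series rises at least
  # floor_p above the running minimum after the last confirmation.
  peaks <- integer(0)
  cand <- NA_integer_
  run_min <- y[1]
  for (i in seq_along(y)) {
    if (is.na(cand)) {
      run_min <- min(run_min, y[i])
      if (y[i] - run_min >= floor_p) cand <- i
    } else {
      if (y[i] > y[cand]) cand <- i
      if (y[cand] - y[i] >= floor_p) {
        peaks <- c(peaks, cand)
        cand <- NA_integer_
        run_min <- y[i]
      }
    }
  }
  if (!is.na(cand)) peaks <- c(peaks, cand)   # open candidate at cycle end
  if (length(peaks) < 2) {
    if (allow_single && length(peaks) == 1) {
      ipk <- after[peaks[1]]
    } else {
      stop("fewer than 2 vertical-velocity peaks after the minimum",
           call. = FALSE)
    }
  } else {
    ipk <- after[peaks[2]]
  }
  c(t_vmin = pct_grid[imin], t_vmax = pct_grid[ipk])
}

.interp_row <- function(pct_grid, mat, p) {
  cbind(approx(pct_grid, mat[, 1], xout = p, rule = 2)$y,
        approx(pct_grid, mat[, 2], xout = p, rule = 2)$y)
}

#' Momentum changes (impulses) over the transition window
#'
#' For each of TL, RB and CoM: the change of the horizontal and vertical
#' momentum components between `t_vmin` and `t_vmax`, and the change of the
#' momentum vector's magnitude `|p(vmax)| - |p(vmin)|`. If `t_lltd` is
#' given, the intermediate momentum at leading-leg touch-down is reported
#' as well (the three-timepoint summary).
#'
#' @param cycle_series list with `pct` (grid) and n x 2 matrices `p_TL`,
#'   `p_RB`, `p_CoM`, `v_CoM` over one cycle.
#' @param window named `c(t_vmin, t_vmax)`, percent GC.
#' @param t_lltd optional LLTD time, percent GC.
#' @return list of class `transition_impulses`: per part `dp` (x, y),
#'   `dmag`, the endpoint vectors, the window, and `angle_change_deg` (CoM
#'   velocity redirection).
#' @export
impulse_over_window <- function(cycle_series, window, t_lltd = NULL) {
  pct <- cycle_series$pct
  if (any(window < pct[1] | window > pct[length(pct)] + diff(pct[1:2]))) {
    stop("window endpoints outside the cycle grid", call. = FALSE)
  }
  if (!(window[1] < window[2])) {
    stop("t_vmin must precede t_vmax", call. = FALSE)
  }
  parts <- c("p_TL", "p_RB", "p_CoM")
  out <- list(window = window)
  for (p in parts) {
    ends <- .interp_row(pct, cycle_series[[p]], window)
    res <- list(
      at_vmin = ends[1, ], at_vmax = ends[2, ],
      dp = ends[2, ] - ends[1, ],
      dmag = sqrt(sum(ends[2, ]^2)) - sqrt(sum(ends[1, ]^2))
    )
    if (!is.null(t_lltd)) {
      res$at_lltd <- drop(.interp_row(pct, cycle_series[[p]], t_lltd))
    }
    out[[p]] <- res
  }
  v_ends <- .interp_row(pct, cycle_series$v_CoM, window)
  out$angle_change_deg <- velocity_angle_change(v_ends[1, ], v_ends[2, ])
  class(out) <- "transition_impulses"
  out
}

#' Direction change of the CoM velocity during the transition
#'
#' Signed angle between the velocity vectors at the start and end of the
#' step-to-step transition, in degrees; positive for upward redirection
#' (counter-clockwise with x forward, y up). Invariant to positive scaling
#' of either vector.
#'
#' @param v1,v2 length-2 velocity vectors, m/s.
#' @return angle in degrees.
#' @export
velocity_angle_change <- function(v1, v2) {
  if (sum(v1^2) == 0 || sum(v2^2) == 0) {
    stop("velocity angle change undefined for a zero vector", call. = FALSE)
  }
  atan2(v1[1] * v2[2] - v1[2] * v2[1], sum(v1 * v2)) * 180 / pi
}

#' Per-cycle transition impulses for a segmented record
#'
#' Slices the momentum series at the given cycle boundaries, locates the
#' transition window on each cycle's vertical CoM velocity and computes the
#' impulses. Failing cycles are reported and excluded, never dropped
#' silently.
#'
#' @param ms a [momentum_series()].
#' @param boundaries touch-down times, s (as passed to [segment_cycles()]).
#' @param n_keep number of cycles.
#' @param events optional `gait_events` supplying per-cycle LLTD times.
#' @param n_grid percent-GC grid length.
#' @param search,prominence_frac,allow_single see
#'   [find_transition_window()].
#' @param vy_smooth_cutoff extra zero-phase low-pass (Hz) applied to the
#'   per-cycle vertical CoM velocity before peak picking only; the CoM
#'   dynamics live well below 15 Hz, and encoder noise surviving the
#'   channel filters otherwise spawns spurious prominence peaks. `NULL`
#'   disables. Impulses are always evaluated on the unsmoothed series.
#' @return list of class `impulse_table`: `per_cycle` data.frame (columns
#'   `cycle`, `t_vmin`, `t_vmax`, `dp_TL_x`, `dp_TL_y`, `dmag_TL`, same for
#'   RB and CoM, `angle_change_deg`), `excluded`, `failures`, `summary`.
#' @export
transition_impulses <- function(ms, boundaries, n_keep = 120, events = NULL,
                                n_grid = 1000, search = c(30, 80),
                                prominence_frac = 0.1, allow_single = FALSE,
                                vy_smooth_cutoff = 15) {
  stopifnot(inherits(ms, "momentum_series"))
  if (length(boundaries) < n_keep + 1) {
    stop(sprintf("requested %d cycles but only %d are available",
                 n_keep, max(0, length(boundaries) - 1)), call. = FALSE)
  }
  pct <- seq(0, 100, length.out = n_grid + 1)[1:n_grid]
  cols <- c("t_vmin", "t_vmax",
            "dp_TL_x", "dp_TL_y", "dmag_TL",
            "dp_RB_x", "dp_RB_y", "dmag_RB",
            "dp_CoM_x", "dp_CoM_y", "dmag_CoM", "angle_change_deg")
  out <- data.frame(cycle = seq_len(n_keep))
  for (cn in cols) out[[cn]] <- NA_real_
  failures <- character(0); excluded <- integer(0)
  slice <- function(mat, tt) {
    cbind(approx(ms$time, mat[, 1], xout = tt, rule = 2)$y,
          approx(ms$time, mat[, 2], xout = tt, rule = 2)$y)
  }
  for (k in seq_len(n_keep)) {
    res <- tryCatch({
      t0 <- boundaries[k]; t1 <- boundaries[k + 1]
      tt <- t0 + pct / 100 * (t1 - t0)
      cyc <- list(pct = pct,
                  p_TL = slice(ms$p_TL, tt), p_RB = slice(ms$p_RB, tt),
                  p_CoM = slice(ms$p_CoM, tt), v_CoM = slice(ms$v_CoM, tt))
      vy <- cyc$v_CoM[, 2]
      if (!is.null(vy_smooth_cutoff)) {
        vy <- lowpass_zero_phase(vy, rate = n_grid / (t1 - t0),
                                 order = 2, cutoff = vy_smooth_cutoff)
      }
      win <- find_transition_window(vy, pct, search,
                                    prominence_frac, allow_single)
      t_lltd <- if (!is.null(events)) events$per_cycle$t_LLTD[k] else NULL
      imp <- impulse_over_window(cyc, win, t_lltd)
      c(win,
        imp$p_TL$dp, imp$p_TL$dmag,
        imp$p_RB$dp, imp$p_RB$dmag,
        imp$p_CoM$dp, imp$p_CoM$dmag,
        imp$angle_change_deg)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded <- c(excluded, k)
      failures <- c(failures, sprintf("cycle %d: %s", k, conditionMessage(res)))
    } else {
      out[k, cols] <- res
    }
  }
  ok <- setdiff(seq_len(n_keep), excluded)
  summ <- data.frame(
    measure = cols,
    mean = vapply(cols, function(cn) mean(out[[cn]][ok]), 1),
    sd = vapply(cols, function(cn) sd(out[[cn]][ok]), 1),
    row.names = NULL
  )
  structure(list(per_cycle = out, summary = summ, excluded = excluded,
                 failures = failures, trailing_side = ms$trailing_side),
            class = "impulse_table")
}

#' @export
print.impulse_table <- function(x, ...) {
  cat(sprintf("<impulse_table> %d cycles (%d excluded)\n",
              nrow(x$per_cycle), length(x$excluded)))
  print(transform(x$summary, mean = signif(mean, 3), sd = signif(sd, 2)))
  invisible(x)
}
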