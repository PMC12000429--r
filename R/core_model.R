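#' bipedgait: gait analysis for a planar spring-tendon biped
#'
#' Analysis pipeline for walking experiments on a planar bipedal robot with
#' actuated hips and knees and passive, spring-loaded ankles. The package
#' covers synthetic sensor-log generation with known event schedules, signal
#' preprocessing, kinematic gait-event detection, segmental momentum and
#' impulse analysis over the step-to-step transition, spring-tendon and
#' electrical energetics, and paired nonparametric comparison of two
#' experimental conditions.
#'
#' ## Conventions
#'
#' All internal computation is in SI units (rad, m, kg, s); degrees appear
#' only at input/output boundaries. Angles: ankle dorsiflexion positive with
#' the swing plateau near -22 degrees, knee flexion positive with full
#' extension at 0, hip flexion positive. The gait cycle (GC) runs from one
#' touch-down of the reference foot to the next; times within a cycle are
#' expressed in percent of the cycle on the half-open interval `[0, 100)`.
#'
#' @keywords internal
#' @importFrom stats approx rnorm runif sd median pnorm quantile ave setNames
#' @importFrom utils head tail read.csv write.csv modifyList
"_PACKAGE"

# ---------------------------------------------------------------------------
# Angle conversion and gait-cycle phase helpers
# ---------------------------------------------------------------------------

#' Convert angles between degrees and radians
#'
#' Exact linear conversion by pi/180. Round-trips are exact to floating-point
#' precision.
#'
#' @param value numeric vector of angles.
#' @param direction `"deg2rad"` or `"rad2deg"`.
#' @return numeric vector in the target unit.
#' @examples
#' convert_angle(-22, "deg2rad")
#' @export
convert_angle <- function(value, direction = c("deg2rad", "rad2deg")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(value), all(is.finite(value)))
  if (direction == "deg2rad") value * pi / 180 else value * 180 / pi
}

#' Express a time instant as percent of a gait cycle
#'
#' Maps a time `t` inside the cycle `[cycle_start, cycle_end)` onto the
#' half-open percent scale `[0, 100)`. Events falling exactly on the next
#' touch-down belong to the next cycle and are rejected here.
#'
#' @param t time in seconds (vectorised).
#' @param cycle_start,cycle_end cycle boundaries in seconds.
#' @return percent of gait cycle in `[0, 100)`.
#' @export
to_percent_gc <- function(t, cycle_start, cycle_end) {
  if (!(cycle_start < cycle_end)) {
    stop("cycle_start must be strictly less than cycle_end", call. = FALSE)
  }
  if (any(t < cycle_start | t >= cycle_end)) {
    stop("t outside the cycle [cycle_start, cycle_end)", call. = FALSE)
  }
  100 * (t - cycle_start) / (cycle_end - cycle_start)
}

# ---------------------------------------------------------------------------
# Morphology
# ---------------------------------------------------------------------------

#' Default morphology of the planar biped
#'
#' Geometric, elastic, mass and electrical constants of the robot. Lengths in
#' m, stiffnesses in N/m (linear) or N·m/rad (rotational), masses in kg.
#' The SOL spring-tendon spans the ankle only; the biarticular GAS
#' spring-tendon spans ankle and knee, both on 13 mm pulleys. Slack lengths
#' are zero at the calibration pose (ankle -22 deg, knee 0 deg). The toe
#' spring constant is stored for completeness but unused by the momentum
#' analysis, which treats each foot as a single segment.
#'
#' Segment mass fractions are not published for the hardware; the defaults
#' use a distal-light distribution (trunk 0.58, each thigh 0.10, each shank
#' 0.07, each foot 0.04) over the 2.1 kg total.
#'
#' @return named list of raw morphology constants, suitable for
#'   [validate_morphology()].
#' @export
default_morphology <- function() {
  list(
    l_thigh = 0.160,
    l_shank = 0.160,
    l_heel  = 0.032,
    l_toe   = 0.017,
    r_SOL   = 0.013,
    r_GAS   = 0.013,
    k_SOL   = 4500,                      # N/m (4.5 N/mm)
    k_GAS   = 1400,                      # N/m (1.4 N/mm)
    k_toe   = 8.04e-3 * 180 / pi,        # N·m/rad from 8.04 N·mm/deg
    l_SOL_slack = 0,
    l_GAS_slack = 0,
    alpha_A_slack = -22 * pi / 180,
    alpha_K_slack = 0,
    total_mass = 2.1,
    segment_mass_fractions = c(
      trunk = 0.58,
      thigh_L = 0.10, thigh_R = 0.10,
      shank_L = 0.07, shank_R = 0.07,
      foot_L = 0.04, foot_R = 0.04
    ),
    segment_com_fractions = c(
      trunk = 0.5, thigh = 0.5, shank = 0.5, foot = 0.5
    ),
    trunk_com_offset = 0.10,             # trunk CoM height above the hip, m
    r_fourbar = 0.2,                     # lower four-bar rod length, m
    hip_height = 0.352,                  # nominal hip height, m
    U_supply = 24,
    g = 9.81
  )
}

.morph_positive_fields <- c(
  "l_thigh", "l_shank", "l_heel", "l_toe", "r_SOL", "r_GAS",
  "k_SOL", "k_GAS", "k_toe", "total_mass", "U_supply", "g",
  "r_fourbar", "hip_height"
)

#' Validate and normalise a morphology configuration
#'
#' Fills unspecified fields from [default_morphology()], checks positivity of
#' lengths, radii, stiffnesses and masses, and checks that the segment mass
#' fractions form a partition of the total mass. Validation is idempotent:
#' validating an already validated morphology changes nothing.
#'
#' All values are expected in SI units (m, N/m, N·m/rad, kg). Unit
#' conversion from datasheet units (mm, N/mm, N·mm/deg) is the caller's
#' responsibility and must be applied exactly once; [default_morphology()]
#' already stores converted values.
#'
#' @param raw_config named list overriding defaults.
#' @return object of class `robot_morphology`.
#' @export
validate_morphology <- function(raw_config = list()) {
  if (inherits(raw_config, "robot_morphology")) raw_config <- unclass(raw_config)
  stopifnot(is.list(raw_config))
  m <- modifyList(default_morphology(), raw_config)

  for (f in .morph_positive_fields) {
    v <- m[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop(sprintf("morphology field '%s' is missing or not a finite number", f),
           call. = FALSE)
    }
    if (v <= 0) {
      stop(sprintf("morphology field '%s' must be strictly positive (got %g)", f, v),
           call. = FALSE)
    }
  }
  for (f in c("l_SOL_slack", "l_GAS_slack", "alpha_A_slack", "alpha_K_slack",
              "trunk_com_offset")) {
    v <- m[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop(sprintf("morphology field '%s' is missing or not a finite number", f),
           call. = FALSE)
    }
  }
  mf <- m$segment_mass_fractions
  required <- c("trunk", "thigh_L", "thigh_R", "shank_L", "shank_R",
                "foot_L", "foot_R")
  if (is.null(names(mf)) || !all(required %in% names(mf))) {
    stop("morphology field 'segment_mass_fractions' must name: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  mf <- mf[required]
  if (any(!is.finite(mf)) || any(mf <= 0)) {
    stop("morphology field 'segment_mass_fractions' must be strictly positive",
         call. = FALSE)
  }
  if (abs(sum(mf) - 1) > 1e-9) {
    stop(sprintf(
      "morphology field 'segment_mass_fractions' must sum to 1 (got %.12f)",
      sum(mf)), call. = FALSE)
  }
  m$segment_mass_fractions <- mf
  cf <- m$segment_com_fractions
  if (any(!is.finite(cf)) || any(cf < 0) || any(cf > 1)) {
    stop("morphology field 'segment_com_fractions' must lie in [0, 1]",
         call. = FALSE)
  }
  structure(m, class = "robot_morphology")
}

#' @export
print.robot_morphology <- function(x, ...) {
  cat("<robot_morphology>\n")
  cat(sprintf("  total mass %.3f kg; l_thigh %.3f m, l_shank %.3f m\n",
              x$total_mass, x$l_thigh, x$l_shank))
  cat(sprintf("  k_SOL %.0f N/m, k_GAS %.0f N/m, pulley radii %.3f m\n",
              x$k_SOL, x$k_GAS, x$r_SOL))
  cat(sprintf("  slack pose: ankle %.1f deg, knee %.1f deg\n",
              x$alpha_A_slack * 180 / pi, x$alpha_K_slack * 180 / pi))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Control parameters
# ---------------------------------------------------------------------------

#' Pattern-generator control parameters
#'
#' Parameters of the amplitude-controlled phase oscillators commanding hip
#' and knee. Amplitudes and offsets in degrees (converted to rad by
#' consumers), timing parameters as fractions of the gait cycle. The two
#' legs run the same pattern shifted by half a cycle.
#'
#' @param mode `"AKFI"` (knee motor active all cycle), `"PKFI"` (zero knee
#'   torque from 35 percent GC to cycle end) or `"PKFI40"` (zero torque from
#'   40 percent GC).
#' @param f gait frequency, Hz.
#' @param F_hip,F_knee flexion factors: start of hip/knee flexion as a
#'   fraction of the oscillator cycle.
#' @param theta_kneeAmplitude,theta_kneeOffset knee trajectory amplitude and
#'   offset, deg.
#' @param theta_hipAmplitude,theta_hipOffset hip trajectory amplitude and
#'   offset, deg.
#' @param phi_hip duration of the hip's steady segment at the end of swing,
#'   fraction of the cycle.
#' @param zero_torque_start start of the zero knee-torque window, fraction of
#'   the gait cycle; ignored for AKFI. Defaults to 0.35 (PKFI) or 0.40
#'   (PKFI40).
#' @param phase_shift_lr left-right phase shift, fraction of the cycle.
#' @param pd_gains record of per-joint PD gains (metadata only; never used in
#'   any computation).
#' @return object of class `control_params`.
#' @export
control_params <- function(mode = c("AKFI", "PKFI", "PKFI40"),
                           f = 1,
                           F_hip = 0.6, F_knee = 0.6,
                           theta_kneeAmplitude = 55, theta_kneeOffset = 8,
                           theta_hipAmplitude = 26, theta_hipOffset = 12,
                           phi_hip = 0.05,
                           zero_torque_start = NULL,
                           phase_shift_lr = 0.5,
                           pd_gains = list(kp_hip_right = 30, kp_hip_left = 26,
                                           kd_hip = 0.2, kp_knee = 7,
                                           kd_knee = 0.2)) {
  mode <- match.arg(mode)
  if (is.null(zero_torque_start)) {
    zero_torque_start <- switch(mode, AKFI = NA_real_, PKFI = 0.35, PKFI40 = 0.40)
  }
  if (!(is.numeric(f) && f > 0)) {
    stop("gait frequency f must be positive", call. = FALSE)
  }
  for (nm in c("F_hip", "F_knee", "phi_hip")) {
    v <- get(nm)
    if (!(v >= 0 && v < 1)) {
      stop(sprintf("%s must lie in [0, 1)", nm), call. = FALSE)
    }
  }
  if (mode != "AKFI" && !(zero_torque_start >= 0 && zero_torque_start < 1)) {
    stop("zero_torque_start must lie in [0, 1)", call. = FALSE)
  }
  if (theta_kneeAmplitude < 0 || theta_hipAmplitude < 0) {
    stop("trajectory amplitudes must be non-negative", call. = FALSE)
  }
  structure(list(
    mode = mode, f = f, F_hip = F_hip, F_knee = F_knee,
    theta_kneeAmplitude = theta_kneeAmplitude,
    theta_kneeOffset = theta_kneeOffset,
    theta_hipAmplitude = theta_hipAmplitude,
    theta_hipOffset = theta_hipOffset,
    phi_hip = phi_hip, zero_torque_start = zero_torque_start,
    phase_shift_lr = phase_shift_lr, pd_gains = pd_gains
  ), class = "control_params")
}

#' @export
print.control_params <- function(x, ...) {
  cat(sprintf("<control_params> mode %s, f %.2f Hz\n", x$mode, x$f))
  cat(sprintf("  knee %g +/- %g deg (F_knee %.2f), hip %g +/- %g deg (F_hip %.2f, steady %.2f)\n",
              x$theta_kneeOffset, x$theta_kneeAmplitude, x$F_knee,
              x$theta_hipOffset, x$theta_hipAmplitude, x$F_hip, x$phi_hip))
  if (!is.na(x$zero_torque_start)) {
    cat(sprintf("  zero knee torque from %.0f%% GC to cycle end\n",
                100 * x$zero_torque_start))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Time-series log container
# ---------------------------------------------------------------------------

.log_channels <- c(
  "hip_L", "hip_R", "knee_L", "knee_R", "ankle_L", "ankle_R",
  "slider_x", "fourbar", "I_hip_L", "I_hip_R", "I_knee_L", "I_knee_R"
)

#' Construct a raw multichannel sensor log
#'
#' A `gait_log` holds a strictly increasing (possibly non-uniform) timestamp
#' vector and the twelve standard channels: joint angles (rad) for hip, knee
#' and ankle of both legs, the four-bar slider horizontal position (m), the
#' four-bar rod angle (rad), and the four motor currents (A).
#'
#' @param timestamps numeric vector, seconds, strictly increasing.
#' @param channels named list or data.frame of numeric vectors, one per
#'   channel in [gait_log_channels()], each the same length as `timestamps`.
#' @param metadata named list (condition label, sampling descriptor,
#'   provenance); stored as-is.
#' @return object of class `gait_log`.
#' @export
gait_log <- function(timestamps, channels, metadata = list()) {
  stopifnot(is.numeric(timestamps), length(timestamps) >= 2)
  if (any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  channels <- as.list(channels)
  missing <- setdiff(.log_channels, names(channels))
  if (length(missing)) {
    stop("missing log channels: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  channels <- channels[.log_channels]
  n <- length(timestamps)
  bad <- names(channels)[vapply(channels, length, 1L) != n]
  if (length(bad)) {
    stop("channels not matching timestamp length: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(timestamps = timestamps, channels = channels,
                 metadata = metadata),
            class = "gait_log")
}

#' Standard channel names of a gait log
#' @return character vector of the twelve channel names.
#' @export
gait_log_channels <- function() .log_channels

#' @export
print.gait_log <- function(x, ...) {
  n <- length(x$timestamps)
  dt <- median(diff(x$timestamps))
  cat(sprintf("<gait_log> %d samples over %.2f s (median spacing %.4g s ~ %.0f Hz)\n",
              n, diff(range(x$timestamps)), dt, 1 / dt))
  if (!is.null(x$metadata$condition)) {
    cat(sprintf("  condition: %s\n", x$metadata$condition))
  }
  invisible(x)
}
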