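# Spring-tendon joint power, motor electrical power, net positive energy
# and cost-of-transport metrics.
#
# Tendon extensions are measured relative to the slack calibration pose
# (ankle -22 deg, knee 0 deg, slack lengths 0 m), so alpha below means
# (angle - calibration angle). The monoarticular SOL spring loads the ankle
# only; the biarticular GAS spring couples ankle and knee through equal
# pulley radii.

#' Ankle joint power from the SOL and GAS spring-tendons
#'
#' When the (slack-relative) ankle angle is at or above the knee angle the
#' biarticular GAS tendon is engaged and both tendons contribute:
#' `P_A = omega_A * (k_SOL * r_SOL * (alpha_A * r_SOL - l_SOL_slack) +
#' k_GAS * r_GAS * ((alpha_A - alpha_K) * r_GAS - l_GAS_slack))`;
#' otherwise only the SOL term remains. With `clamp_slack = TRUE` each
#' bracketed tendon force is floored at zero (a physical tendon cannot
#' push); the default is the literal unclamped expression, which is exactly
#' conservative over closed trajectories.
#'
#' @param alpha_A,alpha_K ankle and knee angles, rad (vectors).
#' @param omega_A ankle angular velocity, rad/s.
#' @param morphology validated morphology.
#' @param clamp_slack floor tendon forces at zero.
#' @return ankle power, W.
#' @export
ankle_power <- function(alpha_A, alpha_K, omega_A, morphology,
                        clamp_slack = FALSE) {
  m <- validate_morphology(morphology)
  aA <- alpha_A - m$alpha_A_slack
  aK <- alpha_K - m$alpha_K_slack
  f_sol <- m$k_SOL * (aA * m$r_SOL - m$l_SOL_slack)
  f_gas <- m$k_GAS * ((aA - aK) * m$r_GAS - m$l_GAS_slack)
  if (clamp_slack) {
    f_sol <- pmax(0, f_sol)
    f_gas <- pmax(0, f_gas)
  }
  gas_on <- aA >= aK
  omega_A * (m$r_SOL * f_sol + ifelse(gas_on, m$r_GAS * f_gas, 0))
}

#' GAS spring-tendon contribution to the knee joint power
#'
#' `P = omega_K * k_GAS * r_GAS * ((alpha_A - alpha_K) * r_GAS -
#' l_GAS_slack)`, with the same slack-relative angle convention as
#' [ankle_power()].
#'
#' @inheritParams ankle_power
#' @param omega_K knee angular velocity, rad/s.
#' @return knee power from the GAS tendon, W.
#' @export
knee_gas_power <- function(alpha_A, alpha_K, omega_K, morphology,
                           clamp_slack = FALSE) {
  m <- validate_morphology(morphology)
  aA <- alpha_A - m$alpha_A_slack
  aK <- alpha_K - m$alpha_K_slack
  f_gas <- m$k_GAS * ((aA - aK) * m$r_GAS - m$l_GAS_slack)
  if (clamp_slack) f_gas <- pmax(0, f_gas)
  omega_K * m$r_GAS * f_gas
}

#' Elastic energy stored in the ankle spring-tendons
#'
#' Quadratic spring energy of both tendons at the given pose, relative to
#' the slack pose. The time derivative of this quantity along a trajectory
#' equals [ankle_power()] plus [knee_gas_power()] (unclamped, GAS always
#' engaged), which is how the conservativity of the elastic model is
#' checked.
#'
#' @inheritParams ankle_power
#' @return stored energy, J.
#' @export
tendon_energy <- function(alpha_A, alpha_K, morphology) {
  m <- validate_morphology(morphology)
  aA <- alpha_A - m$alpha_A_slack
  aK <- alpha_K - m$alpha_K_slack
  x_sol <- aA * m$r_SOL - m$l_SOL_slack
  x_gas <- (aA - aK) * m$r_GAS - m$l_GAS_slack
  0.5 * m$k_SOL * x_sol^2 + 0.5 * m$k_GAS * x_gas^2
}

#' Motor electrical power
#'
#' `P = I_cal * U_supply` per motor channel.
#'
#' @param I_cal measured net current, A (vector).
#' @param U_supply supply voltage, V.
#' @return power, W.
#' @export
motor_power <- function(I_cal, U_supply = 24) {
  stopifnot(is.numeric(I_cal), U_supply > 0)
  I_cal * U_supply
}

#' Mean net positive electrical power
#'
#' Per sample: sum the four motor-power channels, subtract the total idle
#' power of the drivers, clip negative values to zero, then average. The
#' clipping is applied to the summed signal, not per channel.
#'
#' @param powers list (or matrix columns) of power series sharing a grid, W.
#' @param idle_power idle power per driver, W (>= 0).
#' @param n_drivers number of motor drivers (default `length(powers)`).
#' @return mean net positive power, W.
#' @export
net_positive_energy <- function(powers, idle_power = 0,
                                n_drivers = length(powers)) {
  if (idle_power < 0) stop("idle_power must be non-negative", call. = FALSE)
  total <- Reduce(`+`, powers) - idle_power * n_drivers
  mean(pmax(0, total))
}

#' Net positive cost of transport
#'
#' `COT = E_en / (m g v)` with `E_en` the mean net positive electrical
#' power, `m` the body mass, `g` gravity and `v` the mean forward speed.
#'
#' @param E_en mean net positive power, W.
#' @param m mass, kg.
#' @param v mean forward speed, m/s.
#' @param g gravitational acceleration, m/s^2.
#' @return dimensionless COT.
#' @export
cost_of_transport <- function(E_en, m, v, g = 9.81) {
  if (!(m > 0 && g > 0)) stop("m and g must be positive", call. = FALSE)
  if (!(v > 0)) stop("mean speed v must be positive", call. = FALSE)
  E_en / (m * g * v)
}

#' Relative cost of transport
#'
#' Ratio of the robot's net positive COT to a natural runner's COT of the
#' same body mass, in percent; reported raw and rounded to integer percent.
#'
#' @param COT the robot's COT.
#' @param COT_nr natural-runner reference COT (default 1.36 for a 2.1 kg
#'   runner).
#' @return list with `percent` (raw) and `percent_rounded`.
#' @export
relative_cot <- function(COT, COT_nr = 1.36) {
  if (!(COT_nr > 0)) stop("COT_nr must be positive", call. = FALSE)
  pct <- COT / COT_nr * 100
  list(percent = pct, percent_rounded = round(pct))
}

#' Energy summary of a walking record
#'
#' Computes motor powers from the current channels of a (filtered) log,
#' the mean net positive power over the analysed span, and the COT metrics.
#'
#' @param ulog uniform `gait_log` with current channels.
#' @param morphology validated morphology (supplies `U_supply`, mass, g).
#' @param v mean forward speed, m/s; if `NULL`, estimated from the slider
#'   channel.
#' @param idle_power idle power per driver, W.
#' @param COT_nr reference COT.
#' @param span optional `c(t0, t1)` restricting the averaged interval, s.
#' @return list of class `energy_summary`: `E_en`, `v`, `COT`, `COT_re`
#'   (raw and rounded), provenance.
#' @export
energy_summary <- function(ulog, morphology, v = NULL, idle_power = 0,
                           COT_nr = 1.36, span = NULL) {
  m <- validate_morphology(morphology)
  ts <- ulog$timestamps
  keep <- if (is.null(span)) rep(TRUE, length(ts)) else {
    ts - ts[1] >= span[1] & ts - ts[1] <= span[2]
  }
  if (is.null(v)) {
    x <- ulog$channels$slider_x[keep]
    tk <- ts[keep]
    v <- (x[length(x)] - x[1]) / (tk[length(tk)] - tk[1])
  }
  powers <- lapply(c("I_hip_L", "I_hip_R", "I_knee_L", "I_knee_R"),
                   function(nm) motor_power(ulog$channels[[nm]][keep],
                                            m$U_supply))
  E_en <- net_positive_energy(powers, idle_power)
  COT <- cost_of_transport(E_en, m$total_mass, v, m$g)
  structure(list(E_en = E_en, v = v, COT = COT,
                 COT_re = relative_cot(COT, COT_nr),
                 provenance = list(idle_power = idle_power, COT_nr = COT_nr,
                                   U_supply = m$U_supply)),
            class = "energy_summary")
}

#' @export
print.energy_summary <- function(x, ...) {
  cat(sprintf(
    "<energy_summary> E_en %.3f W at v %.3f m/s -> COT %.3f (%.0f%% of a natural runner)\n",
    x$E_en, x$v, x$COT, x$COT_re$percent_rounded))
  invisible(x)
}
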