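straight_pose <- function(n = 1) {
  m <- validate_morphology()
  list(hip_L = rep(0, n), knee_L = rep(0, n),
       ankle_L = rep(m$alpha_A_slack, n),
       hip_R = rep(0, n), knee_R = rep(0, n),
       ankle_R = rep(m$alpha_A_slack, n),
       slider_x = rep(0, n), fourbar = rep(0, n))
}

test_that("forward kinematics honours segment geometry", {
  m <- validate_morphology()
  ch <- straight_pose()
  pos <- forward_kinematics(ch, m)
  hip_y <- m$hip_height
  # straight leg: hip-to-ankle vertical distance = l_thigh + l_shank
  ankle_y <- pos$shank_L[1, 2] - (1 - m$segment_com_fractions[["shank"]]) *
    m$l_shank * (-1) * 0  # shank CoM midpoint; recompute ankle directly
  knee <- c(0, hip_y - m$l_thigh)
  expect_equal(pos$thigh_L[1, ], c(0, hip_y - 0.5 * m$l_thigh),
               ignore_attr = TRUE)
  expect_equal(pos$shank_L[1, ], c(0, hip_y - m$l_thigh - 0.5 * m$l_shank),
               ignore_attr = TRUE)
  expect_equal(hip_y - (knee[2] - m$l_shank), 0.320)
  # foot horizontal at the slack pose
  expect_equal(pos$foot_L[1, 2], hip_y - 0.32, tolerance = 1e-12,
               ignore_attr = TRUE)
  # pure slider translation moves every CoM by (delta, 0)
  ch2 <- straight_pose()
  ch2$slider_x <- ch2$slider_x + 0.37
  pos2 <- forward_kinematics(ch2, m)
  for (nm in names(pos)) {
    expect_equal(pos2[[nm]] - pos[[nm]], cbind(0.37, 0), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # knee flexed 90 deg with hip at 0: ankle x-offset = l_shank behind hip
  ch3 <- straight_pose()
  ch3$knee_L <- pi / 2
  pos3 <- forward_kinematics(ch3, m)
  shank_com_x <- pos3$shank_L[1, 1]
  expect_equal(shank_com_x, -0.5 * m$l_shank, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(forward_kinematics(straight_pose()[-1], m), "missing")
})

test_that("segment momentum is the exact mass-velocity product", {
  expect_equal(segment_momentum(0.3, c(1, 0)), c(0.3, 0))
  expect_equal(segment_momentum(0.3, c(0, 0)), c(0, 0))
  m <- validate_morphology()
  masses <- segment_masses(m)
  v <- c(0.7, -0.2)
  total <- Reduce(`+`, lapply(masses, segment_momentum, v_i = v))
  expect_equal(total, m$total_mass * v, tolerance = 1e-12)
})

test_that("momentum partition is additive, relabel-invariant and mass-consistent", {
  m <- validate_morphology()
  masses <- segment_masses(m)
  set.seed(5)
  momenta <- lapply(masses, function(mi) mi * matrix(rnorm(20), 10, 2))
  part <- partition_momentum(momenta, "L", m$total_mass)
  expect_identical(part$p_CoM, part$p_TL + part$p_RB)
  sw <- partition_momentum(momenta, "R", m$total_mass)
  expect_equal(sw$p_CoM, part$p_CoM, tolerance = 1e-15)
  # uniform motion: p_TL / p_CoM equals the TL mass fraction
  v <- c(0.44, 0)
  momenta_u <- lapply(masses, function(mi) mi * matrix(v, 1, 2, byrow = TRUE))
  pu <- partition_momentum(momenta_u, "L", m$total_mass)
  frac <- sum(masses[c("foot_L", "shank_L", "thigh_L")]) / m$total_mass
  expect_equal(pu$p_TL[1] / pu$p_CoM[1], frac, tolerance = 1e-12)
  # trailing leg at rest: CoM momentum equals RB momentum
  momenta_r <- momenta_u
  for (nm in c("foot_L", "shank_L", "thigh_L")) momenta_r[[nm]][] <- 0
  pr <- partition_momentum(momenta_r, "L", m$total_mass)
  expect_equal(pr$p_CoM, pr$p_RB)
})

test_that("momentum additivity holds at machine precision on a full record", {
  ms <- cached_analysis("AKFI", noisy = TRUE)$momentum
  expect_identical(ms$p_CoM, ms$p_TL + ms$p_RB)
  expect_lt(max(abs(ms$p_CoM - (ms$p_TL + ms$p_RB))), 1e-15)
})

test_that("transition window picks the second peak after the minimum", {
  pct <- make_pct_grid(1000)
  vy <- -0.2 * exp(-((pct - 45) / 3)^2) +
    0.15 * exp(-((pct - 55) / 2.5)^2) + 0.15 * exp(-((pct - 65) / 2.5)^2)
  w <- find_transition_window(vy, pct)
  expect_equal(unname(w["t_vmin"]), 45, tolerance = 0.2)
  expect_equal(unname(w["t_vmax"]), 65, tolerance = 0.2)
  expect_error(find_transition_window(seq(1, 0, length.out = 1000), pct),
               "rise|peaks")
  # single-peak series errors unless the fallback is explicit
  vy1 <- -0.2 * exp(-((pct - 45) / 3)^2) + 0.15 * exp(-((pct - 60) / 4)^2)
  expect_error(find_transition_window(vy1, pct), "fewer than 2")
  w1 <- find_transition_window(vy1, pct, allow_single = TRUE)
  expect_equal(unname(w1["t_vmax"]), 60, tolerance = 0.3)
})

test_that("impulses subtract endpoint momenta and stay additive", {
  pct <- make_pct_grid(200)
  const <- list(pct = pct,
                p_TL = cbind(rep(0.1, 200), rep(0, 200)),
                p_RB = cbind(rep(0.2, 200), rep(0.1, 200)),
                p_CoM = cbind(rep(0.3, 200), rep(0.1, 200)),
                v_CoM = cbind(rep(0.3, 200) / 2.1, rep(0.1, 200) / 2.1))
  imp0 <- impulse_over_window(const, c(t_vmin = 45, t_vmax = 65))
  expect_equal(imp0$p_TL$dp, c(0, 0))
  expect_equal(imp0$p_CoM$dmag, 0)
  # linear ramp on TL x: 0.1 -> 0.27 across the window
  ramp <- const
  ramp$p_TL[, 1] <- seq(0, 0.5, length.out = 200)
  ramp$p_CoM <- ramp$p_TL + ramp$p_RB
  w <- c(t_vmin = pct[41], t_vmax = pct[109])
  imp <- impulse_over_window(ramp, w)
  expect_equal(imp$p_TL$dp[1],
               ramp$p_TL[109, 1] - ramp$p_TL[41, 1], tolerance = 1e-9)
  expect_equal(imp$p_CoM$dp, imp$p_TL$dp + imp$p_RB$dp, tolerance = 1e-12)
  expect_error(impulse_over_window(const, c(t_vmin = -5, t_vmax = 65)),
               "outside")
})

test_that("impulse equals the integrated momentum gradient over the window", {
  an <- cached_analysis("AKFI", noisy = FALSE, n_cycles = 6, seed = 13)
  ms <- an$momentum
  k <- 3
  t0 <- an$boundaries[k]; t1 <- an$boundaries[k + 1]
  win_pct <- c(an$impulses$per_cycle$t_vmin[k], an$impulses$per_cycle$t_vmax[k])
  tw <- t0 + win_pct / 100 * (t1 - t0)
  p <- ms$p_TL[, 1]
  a <- which.min(abs(ms$time - tw[1]))
  b <- which.min(abs(ms$time - tw[2]))
  g <- time_gradient(p, 1000)
  integ <- sum((g[a:(b - 1)] + g[(a + 1):b]) / 2) / 1000
  # trapezoid integration of central differences telescopes exactly to the
  # quarter-weighted endpoint average: consistency of the two conventions
  direct_mid <- (p[b - 1] + 2 * p[b] + p[b + 1]) / 4 -
    (p[a - 1] + 2 * p[a] + p[a + 1]) / 4
  expect_equal(integ, direct_mid, tolerance = 1e-9)
  # and agrees with the plain endpoint subtraction to discretisation error
  expect_equal(integ, p[b] - p[a], tolerance = 1e-3)
})

test_that("velocity redirection angle is signed, exact and scale-invariant", {
  expect_equal(velocity_angle_change(c(1, 0), c(1, 0)), 0)
  expect_equal(velocity_angle_change(c(1, -0.1), c(1, 0.1)),
               2 * atan(0.1) * 180 / pi, tolerance = 1e-12)
  expect_equal(velocity_angle_change(c(3, -0.3), c(5, 0.5)),
               2 * atan(0.1) * 180 / pi, tolerance = 1e-12)
  expect_equal(velocity_angle_change(c(1, 0.1), c(1, -0.1)),
               -2 * atan(0.1) * 180 / pi, tolerance = 1e-12)
  expect_error(velocity_angle_change(c(0, 0), c(1, 0)), "zero")
})

test_that("aggregate kinetic energy matches |p|^2 / 2m", {
  expect_equal(kinetic_energy(c(0, 0), 2.1), 0)
  # whole body rigid at v: E = 0.5 * M * |v|^2
  v <- c(0.4, 0.1)
  expect_equal(kinetic_energy(2.1 * v, 2.1), 0.5 * 2.1 * sum(v^2))
  # |p| = 0.9387 at 2.1 kg gives ~0.21 J
  expect_equal(kinetic_energy(c(0.9387, 0), 2.1), 0.21, tolerance = 0.005)
  segs <- list(list(m = 1, v = c(1, 0)), list(m = 2, v = c(0, 1)))
  expect_equal(kinetic_energy(NULL, NULL, form = "segment_sum",
                              segments = segs), 0.5 + 1)
})
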