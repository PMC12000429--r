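test_that("commanded knee curve realises amplitude, offset and L/R shift", {
  ph <- (0:1999) / 2000              # even grid hitting the pulse peak
  p <- control_params("AKFI")
  tr <- cpg_reference_trajectory(p, ph)
  d2r <- pi / 180
  expect_equal(max(tr$knee_L) - min(tr$knee_L), 55 * d2r, tolerance = 1e-9)
  expect_equal(min(tr$knee_L), 8 * d2r, tolerance = 1e-9)
  # zero amplitude -> constant offset
  p0 <- control_params("AKFI", theta_kneeAmplitude = 0)
  tr0 <- cpg_reference_trajectory(p0, ph)
  expect_true(all(abs(tr0$knee_L - 8 * d2r) < 1e-12))
  # left and right identical after a half-cycle circular shift
  n <- length(ph)
  idx <- ((seq_len(n) - 1 + n / 2) %% n) + 1
  expect_equal(tr$knee_R, tr$knee_L[idx], tolerance = 1e-9)
  expect_equal(tr$hip_R, tr$hip_L[idx], tolerance = 1e-9)
})

test_that("commanded hip curve stays within bounds and holds at end of swing", {
  ph <- seq(0, 1, length.out = 4001)[1:4000]
  p <- control_params("AKFI")
  tr <- cpg_reference_trajectory(p, ph)
  d2r <- pi / 180
  expect_true(all(tr$hip_L <= (12 + 26) * d2r + 1e-12))
  expect_true(all(tr$hip_L >= (12 - 26) * d2r - 1e-12))
  hold <- tr$hip_L[ph >= 1 - p$phi_hip]
  expect_true(all(abs(hold - (12 + 26) * d2r) < 1e-12))
  # continuity across the periodic wrap
  expect_lt(abs(tr$hip_L[1] - tr$hip_L[length(ph)]), 1e-3)
})

test_that("ground-truth schedules honour the condition means and ordering", {
  ctrl <- control_params("AKFI")
  s0 <- schedule_ground_truth(ctrl, 10, seed = 3, event_jitter_sd = 0)
  expect_true(all(s0$t_SAPF == 46.25))
  expect_true(all(s0$t_SKF == 39.00))
  ctrl_p <- control_params("PKFI")
  sp <- schedule_ground_truth(ctrl_p, 10, seed = 3, event_jitter_sd = 0)
  expect_true(all(sp$t_SAPF - sp$t_LLTD > 0))   # SAPF after LLTD
  expect_true(all(s0$t_SAPF - s0$t_LLTD < 0))   # SAPF before LLTD
  # PKFI knee flexion later by ~4.7 %GC
  expect_equal(mean(sp$t_SKF) - mean(s0$t_SKF), 4.67, tolerance = 1e-9)
  s1 <- schedule_ground_truth(ctrl, 50, seed = 9)
  s2 <- schedule_ground_truth(ctrl, 50, seed = 9)
  expect_identical(s1, s2)                      # seeded determinism
  expect_true(all(s1$t_SKF <= s1$t_SHF & s1$t_SHF <= s1$t_SAPF &
                    s1$t_SAPF < s1$t_TO))
  bad <- c(t_SKF = 50, t_SHF = 40, t_SAPF = 46, t_LLTD = 48, t_TO = 60)
  expect_error(schedule_ground_truth(ctrl, 5, seed = 1, means = bad),
               "ordering|SKF")
})

test_that("synthesized ankle peaks at the scheduled SAPF and is flat in swing", {
  ctrl <- control_params("AKFI")
  sched <- schedule_ground_truth(ctrl, 4, seed = 5, event_jitter_sd = 0,
                                 period_jitter_sd = 0)
  syn <- synthesize_joint_angles(sched, ctrl, validate_morphology(),
                                 rate = 2000)
  log <- syn$log
  t <- log$timestamps
  ank <- log$channels$ankle_L
  # cycle 2: argmax of the stance ankle angle at t_SAPF
  in2 <- t >= 1 & t < 2
  t_max <- t[in2][which.max(ank[in2])]
  expect_lt(abs((t_max - 1) * 100 - 46.25), 0.1)
  # swing plateau exactly constant at -22 deg
  sw <- t >= 1.70 & t <= 1.95
  expect_lt(sd(ank[sw]), 1e-9)
  expect_equal(mean(ank[sw]), -22 * pi / 180, tolerance = 1e-9)
})

test_that("doubling the synthesis rate refines the same curves", {
  ctrl <- control_params("AKFI")
  sched <- schedule_ground_truth(ctrl, 3, seed = 5, event_jitter_sd = 0,
                                 period_jitter_sd = 0)
  m <- validate_morphology()
  lo <- synthesize_joint_angles(sched, ctrl, m, rate = 1000)$log
  hi <- synthesize_joint_angles(sched, ctrl, m, rate = 2000)$log
  y <- approx(hi$timestamps, hi$channels$knee_L, xout = lo$timestamps)$y
  expect_lt(max(abs(y - lo$channels$knee_L), na.rm = TRUE), 2 * pi / 5000)
})

test_that("sensor model quantises, jitters and reproduces under a seed", {
  ctrl <- control_params("AKFI")
  sched <- schedule_ground_truth(ctrl, 3, seed = 5, event_jitter_sd = 0,
                                 period_jitter_sd = 0)
  syn <- synthesize_joint_angles(sched, ctrl, validate_morphology(),
                                 rate = 2000)
  # identity: no jitter, no noise, infinite counts, matching rate
  ident <- apply_sensor_model(syn$log, noise_model_none(rate = 2000))
  expect_equal(ident$channels$hip_L,
               syn$log$channels$hip_L[seq_along(ident$timestamps)],
               tolerance = 1e-12)
  # hip encoder: all values integer multiples of 2*pi/5000
  nm <- noise_model(seed = 77)
  noisy <- apply_sensor_model(syn$log, nm)
  q <- 2 * pi / 5000
  expect_true(all(abs(noisy$channels$hip_L / q -
                        round(noisy$channels$hip_L / q)) < 1e-9))
  q_ank <- 2 * pi / 4096
  expect_true(all(abs(noisy$channels$ankle_L / q_ank -
                        round(noisy$channels$ankle_L / q_ank)) < 1e-9))
  # sampling spacing: jittered around 1/600
  expect_lt(abs(median(diff(noisy$timestamps)) - 1 / 600), 1 / 6000)
  # same seed -> identical log
  noisy2 <- apply_sensor_model(syn$log, noise_model(seed = 77))
  expect_identical(noisy$channels, noisy2$channels)
  expect_identical(noisy$timestamps, noisy2$timestamps)
})

test_that("condition contrast of the default schedules is preserved", {
  a <- cached_sim("AKFI", noisy = FALSE)
  p <- cached_sim("PKFI", noisy = FALSE)
  d <- mean(p$truth$t_SKF) - mean(a$truth$t_SKF)
  expect_equal(d, 4.67, tolerance = 3 * 0.3 / sqrt(120))
})
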