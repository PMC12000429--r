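make_log <- function(ts, f) {
  ch <- setNames(lapply(gait_log_channels(), function(nm) f(ts)),
                 gait_log_channels())
  gait_log(ts, ch)
}

test_that("uniform resampling is exact on affine signals and identity on matching grids", {
  ts <- seq(0, 1, by = 1e-3)
  log <- make_log(ts, function(t) 2 + 3 * t)
  u <- resample_uniform(log, 1000)
  expect_equal(u$timestamps, ts)
  expect_equal(u$channels$hip_L, 2 + 3 * ts, tolerance = 1e-12)
  # jittered ~600 Hz sinusoid reconstructed within 1e-3
  set.seed(42)
  tj <- cumsum(1 / 600 * (1 + 0.15 * runif(700, -1, 1)))
  logj <- make_log(tj, function(t) sin(2 * pi * 5 * t))
  uj <- resample_uniform(logj, 1000)
  expect_lt(max(abs(uj$channels$ankle_L - sin(2 * pi * 5 * uj$timestamps))),
            1e-3)
  # duplicate timestamps are rejected at construction already
  expect_error(make_log(c(0, 1e-3, 1e-3, 3e-3), function(t) t),
               "strictly increasing")
})

test_that("zero-phase Butterworth has unit DC gain, no lag, squared response at cutoff", {
  rate <- 1000
  t <- seq(0, 4, by = 1 / rate)
  expect_equal(lowpass_zero_phase(rep(2.5, 1500), rate, 2, 20),
               rep(2.5, 1500), tolerance = 1e-9)
  # sinusoid well below cutoff: zero lag at the cross-correlation peak
  x <- sin(2 * pi * 2 * t)
  y <- lowpass_zero_phase(x, rate, 2, 20)
  mid <- 1000:3000
  lags <- -5:5
  cc <- vapply(lags, function(L) sum(x[mid] * y[mid + L]), 1)
  expect_equal(lags[which.max(cc)], 0)
  # at the cutoff an order-2 filter applied twice attenuates to ~0.5
  fc <- 10
  xc <- sin(2 * pi * fc * t)
  yc <- lowpass_zero_phase(xc, rate, 2, fc)
  ratio <- sqrt(mean(yc[mid]^2) / mean(xc[mid]^2))
  expect_equal(ratio, 0.5, tolerance = 0.02)
  expect_error(lowpass_zero_phase(x, rate, 2, 600), "Nyquist")
  expect_error(lowpass_zero_phase(x[1:5], rate, 2, 20), "short")
})

test_that("filtering commutes with time reversal away from edges", {
  set.seed(7)
  rate <- 1000
  x <- as.numeric(stats::filter(rnorm(3000), rep(1 / 10, 10), sides = 2))
  x[is.na(x)] <- 0
  a <- lowpass_zero_phase(x, rate, 2, 30)
  b <- rev(lowpass_zero_phase(rev(x), rate, 2, 30))
  core <- 300:2700
  expect_lt(max(abs(a[core] - b[core])), 1e-8)
})

test_that("touch-downs are recovered from plateau departures", {
  sim <- cached_sim("AKFI", noisy = FALSE, n_cycles = 8, seed = 21)
  cfg <- default_config()
  u <- resample_uniform(sim$log, 1000)
  f <- filter_log(u, default_filtering())
  td <- detect_touchdowns(f$channels$ankle_L, 1000)
  truth_starts <- sim$truth$t_start
  # every detected boundary sits within 0.5 %GC (5 ms) of a scheduled one
  err <- vapply(td, function(s) min(abs(truth_starts - s)), 1)
  expect_lt(max(err), 0.005)
  expect_gte(length(td), 7)
  expect_error(detect_touchdowns(rep(0.5, 5000), 1000), "plateau")
})

test_that("two identical concatenated cycles give two boundaries one period apart", {
  ctrl <- control_params("AKFI")
  sched <- schedule_ground_truth(ctrl, 3, seed = 2, event_jitter_sd = 0,
                                 period_jitter_sd = 0)
  syn <- synthesize_joint_angles(sched, ctrl, validate_morphology(),
                                 rate = 1000)
  ank <- lowpass_zero_phase(syn$log$channels$ankle_L, 1000, 2, 50)
  td <- detect_touchdowns(ank, 1000)
  expect_equal(length(td), 2)          # cycle 1 start lacks a prior plateau
  expect_equal(diff(td), 1, tolerance = 2e-3)
})

test_that("cycle segmentation keeps the requested count and degenerate SD is zero", {
  ts <- seq(0, 6, by = 1e-3)
  per <- sin(2 * pi * ts)               # identical 1 s cycles
  ch <- setNames(lapply(gait_log_channels(), function(nm) per),
                 gait_log_channels())
  log <- gait_log(ts, ch, metadata = list(uniform_rate = 1000))
  ens <- segment_cycles(log, boundaries = 0:5, n_keep = 5, n_grid = 500)
  expect_equal(length(ens$periods), 5)
  expect_lt(max(ens$sd$hip_L), 1e-9)
  expect_equal(ens$mean$hip_L, sin(2 * pi * ens$pct / 100), tolerance = 1e-6)
  expect_error(segment_cycles(log, boundaries = 0:5, n_keep = 6),
               "only 5")
})

test_that("segmentation of a noiseless synthetic log reproduces the generator curves", {
  sim <- cached_sim("AKFI", noisy = FALSE, n_cycles = 8, seed = 21)
  u <- resample_uniform(sim$log, 1000)
  ens <- segment_cycles(u, sim$truth$t_start - u$timestamps[1],
                        n_keep = 8, n_grid = 1000)
  # swing plateau value and stance peak position survive the round trip
  plateau <- ens$mean$ankle_L[ens$pct >= 70 & ens$pct <= 95]
  expect_lt(max(abs(plateau - (-22 * pi / 180))), 2 * (2 * pi / 4096))
  i_max <- which.max(ens$mean$ankle_L)
  expect_lt(abs(ens$pct[i_max] - 46.25), 0.5)
})
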