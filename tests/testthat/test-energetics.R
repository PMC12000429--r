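test_that("ankle power follows the two-branch spring-tendon expression", {
  m <- validate_morphology()
  # calibration pose, zero slack: zero power at any angular velocity
  expect_equal(ankle_power(m$alpha_A_slack, m$alpha_K_slack, 3, m), 0)
  # SOL-only branch: relative alpha_A = 0.10 rad below the knee angle
  aA <- m$alpha_A_slack + 0.10
  aK <- m$alpha_K_slack + 0.50         # knee above ankle -> GAS off
  expect_equal(ankle_power(aA, aK, 1, m),
               1 * 4500 * 0.013 * (0.10 * 0.013), tolerance = 1e-12)
  # both branches: GAS term adds when relative ankle >= relative knee
  aK2 <- m$alpha_K_slack + 0.04
  expect_equal(ankle_power(aA, aK2, 1, m),
               4500 * 0.013 * 0.10 * 0.013 +
                 1400 * 0.013 * (0.06 * 0.013), tolerance = 1e-12)
  # clamped version floors a compressive tendon force at zero
  aA_neg <- m$alpha_A_slack - 0.10
  expect_lt(ankle_power(aA_neg, aK, 1, m), 0)
  expect_equal(ankle_power(aA_neg, aK, 1, m, clamp_slack = TRUE), 0)
})

test_that("GAS knee power matches the printed expression", {
  m <- validate_morphology()
  expect_equal(knee_gas_power(m$alpha_A_slack + 0.3, m$alpha_K_slack + 0.3,
                              0, m), 0)
  expect_equal(knee_gas_power(m$alpha_A_slack + 0.2, m$alpha_K_slack + 0.2,
                              5, m), 0)          # slack tendon
  expect_equal(knee_gas_power(m$alpha_A_slack + 0.2, m$alpha_K_slack,
                              2, m),
               2 * 1400 * 0.013 * (0.2 * 0.013), tolerance = 1e-12)
})

test_that("elastic power is conservative over closed trajectories", {
  m <- validate_morphology()
  rate <- 2000
  t <- seq(0, 1, by = 1 / rate)
  # closed ankle loop with a frozen knee: the ankle power alone integrates
  # to zero
  aA <- m$alpha_A_slack + 0.25 * (1 - cos(2 * pi * t))
  aK_const <- rep(m$alpha_K_slack, length(t))
  wA <- time_gradient(aA, rate)
  pA0 <- ankle_power(aA, aK_const, wA, m)
  loop <- sum(pA0[-1] + pA0[-length(t)]) / 2 / rate
  expect_lt(abs(loop), 1e-6)
  # with the knee frozen, the ankle power is the exact time derivative of
  # the stored elastic energy along the trajectory
  E <- tendon_energy(aA, aK_const, m)
  dE <- time_gradient(E, rate)
  core <- 100:1900
  expect_lt(max(abs((pA0 - dE)[core])) / max(abs(dE)), 1e-3)
  # closed loading-unloading loop of both joints, GAS engaged throughout:
  # the summed spring-tendon joint powers also integrate to zero over the
  # symmetric loop
  aK <- m$alpha_K_slack + 0.08 * (1 - cos(2 * pi * t))
  wK <- time_gradient(aK, rate)
  pA <- ankle_power(aA, aK, wA, m)
  pK <- knee_gas_power(aA, aK, wK, m)
  total <- sum((pA + pK)[-1] + (pA + pK)[-length(t)]) / 2 / rate
  expect_lt(abs(total), 1e-6)
})

test_that("motor power and net positive energy follow the stated order of operations", {
  expect_equal(motor_power(0, 24), 0)
  expect_equal(motor_power(0.5, 24), 12)
  expect_equal(motor_power(c(1, 2), 24), c(24, 48))   # linear in current
  expect_equal(net_positive_energy(list(rep(2.5, 10), rep(2.5, 10),
                                        rep(2.5, 10), rep(2.5, 10)),
                                   idle_power = 2.5), 0)
  expect_equal(net_positive_energy(list(rep(10, 5)), idle_power = 2,
                                   n_drivers = 1), 8)
  # clipping after summation differs from clipping per channel
  a <- c(3, -2); b <- c(-2, 3)
  summed <- net_positive_energy(list(a, b), idle_power = 0)
  perchan <- mean(pmax(0, a)) + mean(pmax(0, b))
  expect_equal(summed, 1)
  expect_false(isTRUE(all.equal(summed, perchan)))
  # monotone nonincreasing in idle power
  set.seed(2)
  ch <- replicate(4, abs(rnorm(100)), simplify = FALSE)
  e <- vapply(c(0, 0.1, 0.5, 1), function(ip) {
    net_positive_energy(ch, idle_power = ip)
  }, 1)
  expect_true(all(diff(e) <= 0))
  expect_error(net_positive_energy(ch, idle_power = -1), "non-negative")
})

test_that("cost of transport normalises power by m g v", {
  expect_equal(cost_of_transport(2.1 * 9.81 * 0.5, 2.1, 0.5), 1)
  expect_equal(cost_of_transport(0, 2.1, 0.5), 0)
  expect_equal(cost_of_transport(4.534, 2.1, 0.5), 4.534 / (2.1 * 9.81 * 0.5),
               tolerance = 1e-12)
  expect_equal(cost_of_transport(4.534, 2.1, 0.5), 0.4402, tolerance = 1e-4)
  # invariant under simultaneous scaling of E and m g v
  expect_equal(cost_of_transport(4.534 * 3, 2.1 * 3, 0.5),
               cost_of_transport(4.534, 2.1, 0.5))
  expect_error(cost_of_transport(1, 2.1, 0), "positive")
})

test_that("relative COT reports raw and integer-rounded percentages", {
  expect_equal(relative_cot(0.56, 1.36)$percent_rounded, 41)
  expect_equal(relative_cot(0.52, 1.36)$percent_rounded, 38)
  expect_equal(relative_cot(1.36, 1.36)$percent, 100)
  expect_error(relative_cot(0.5, 0), "positive")
})
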