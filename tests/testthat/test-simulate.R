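test_that("with no pumping the system relaxes to the compliance-weighted mean", {
  # elastance pinned (numerically) to E_d, no notch, no RSA: a passive RC
  # network whose equilibrium pressure is the stored-volume-weighted mean
  p <- cardio_params(E_s0 = 0.06 * (1 + 1e-9), E_d = 0.06,
                     c1 = 0, c3 = 0, c4 = 0,
                     p_e0 = 20, p_a0 = 25, p_v0 = 40, p_LV0 = 15)
  U0 <- p$p_LV0 / p$E_d
  p_star <- (p$C_e * p$p_e0 + p$C_a * p$p_a0 + p$C_v * p$p_v0 + U0) /
    (p$C_e + p$C_a + p$C_v + 1 / p$E_d)
  sim <- simulate_cardio(p, duration = 1500, fs_out = 10)
  final <- dplyr::slice_tail(sim$signals, n = 1)
  for (comp in c("p_e", "p_a", "p_v", "p_LV")) {
    expect_equal(final[[comp]], p_star, tolerance = 1e-8)
  }
})

test_that("total stored volume is conserved to solver tolerance over 30 s", {
  sim <- cw_cached_sim("table1_nominal", 30)
  expect_lt(sim$volume_drift, 1e-6)
  sim1 <- cw_cached_sim("patient1", 30)
  expect_lt(sim1$volume_drift, 1e-6)
})

test_that("valve closure fires exactly once per beat in steady operation", {
  sim <- cw_cached_sim("table1_nominal", 30)
  ev <- sim$events$t_n
  steady <- ev[ev >= 10]
  Tb <- 2 * pi / sim$params$omega0
  gaps <- diff(steady)
  expect_true(all(gaps > 0.8 * Tb & gaps < 1.25 * Tb))
  # as many events as elapsed cardiac cycles (accumulated phase / 2 pi)
  cycles <- (cardiac_phase(max(steady), sim$params) -
               cardiac_phase(min(steady), sim$params)) / (2 * pi)
  expect_lt(abs(cycles - (length(steady) - 1)), 0.5)
})

test_that("closure events are the downward p_LV = p_e crossings", {
  sim <- cw_cached_sim("table1_nominal", 30)
  sig <- sim$signals
  for (tn in sim$events$t_n[3:6]) {
    i <- findInterval(tn, sig$time)
    gap_before <- sig$p_LV[i - 1] - sig$p_e[i - 1]
    gap_after <- sig$p_LV[i + 2] - sig$p_e[i + 2]
    expect_gt(gap_before, -1)   # at or above zero just before
    expect_lt(gap_after, gap_before)  # falling through the crossing
  }
})

test_that("the closure delay modes behave as documented", {
  fixed <- cw_cached_sim("table1_nominal", 15)
  expect_true(all(fixed$events$dt == fixed$params$dt0))
  adaptive <- simulate_cardio(load_fixture("table1_nominal")$params,
                              duration = 15, dt_mode = "adaptive")
  expect_equal(adaptive$events$dt[1], adaptive$params$dt0)
  # measured delays settle to a cycle-independent value
  dts <- utils::tail(adaptive$events$dt, 5)
  expect_lt(diff(range(dts)) / mean(dts), 0.05)
})

test_that("the hypotensive fixture produces no dicrotic notch", {
  # its rebound-pulse height is ~8e-6 ml/s: six orders below the other fluxes
  sim <- cw_cached_sim("patient2", 30)
  p <- sim$params
  expect_lt(notch_impulse(sim$events$t_n[5] + p$c6 * p$dt0,
                          sim$events, p), 1e-5)
  sig <- signal_window(arterial_signal(sim), from = 10)
  expect_true(is.na(cardiowave:::.cw_detect_notch(sig)))
})

test_that("simulation rejects invalid run specifications", {
  expect_error(simulate_cardio(params_table1(), duration = -1), "duration")
  expect_error(simulate_cardio(params_table1(), duration = 10, fs_out = 2),
               "fs_out")
})

test_that("simulated heart rate matches the prescribed angular frequency", {
  sim <- cw_cached_sim("patient1", 30)
  sp <- steady_pressures(sim)
  hr_expected <- 60 * sim$params$omega0 / (2 * pi)
  expect_lt(abs(sp$hr - hr_expected), 2)
})
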