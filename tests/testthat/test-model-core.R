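test_that("activation rises sin^2-shaped over systole and switches off cleanly", {
  Tb <- 0.9
  om <- 2 * pi / Tb
  expect_equal(activation(0, 0, om, 1 / 3), 0)
  expect_equal(activation(Tb / 6, 0, om, 1 / 3), 1)      # mid-systole
  expect_equal(activation(Tb / 3, 0, om, 1 / 3), 0, tolerance = 1e-12)
  # continuity at the systole -> diastole switch
  eps <- 1e-6
  expect_lt(activation(Tb / 3 - eps, 0, om, 1 / 3), 1e-9)
  expect_equal(activation(Tb / 2, 0, om, 1 / 3), 0)
  expect_error(activation(0.1, 0, -1, 1 / 3), "omega")
})

test_that("angular frequency follows the respiratory modulation exactly", {
  p <- params_table1()
  p0 <- cardio_params(c3 = 0)
  tt <- seq(0, 10, by = 0.37)
  expect_equal(angular_frequency(tt, p0), rep(7.54, length(tt)))
  expect_equal(angular_frequency(0, p), 7.54)
  # quarter respiratory phase: omega0 * t / c2 = pi/2
  t_quarter <- pi * p$c2 / (2 * p$omega0)
  expect_equal(angular_frequency(t_quarter, p), 7.55)
  expect_true(all(angular_frequency(tt, p) >= p$omega0 - p$c3))
  expect_true(all(angular_frequency(tt, p) <= p$omega0 + p$c3))
})

test_that("elastance interpolates E_d..E_s with the documented bounds", {
  p <- params_table1()
  Tb <- 2 * pi / p$omega0
  # any diastolic instant gives E_d
  expect_equal(elastance(0.6 * Tb, p), p$E_d)
  # mid-systole with c1 = 0 gives E_s0
  p0 <- cardio_params(c1 = 0, c3 = 0)
  expect_equal(elastance((pi / 3) / p0$omega0, p0), p0$E_s0)
  # mid-systole coinciding with peak respiratory modulation: E = E_s0 + c1
  pd <- cardio_params(c2 = 14 / 3, c3 = 0)
  t_star <- (2 * pi + pi / 3) / pd$omega0
  expect_equal(elastance(t_star, pd), 3.1, tolerance = 1e-9)
  # bounds over a dense grid
  tt <- seq(0, 10, by = 0.003)
  E <- elastance(tt, p)
  expect_true(all(E >= p$E_d - 1e-12 & E <= p$E_s0 + p$c1 + 1e-12))
  # respiratory trough with excessive c1: E_s dips below E_d
  pbad <- cardio_params(c1 = 3.5)
  t_trough <- 3 * pi * pbad$c2 / (2 * pbad$omega0)
  expect_error(elastance(t_trough, pbad), "E_s")
})

test_that("aortic valve resistance has the closed-form knee and hard cap", {
  p <- params_table1()  # eps1 = 1e-5, A1 = 0.5
  expect_equal(aortic_valve_resistance(100, 100, p), p$R_e0 * (1 + 1e-5))
  # wide-open limit: correction below double precision
  expect_equal(aortic_valve_resistance(150, 100, p), p$R_e0)
  # R_e doubles exactly where eps1 * exp(-A1 * dp) = 1
  dp_half <- log(p$eps1) / p$A1
  expect_equal(aortic_valve_resistance(100 + dp_half, 100, p), 2 * p$R_e0,
               tolerance = 1e-9)
  # deep reverse gradients hit the cap without overflow warnings
  expect_silent(r <- aortic_valve_resistance(-1e7, 100, p))
  expect_equal(r, p$R_eM)
  # monotone non-increasing in the forward gradient
  dps <- seq(-60, 60, by = 0.5)
  rr <- aortic_valve_resistance(100 + dps, 100, p)
  expect_true(all(diff(rr) <= 1e-12))
  expect_true(all(rr >= p$R_e0 & rr <= p$R_eM))
})

test_that("mitral valve is a Heaviside switch with equality counting as open", {
  p <- params_table1()
  expect_equal(mitral_valve_resistance(15, 10, p), p$R_v0)
  expect_equal(mitral_valve_resistance(10, 15, p), p$R_eM)
  expect_equal(mitral_valve_resistance(12, 12, p), p$R_v0)
})

test_that("notch impulse is a Gaussian of height c4 with closed-form width", {
  p <- cardio_params(c5 = 4 * log(100), c6 = 7.5, c4 = 500)
  ev <- tibble::tibble(t_n = 1, dt = 0.1)
  centre <- 1 + p$c6 * 0.1
  expect_equal(notch_impulse(centre, ev, p), p$c4)
  # at half a closure delay from the centre the pulse is c4/100 exactly
  expect_equal(notch_impulse(centre + 0.05, ev, p), p$c4 / 100, tolerance = 1e-12)
  expect_equal(notch_impulse(centre - 0.05, ev, p), p$c4 / 100, tolerance = 1e-12)
  expect_equal(notch_impulse(3, NULL, p), 0)
  expect_equal(notch_impulse(0.5, ev, p), 0)  # before the first event
  expect_error(notch_impulse(1, tibble::tibble(t_n = 1, dt = -0.1), p),
               "positive")
  expect_error(notch_impulse(1, tibble::tibble(t_n = c(1, 1), dt = c(0.1, 0.1)), p),
               "increasing")
  # sum mode keeps earlier pulses alive, latest mode drops them: with
  # dt = 0.3 the first event's pulse peaks at t = 2.25, after the second
  # event has superseded it
  ev2 <- tibble::tibble(t_n = c(0, 1), dt = c(0.3, 0.3))
  t_old_centre <- 0 + p$c6 * 0.3
  expect_lt(notch_impulse(t_old_centre, ev2, p, mode = "latest"), 1e-3 * p$c4)
  expect_equal(notch_impulse(t_old_centre, ev2, p, mode = "sum"), p$c4,
               tolerance = 1e-6)
})

test_that("all-equal pressures with no pumping give a stationary state", {
  p <- params_table1()
  Tb <- 2 * pi / p$omega0
  t_dia <- 0.6 * Tb  # diastole: activation 0, elastance constant E_d
  pres <- 40
  state <- c(p_e = pres, p_a = pres, p_v = pres, U_LV = pres / p$E_d)
  d <- system_rhs(t_dia, state, NULL, p)
  expect_equal(unlist(d[1, c("dp_e", "dp_a", "dp_v", "dU_LV")]),
               c(dp_e = 0, dp_a = 0, dp_v = 0, dU_LV = 0))
  expect_equal(d$p_LV, pres)
})

test_that("compliance-weighted derivatives telescope to zero for any state", {
  set.seed(41)
  for (i in 1:25) {
    p <- cw_random_params()
    ev <- tibble::tibble(t_n = 0.2, dt = p$dt0)
    st <- c(runif(3, 5, 150), runif(1, 50, 900))
    t <- runif(1, 0.2, 3)
    d <- system_rhs(t, st, ev, p)
    bal <- p$C_e * d$dp_e + p$C_a * d$dp_a + p$C_v * d$dp_v + d$dU_LV
    scale <- max(abs(c(d$dp_e, d$dp_a, d$dp_v, d$dU_LV, 1)))
    expect_lt(abs(bal) / scale, 1e-12)
  }
})

test_that("right-hand side matches an independent flux-summation oracle", {
  set.seed(99)
  for (i in 1:100) {
    p <- cw_random_params()
    ev <- if (i %% 3 == 0) NULL else tibble::tibble(t_n = runif(1, 0, 0.5),
                                                    dt = p$dt0)
    st <- c(runif(3, 5, 150), runif(1, 50, 900))
    t <- runif(1, 0.6, 4)
    d <- system_rhs(t, st, ev, p)
    o <- cw_oracle_rhs(t, st, p, ev)
    got <- unlist(d[1, c("dp_e", "dp_a", "dp_v", "dU_LV")], use.names = FALSE)
    expect_equal(got, unname(o), tolerance = 1e-10)
  }
})

test_that("non-finite states are rejected with a time stamp", {
  expect_error(system_rhs(1.5, c(NaN, 80, 10, 100), NULL, params_table1()),
               "non-finite state at t = 1.5")
})
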