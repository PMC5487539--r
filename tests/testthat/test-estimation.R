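test_that("initial guesses implement the pulse-pressure compliance relation", {
  # 95 + 25 sin: 120/70 at 75 bpm -> C_a = 70 / 50 = 1.4 ml/mmHg
  t <- seq(0, 30, by = 0.01)
  sig <- pressure_signal(t, 95 + 25 * sin(2 * pi * t / 0.8))
  p <- init_guesses(sig, sv_assumed = 70)
  expect_equal(p$C_a, 1.4, tolerance = 0.01)
  expect_equal(p$C_v / p$C_a, 20)
  expect_equal(p$C_e, p$C_a)
  expect_equal(p$E_d, 1 / p$C_v)
  expect_equal(p$E_s0, 1 / p$C_a)
  expect_equal(p$omega0, 2 * pi * 75 / 60, tolerance = 1e-3)
  expect_equal(p$phi, 1 / 3)
  expect_equal(p$p_e0, p$p_a0)
  expect_equal(p$p_LV0, p$p_a0)
  expect_equal(p$p_v0, p$p_a0 / 3)
  expect_equal(p$dt0, 0.1 * 2 * pi / p$omega0)
})

test_that("degenerate and empty recordings are rejected before fitting", {
  t <- seq(0, 10, by = 0.01)
  expect_error(init_guesses(pressure_signal(t, rep(90, length(t)))),
               "insufficient signal")
  expect_error(fit_cardio(tibble::tibble(time = numeric(),
                                         pressure = numeric())),
               "at least 2 samples")
})

test_that("the approximate gradient is exact on quadratics and biased on cubics", {
  # central differences: exact for F = theta^2 (2 * 50 = 100)
  g <- approx_gradient(function(th) th[1]^2, 50)
  expect_equal(as.numeric(g), 100)
  # F = theta^3 at 2 with 10% step: ((2.2^3 - 1.8^3) / 0.4) = 12.04
  g3 <- approx_gradient(function(th) th[1]^3, 2, rel_step = 0.1)
  expect_equal(as.numeric(g3), 12.04, tolerance = 1e-12)
  # a coordinate the objective ignores gets a zero component
  g2 <- approx_gradient(function(th) th[1]^2, c(3, 7))
  expect_equal(as.numeric(g2)[2], 0)
  # failing probes are flagged, not fatal
  gf <- approx_gradient(function(th) if (th[2] > 5.5) stop("boom") else th[1],
                        c(1, 5.2))
  expect_true(attr(gf, "failed")[2])
  expect_false(attr(gf, "failed")[1])
})

test_that("stage 1 recognises a fixed point immediately", {
  theta_true <- c(C_v = 30, p_a0 = 40, C_a = 1.8, R_LV = 0.9, A1 = 0.45)
  base <- init_guesses(
    generate_pseudo_patient(load_fixture("table1_nominal")$params,
                            duration = 20)$signal)
  truth <- cardiowave:::.cw_apply_theta(base, theta_true)
  target <- generate_pseudo_patient(truth, duration = 20)$signal
  s1 <- stage1_descent(target, truth, theta0 = theta_true, max_iter = 5)
  expect_true(s1$converged)
  expect_equal(s1$iterations, 0L)
  expect_lt(s1$objective$delta_mu, 1e-6)
  expect_lt(s1$objective$delta_sigma, 1e-6)
})

test_that("simplex stages never leave the objective worse than they found it", {
  fx <- load_fixture("patient1")
  target <- generate_pseudo_patient(fx$params, duration = 20)$signal
  # start stage 2 at the generating truth with only C_v perturbed +10%
  # (ties re-applied, so E_d moves with it)
  th <- c(C_v = fx$params$C_v * 1.1, p_a0 = fx$params$p_a0,
          C_a = fx$params$C_a, R_LV = fx$params$R_LV, A1 = fx$params$A1)
  start2 <- cardiowave:::.cw_apply_theta(fx$params, th)
  s2 <- stage2_simplex(target, start2, max_eval_per_par = 60)
  expect_lte(s2$objective$delta2, s2$objective$delta2_initial)
  # and the single perturbed coordinate is pulled back toward the truth
  expect_lt(abs(s2$params$C_v - fx$params$C_v) / fx$params$C_v, 0.05)
})

test_that("stage 4 skips cleanly when there is no notch to refine", {
  fx <- load_fixture("patient2")  # rebound pulse height ~8e-6: no notch
  target <- generate_pseudo_patient(fx$params, duration = 20)$signal
  s4 <- stage4_notch_refine(target, fx$params)
  expect_identical(s4$note, "skipped")
  expect_identical(unclass(s4$params), unclass(fx$params))
})

test_that("glance and tidy summarise a (short) staged fit", {
  fx <- load_fixture("patient1")
  target <- generate_pseudo_patient(fx$params, duration = 20)$signal
  fit <- fit_cardio(target, stages = 1)
  g <- glance(fit)
  expect_equal(g$n_stages, 1)
  expect_false(g$aborted)
  expect_true(g$stage1_converged)
  expect_lte(g$stage1_iterations, 35)
  td <- tidy(fit)
  expect_setequal(unique(td$stage), "stage1")
  expect_equal(nrow(td), 26)
})
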