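test_that("beat segmentation recovers amplitude and rate of a pure sinusoid", {
  sig <- cw_sine_signal()  # 90 + 30 sin(2 pi t / 0.8): 120/60 at 75 bpm
  beats <- segment_beats(sig)
  expect_gte(nrow(beats), 8)
  expect_equal(mean(beats$systolic), 120, tolerance = 1e-3)
  expect_equal(mean(beats$diastolic), 60, tolerance = 1e-3)
  expect_equal(beats$hr[1], 75, tolerance = 0.02)
  expect_true(all(beats$systolic > beats$diastolic))
  expect_true(all(beats$period > 0))
})

test_that("segmentation refuses constant or undersampled signals", {
  t <- seq(0, 5, by = 0.01)
  expect_error(segment_beats(pressure_signal(t, rep(80, length(t)))),
               "insufficient signal")
  slow <- pressure_signal(seq(0, 8, by = 0.1),
                          90 + 30 * sin(2 * pi * seq(0, 8, by = 0.1) / 0.8))
  expect_error(segment_beats(slow), "sampling rate")
})

test_that("simulated heart rate is read back to within 2 bpm", {
  sim <- cw_cached_sim("patient1", 30)
  beats <- segment_beats(signal_window(arterial_signal(sim), from = 10))
  expect_lt(abs(beats$hr[1] - 60 * 8.3706 / (2 * pi)), 2)
})

test_that("moment distances obey shift and scale identities", {
  set.seed(7)
  t <- seq(0, 5, by = 0.01)
  ref <- pressure_signal(t, 90 + 25 * sin(2 * pi * t / 0.8) + rnorm(length(t)))
  expect_equal(unlist(stat_distances(ref, ref)),
               c(delta_mu = 0, delta_sigma = 0))
  shifted <- pressure_signal(t, ref$pressure + 5)
  d <- stat_distances(shifted, ref)
  expect_equal(d$delta_mu, 5)
  expect_equal(d$delta_sigma, 0, tolerance = 1e-12)
  # doubling a zero-mean signal leaves the mean and adds sd(ref) to the sd
  zm <- pressure_signal(t, ref$pressure - mean(ref$pressure))
  doubled <- pressure_signal(t, 2 * zm$pressure)
  d2 <- stat_distances(doubled, zm)
  expect_equal(d2$delta_mu, 0, tolerance = 1e-12)
  expect_equal(d2$delta_sigma, stats::sd(zm$pressure), tolerance = 1e-12)
})

test_that("L2 distance matches closed forms and a direct quadrature oracle", {
  t <- seq(0, 4, by = 0.01)
  a <- pressure_signal(t, 80 + 10 * sin(t))
  expect_equal(l2_distance(a, a), 0)
  # constant offset d over a window of length L integrates to d * sqrt(L)
  b <- pressure_signal(t, a$pressure + 3)
  expect_equal(l2_distance(b, a, from = 1, to = 3), 3 * sqrt(2),
               tolerance = 1e-9)
  # small stored vectors against an independently coded trapezoid sum
  t10 <- seq(0, 0.9, by = 0.1)
  x <- c(5, 7, 6, 9, 8, 4, 3, 6, 7, 5)
  y <- c(4, 8, 5, 9, 9, 2, 3, 7, 6, 6)
  d2 <- (x - y)^2
  oracle <- sqrt(sum(0.1 * (utils::head(d2, -1) + utils::tail(d2, -1)) / 2))
  expect_equal(l2_distance(pressure_signal(t10, x), pressure_signal(t10, y)),
               oracle, tolerance = 1e-10)
  # disjoint supports are an error
  late <- pressure_signal(t + 100, a$pressure)
  expect_error(l2_distance(a, late), "disjoint")
})

test_that("respiratory metrics read off a constructed modulated beat series", {
  k <- 1:40
  beats <- tibble::tibble(
    beat = k, t_start = 0.8 * (k - 1), t_sys = 0.8 * (k - 1) + 0.2,
    systolic = 120 + 2.5 * sin(2 * pi * k / 5), diastolic = 70,
    period = 0.8, hr = 75
  )
  m <- respiratory_metrics(beats)
  expect_equal(m$sys_variation, 2 * 2.5 * sin(2 * pi / 5), tolerance = 1e-9)
  expect_equal(m$beats_per_breath, 5, tolerance = 0.1)
  # constant series: zero variation, undefined breath rate
  const <- dplyr::mutate(beats, systolic = 120)
  m0 <- respiratory_metrics(const)
  expect_equal(m0$sys_variation, 0)
  expect_true(is.na(m0$beats_per_breath))
  expect_error(respiratory_metrics(beats[1:4, ]), "too few beats")
})

test_that("the upstroke period estimator is unbiased to sub-sample accuracy", {
  t <- seq(0, 20, by = 0.01)
  per <- 0.7703  # deliberately incommensurate with the 10 ms grid
  sig <- pressure_signal(t, 90 + 25 * sin(2 * pi * t / per))
  expect_equal(cardiowave:::.cw_mean_period(sig, from = 1), per,
               tolerance = 1e-4)
})
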