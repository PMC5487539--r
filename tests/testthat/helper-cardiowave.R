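# Shared fixtures for the test suite. Simulations are kept short; anything
# that needs a settled waveform uses the cached runs below.

cw_cached_sim <- local({
  cache <- list()
  function(fixture, duration = 30, ...) {
    key <- paste(fixture, duration, ...)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- simulate_cardio(load_fixture(fixture)$params,
                                       duration = duration, ...)
    }
    cache[[key]]
  }
})

# A clean synthetic sinusoidal "recording": 90 + 30 sin(2 pi t / 0.8),
# i.e. 120/60 mmHg at exactly 75 bpm.
cw_sine_signal <- function(duration = 8, fs = 100, mean = 90, amp = 30,
                           period = 0.8) {
  t <- seq(0, duration, by = 1 / fs)
  pressure_signal(t, mean + amp * sin(2 * pi * t / period))
}

# Independent brute-force right-hand side: term-by-term flux balance written
# directly from the compartment picture, sharing no code with system_rhs().
cw_oracle_rhs <- function(t, y, params, events = NULL) {
  p <- params
  # elastance, written out longhand
  Phi <- p$omega0 * t - (p$c3 * p$c2 / p$omega0) * (cos(p$omega0 * t / p$c2) - 1)
  psi <- Phi - 2 * pi * floor(Phi / (2 * pi))
  act <- 0
  if (psi < 2 * pi * p$phi) act <- sin(psi / (2 * p$phi))^2
  E <- p$E_d + act * ((p$E_s0 + p$c1 * sin(p$omega0 * t / p$c2)) - p$E_d)
  pLV <- E * y[4]
  # valves
  arg <- -p$A1 * (pLV - y[1])
  Re <- p$R_e0 * (1 + p$eps1 * exp(min(arg, 700)))
  if (Re > p$R_eM) Re <- p$R_eM
  Rv <- if (y[3] >= pLV) p$R_v0 else p$R_eM
  # notch pulse (most recent event only)
  f <- 0
  if (!is.null(events) && nrow(events) > 0) {
    ev <- events[max(which(events$t_n <= t)), ]
    f <- p$c4 * exp(-p$c5 * (t - ev$t_n - p$c6 * ev$dt)^2 / ev$dt^2)
  }
  flux_LV_to_e <- (pLV - y[1]) / Re
  flux_e_to_a <- (y[1] - y[2]) / p$R_a
  flux_a_to_v <- (y[2] - y[3]) / p$R_LV
  flux_v_to_LV <- (y[3] - pLV) / Rv
  c(p_e = (flux_LV_to_e - flux_e_to_a + f) / p$C_e,
    p_a = (flux_e_to_a - flux_a_to_v) / p$C_a,
    p_v = (flux_a_to_v - flux_v_to_LV) / p$C_v,
    U = (flux_v_to_LV - flux_LV_to_e) - f)
}

# Random but valid parameter sets for property tests.
cw_random_params <- function() {
  cardio_params(
    R_e0 = runif(1, 0.003, 0.02), R_a = runif(1, 0.01, 0.08),
    R_v0 = runif(1, 0.003, 0.02), R_LV = runif(1, 0.2, 1.5),
    R_eM = runif(1, 5, 15),
    C_e = runif(1, 1, 3), C_a = runif(1, 1, 3), C_v = runif(1, 10, 60),
    E_d = runif(1, 0.02, 0.08), E_s0 = runif(1, 0.3, 3),
    c1 = runif(1, 0, 0.05), c2 = runif(1, 3, 8), c3 = runif(1, 0, 0.02),
    c4 = runif(1, 0, 500), c5 = runif(1, 1, 20), c6 = runif(1, 0.5, 7.5),
    omega0 = runif(1, 6, 11), phi = runif(1, 0.25, 0.4),
    A1 = runif(1, 0.3, 0.6), dt0 = runif(1, 0.05, 0.8)
  )
}
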