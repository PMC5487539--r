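#' Integrated cardiac phase
#'
#' The instantaneous angular heart rate is
#' `omega(t) = omega0 + c3 * sin(omega0 * t / c2)` (respiratory sinus
#' arrhythmia). Beats are delimited by the accumulated phase
#' `Phi(t) = integral of omega`, which has the closed form
#' `omega0 * t - (c3 * c2 / omega0) * (cos(omega0 * t / c2) - 1)`:
#' a new beat starts at every multiple of `2*pi`, and systole occupies the
#' first fraction `phi` of each `2*pi` of phase.
#'
#' @param t Time (s), vectorised.
#' @param params A [cardio_params()] object.
#' @return Accumulated phase (rad).
#' @export
cardiac_phase <- function(t, params) {
  params$omega0 * t -
    (params$c3 * params$c2 / params$omega0) *
      (cos(params$omega0 * t / params$c2) - 1)
}

#' Instantaneous angular heart frequency
#'
#' `omega(t) = omega0 + c3 * sin(omega0 * t / c2)`, bounded in
#' `[omega0 - c3, omega0 + c3]`.
#'
#' @inheritParams cardiac_phase
#' @return Angular frequency (rad/s), vectorised over `t`.
#' @export
angular_frequency <- function(t, params) {
  if (params$omega0 <= 0) stop("omega0 must be positive", call. = FALSE)
  params$omega0 + params$c3 * sin(params$omega0 * t / params$c2)
}

#' Ventricular activation function
#'
#' The dimensionless activation `a(t)` rises from 0 to 1 and back to 0 as
#' `sin^2(omega * (t - t0) / (2 * phi))` over the systolic fraction `phi` of
#' the beat starting at `t0`, and is 0 for the rest of the cycle (diastole).
#' For the default `phi = 1/3` the argument equals `3 * omega * (t - t0) / 2`.
#' The function is continuous at the systole-to-diastole switch.
#'
#' @param t Time (s), vectorised.
#' @param t0 Start time of the current beat (s).
#' @param omega Angular heart frequency for the beat (rad/s), positive.
#' @param phi Systolic fraction of the cycle, in (0, 1).
#' @return Activation in `[0, 1]`.
#' @export
#' @examples
#' activation(0.15, 0, 2 * pi / 0.9, 1 / 3) # mid-systole -> 1
activation <- function(t, t0, omega, phi = 1 / 3) {
  if (any(omega <= 0)) stop("omega must be positive", call. = FALSE)
  if (any(t < t0)) stop("t must not precede the beat start t0", call. = FALSE)
  psi <- omega * (t - t0)
  ifelse(psi < 2 * pi * phi, sin(psi / (2 * phi))^2, 0)
}

#' Time-varying left-ventricular elastance
#'
#' `E_LV(t) = E_d + a(t) * (E_s(t) - E_d)` with the systolic elastance
#' `E_s(t) = E_s0 + c1 * sin(omega0 * t / c2)` modulated at the breathing
#' frequency. During diastole (`a = 0`) the elastance equals `E_d`; the value
#' is always within `[E_d, E_s0 + c1]`.
#'
#' @inheritParams cardiac_phase
#' @return Elastance (mmHg/ml), vectorised over `t`.
#' @export
elastance <- function(t, params) {
  E_s <- params$E_s0 + params$c1 * sin(params$omega0 * t / params$c2)
  if (any(E_s <= params$E_d)) {
    stop("systolic elastance E_s(t) must exceed E_d (reduce |c1|)", call. = FALSE)
  }
  psi <- cardiac_phase(t, params) %% (2 * pi)
  a <- ifelse(psi < 2 * pi * params$phi, sin(psi / (2 * params$phi))^2, 0)
  params$E_d + a * (E_s - params$E_d)
}

#' Aortic valve resistance
#'
#' `R_e = R_e0 * (1 + eps1 * exp(-A1 * (p_LV - p_e)))`, capped at `R_eM`.
#' The resistance is essentially `R_e0` while the ventricle drives forward
#' flow and grows exponentially once the pressure drop reverses; the exponent
#' is clamped at 700 before exponentiation so the cap is returned instead of
#' numeric overflow.
#'
#' @param p_LV Left-ventricular pressure (mmHg).
#' @param p_e Exit-region pressure (mmHg).
#' @param params A [cardio_params()] object.
#' @return Resistance (s·mmHg/ml), in `[R_e0, R_eM]`, vectorised.
#' @export
aortic_valve_resistance <- function(p_LV, p_e, params) {
  ex <- pmin(-params$A1 * (p_LV - p_e), 700)
  pmin(params$R_e0 * (1 + params$eps1 * exp(ex)), params$R_eM)
}

#' Mitral valve resistance
#'
#' Heaviside valve at the ventricular inlet: `R_v0` while the veins are at or
#' above ventricular pressure (open, filling), `R_eM` otherwise (closed).
#' Equality counts as open, which avoids chattering on a zero-measure set.
#'
#' @param p_v Venous pressure (mmHg).
#' @param p_LV Left-ventricular pressure (mmHg).
#' @param params A [cardio_params()] object.
#' @return Resistance (s·mmHg/ml), vectorised.
#' @export
mitral_valve_resistance <- function(p_v, p_LV, params) {
  ifelse(p_v >= p_LV, params$R_v0, params$R_eM)
}

#' Dicrotic-notch rebound impulse
#'
#' Gaussian flux pulse `f(t) = c4 * exp(-c5 * (t - t_n - c6*dt)^2 / dt^2)`
#' modelling blood rebounding into the exit region as the aortic valve closes.
#' Each valve-closure event `(t_n, dt)` contributes one pulse of height `c4`
#' centred at `t_n + c6*dt`; with `mode = "latest"` only the most recent event
#' at or before `t` contributes, with `mode = "sum"` all supplied events do.
#'
#' @param t Time (s), scalar.
#' @param events A data frame with columns `t_n` (strictly increasing event
#'   times, s) and `dt` (positive closure delays, s); may have zero rows.
#' @param params A [cardio_params()] object.
#' @param mode `"latest"` (default) or `"sum"`.
#' @return Flux (ml/s), non-negative.
#' @export
notch_impulse <- function(t, events, params, mode = c("latest", "sum")) {
  mode <- match.arg(mode)
  if (is.null(events) || nrow(events) == 0) return(0)
  if (any(events$dt <= 0)) stop("event closure delays must be positive", call. = FALSE)
  if (is.unsorted(events$t_n, strictly = TRUE)) {
    stop("event times must be strictly increasing", call. = FALSE)
  }
  past <- events[events$t_n <= t, , drop = FALSE]
  if (nrow(past) == 0) return(0)
  if (mode == "latest") past <- past[nrow(past), , drop = FALSE]
  z <- (t - past$t_n - params$c6 * past$dt) / past$dt
  sum(params$c4 * exp(pmax(-params$c5 * z^2, -700)))
}

#' System right-hand side
#'
#' Time derivatives of the four-compartment state. The state is
#' `(p_e, p_a, p_v, U_LV)` where `U_LV = p_LV / E_LV(t)` is the
#' volume-like ventricular variable; integrating `U_LV` rather than `p_LV`
#' makes total stored volume `C_e*p_e + C_a*p_a + C_v*p_v + U_LV` an exact
#' invariant of the flux balance (the notch flux cancels between the exit
#' and ventricular equations). `p_LV` is recovered as `E_LV(t) * U_LV`.
#'
#' @param t Time (s), scalar.
#' @param state Numeric vector `c(p_e, p_a, p_v, U_LV)` or a one-row data
#'   frame with those columns.
#' @param events Valve-closure event log as in [notch_impulse()] (or `NULL`).
#' @param params A [cardio_params()] object.
#' @param f_mode Notch impulse mode, see [notch_impulse()].
#' @return A tibble with one row: the four time derivatives
#'   (`dp_e`, `dp_a`, `dp_v`, `dU_LV`) plus the diagnostic columns
#'   `p_LV`, `R_e`, `R_v` and `f`.
#' @export
system_rhs <- function(t, state, events = NULL, params, f_mode = "latest") {
  if (is.data.frame(state)) state <- unlist(state[1, c("p_e", "p_a", "p_v", "U_LV")])
  if (!all(is.finite(state))) {
    stop("non-finite state at t = ", format(t), call. = FALSE)
  }
  p_e <- state[[1]]; p_a <- state[[2]]; p_v <- state[[3]]; U <- state[[4]]
  E <- elastance(t, params)
  p_LV <- E * U
  R_e <- aortic_valve_resistance(p_LV, p_e, params)
  R_v <- mitral_valve_resistance(p_v, p_LV, params)
  f <- notch_impulse(t, events, params, mode = f_mode)
  Q_LVe <- (p_LV - p_e) / R_e
  Q_ea <- (p_e - p_a) / params$R_a
  Q_av <- (p_a - p_v) / params$R_LV
  Q_vLV <- (p_v - p_LV) / R_v
  tibble::tibble(
    dp_e = (Q_LVe - Q_ea + f) / params$C_e,
    dp_a = (Q_ea - Q_av) / params$C_a,
    dp_v = (Q_av - Q_vLV) / params$C_v,
    dU_LV = Q_vLV - Q_LVe - f,
    p_LV = p_LV, R_e = R_e, R_v = R_v, f = f
  )
}
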