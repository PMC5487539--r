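.cw_nevmax <- 16L
.cw_nparms <- 24L + 2L * .cw_nevmax

# Pack the parameter block for the compiled core. `events` is a data frame
# with columns t_n and dt (most recent last); only the pulses that can still
# influence times >= t_from are passed down.
.cw_parvec <- function(params, root_mode, hyst, thr, events, f_mode, t_from) {
  p <- params
  v <- numeric(.cw_nparms)
  v[1:20] <- c(p$R_e0, p$R_a, p$R_v0, p$R_LV, p$R_eM,
               p$C_e, p$C_a, p$C_v, p$E_d, p$E_s0,
               p$c1, p$c2, p$c3, p$c4, p$c5, p$c6,
               p$omega0, p$phi, p$eps1, p$A1)
  v[21] <- root_mode
  v[22] <- hyst
  v[23] <- thr
  if (!is.null(events) && nrow(events) > 0) {
    if (f_mode == "latest") {
      keep <- events[nrow(events), , drop = FALSE]
    } else {
      # a pulse is spent once t exceeds its centre by ~6 half-widths
      horizon <- events$t_n + p$c6 * events$dt + 6 * events$dt / sqrt(max(p$c5, 1e-12))
      keep <- events[horizon >= t_from, , drop = FALSE]
      if (nrow(keep) > .cw_nevmax) {
        keep <- keep[seq(nrow(keep) - .cw_nevmax + 1L, nrow(keep)), , drop = FALSE]
      }
    }
    n <- nrow(keep)
    v[24] <- n
    if (n > 0) {
      v[24 + seq_len(n)] <- keep$t_n
      v[24 + .cw_nevmax + seq_len(n)] <- keep$dt
    }
  }
  v
}

# Sign of d(p_LV - p_e)/dt at (t, y), used to classify a detected crossing.
.cw_dgdt <- function(t, y, events, params, f_mode) {
  h <- 1e-7
  Edot <- (elastance(t + h, params) - elastance(t - h, params)) / (2 * h)
  E <- elastance(t, params)
  d <- system_rhs(t, y, events, params, f_mode = f_mode)
  Edot * y[[4]] + E * d$dU_LV[[1]] - d$dp_e[[1]]
}

#' Simulate the four-compartment circulation
#'
#' Integrates the pressure dynamics from the initial pressures in `params`
#' (the ventricular state starts at `U_LV = p_LV0 / E_LV(0)`), detecting each
#' downward crossing of `p_LV - p_e` through zero. Every such crossing is an
#' aortic-valve closure event `t_n`; each event launches a Gaussian rebound
#' impulse whose closure delay is either held at `dt0` for all cycles
#' (`dt_mode = "fixed"`, the default) or updated each cycle to the measured
#' interval from `t_n` to the time the valve resistance first exceeds
#' `2 * R_e0` (`dt_mode = "adaptive"`).
#'
#' The integrator is adaptive and stiff-capable (`deSolve::lsodar`) with
#' root-finding event detection. Because the soft exponential valve admits a
#' regime where `p_LV` hovers within solver noise of `p_e`, closure detection
#' uses hysteresis: after an accepted closure the root function re-arms only
#' once `p_LV - p_e` has risen through `+hyst` (valve genuinely reopened).
#'
#' @param params A [cardio_params()] object.
#' @param duration Simulation length (s), positive.
#' @param fs_out Output sampling rate (Hz); 100 Hz resolves the notch and is
#'   a typical monitor rate.
#' @param dt_mode Closure-delay handling, `"fixed"` or `"adaptive"`.
#' @param f_mode Notch-impulse accounting: `"sum"` (all still-active pulses,
#'   the default — with fitted closure delays near a full beat a pulse peaks
#'   one or more beats after the event that launched it) or `"latest"`
#'   (only the most recent event's pulse).
#' @param rtol,atol Solver tolerances (relative; absolute, mmHg).
#' @param hyst Reopening hysteresis (mmHg) for event detection.
#' @return An object of class `cardio_sim` with elements
#'   \describe{
#'     \item{signals}{tibble `time, p_e, p_a, p_v, p_LV` at `fs_out`.}
#'     \item{events}{tibble `n, t_n, dt`: closure times and delays.}
#'     \item{params, fs, duration, dt_mode, f_mode}{run configuration.}
#'     \item{volume_drift}{max relative drift of the conserved total volume.}
#'   }
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_cardio(params_table1(), duration = 10)
#' head(sim$signals)
#' }
simulate_cardio <- function(params, duration = 30, fs_out = 100,
                            dt_mode = c("fixed", "adaptive"),
                            f_mode = c("sum", "latest"),
                            rtol = 1e-8, atol = 1e-8, hyst = 2) {
  dt_mode <- match.arg(dt_mode)
  f_mode <- match.arg(f_mode)
  validate_params(params)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (fs_out < 10) stop("fs_out must be at least 10 Hz", call. = FALSE)

  thr <- log(params$eps1) / params$A1  # p_LV - p_e at which R_e = 2*R_e0
  grid <- seq(0, duration, by = 1 / fs_out)
  y <- c(params$p_e0, params$p_a0, params$p_v0,
         params$p_LV0 / elastance(0, params))
  events <- tibble::tibble(t_n = numeric(), dt = numeric())
  pending_dt <- params$dt0

  g0 <- elastance(0, params) * y[4] - y[1] # p_LV - p_e at t = 0
  phase <- if (g0 > hyst) "open" else "closed"
  tcur <- 0
  rows <- vector("list", 64L); nrow_i <- 0L
  guard <- 0L; guard_max <- 200L + 50L * ceiling(duration)

  while (tcur < duration - 1e-10) {
    guard <- guard + 1L
    if (guard > guard_max) {
      stop("integration stalled near t = ", format(tcur),
           " (event chatter guard exceeded)", call. = FALSE)
    }
    tt <- c(tcur, grid[grid > tcur + 1e-12])
    if (length(tt) < 2) break
    root_mode <- switch(phase, open = 0, closed = 1, closing = 2)
    pv <- .cw_parvec(params, root_mode, hyst, thr, events, f_mode, tcur)
    sol <- deSolve::lsodar(
      y = y, times = tt, func = "cardiowave_derivs", parms = pv,
      dllname = "cardiowave", initfunc = "cardiowave_init",
      rootfunc = "cardiowave_root", nroot = 2L, nout = 1L,
      outnames = "p_LV", rtol = rtol, atol = atol
    )
    nrow_i <- nrow_i + 1L
    rows[[nrow_i]] <- unclass(sol)
    last <- nrow(sol)
    y <- as.numeric(sol[last, 2:5])
    if (!all(is.finite(y))) {
      stop("integration failure at t = ", format(sol[last, 1]), call. = FALSE)
    }
    troot <- attr(sol, "troot")
    if (is.null(troot) || length(troot) == 0) break
    tcur <- troot[length(troot)]
    iroot <- attr(sol, "iroot")
    which_root <- if (is.null(iroot) || !any(iroot != 0)) 1L else which(iroot != 0)[1]

    if (phase == "open") {
      if (.cw_dgdt(tcur, y, events, params, f_mode) < 0) {
        dt_n <- if (dt_mode == "fixed") params$dt0 else pending_dt
        events <- tibble::add_row(events, t_n = tcur, dt = dt_n)
        phase <- if (dt_mode == "adaptive") "closing" else "closed"
      }
    } else if (phase == "closing") {
      if (which_root == 2L) {
        # valve resistance just reached 2*R_e0: measured closure interval
        pending_dt <- max(tcur - events$t_n[nrow(events)], 1e-4)
        phase <- "closed"
      } else {
        phase <- "open"
      }
    } else {
      phase <- "open"
    }
    tcur <- tcur + 1e-8
  }

  out <- do.call(rbind, rows[seq_len(nrow_i)])
  # retain exactly the requested grid (root stops introduce off-grid rows)
  idx <- round(out[, 1] * fs_out)
  on_grid <- abs(out[, 1] - idx / fs_out) < 1e-9
  out <- out[on_grid, , drop = FALSE]
  out <- out[!duplicated(idx[on_grid]), , drop = FALSE]

  signals <- tibble::tibble(
    time = out[, 1], p_e = out[, 2], p_a = out[, 3],
    p_v = out[, 4], p_LV = out[, 6]
  )
  U <- out[, 5]
  if (any(signals$p_e < 0 | signals$p_a < 0 | signals$p_v < 0 | U < 0)) {
    stop("state validity violated: a compartment volume became negative",
         call. = FALSE)
  }
  vol <- params$C_e * signals$p_e + params$C_a * signals$p_a +
    params$C_v * signals$p_v + U
  drift <- max(abs(vol - vol[1])) / abs(vol[1])

  structure(list(
    signals = signals,
    events = tibble::tibble(n = seq_len(nrow(events)), t_n = events$t_n,
                            dt = events$dt),
    params = params, fs = fs_out, duration = duration,
    dt_mode = dt_mode, f_mode = f_mode, volume_drift = drift
  ), class = "cardio_sim")
}

#' @export
print.cardio_sim <- function(x, ...) {
  cat(sprintf("<cardio_sim> %.1f s at %g Hz, %d valve-closure events, volume drift %.2g\n",
              x$duration, x$fs, nrow(x$events), x$volume_drift))
  invisible(x)
}

#' Extract one compartment's trace as a pressure signal
#'
#' @param sim A `cardio_sim`.
#' @param compartment One of `"p_a"` (default), `"p_e"`, `"p_v"`, `"p_LV"`.
#' @return A [pressure_signal()].
#' @export
compartment_signal <- function(sim, compartment = c("p_a", "p_e", "p_v", "p_LV")) {
  compartment <- match.arg(compartment)
  pressure_signal(sim$signals$time, sim$signals[[compartment]])
}

#' @rdname compartment_signal
#' @export
arterial_signal <- function(sim) compartment_signal(sim, "p_a")

#' Plot a simulation
#'
#' All four compartment pressures against time.
#'
#' @param object A `cardio_sim`.
#' @param from,to Optional time window (s).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cardio_sim <- function(object, from = 0, to = Inf, ...) {
  df <- tidyr::pivot_longer(object$signals, -"time",
                            names_to = "compartment", values_to = "pressure")
  df <- dplyr::filter(df, .data$time >= from, .data$time <= to)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$pressure,
                                   colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "pressure (mmHg)", colour = NULL) +
    ggplot2::theme_minimal()
}
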