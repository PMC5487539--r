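#' Initial parameter guesses from a pressure recording
#'
#' Builds a full parameter set from an arterial recording and literature
#' defaults. The arterial compliance comes from the stroke-volume/pulse-
#' pressure relation `C_a = SV / (P_sys - P_dia)` with an assumed stroke
#' volume (70 ml by default; not observable from pressure alone). The exit
#' compliance is set equal to `C_a`, the venous compliance to `20 * C_a`,
#' and the elastances to the reciprocal compliances (`E_d = 1/C_v`,
#' `E_s0 = 1/C_a`). Signal-derived values: `omega0 = 2*pi*HR/60` from the
#' detected heart rate, `phi = 1/3`, `c2` from the respiratory modulation of
#' the systolic series, `p_a0` = first diastolic value, `p_v0 = p_a0/3`,
#' `p_e0 = p_LV0 = p_a0`, and `dt0 = 0.1 * T`. All other constants keep the
#' values in `base`.
#'
#' @param signal A [pressure_signal()] long enough for beat segmentation and
#'   respiratory estimation.
#' @param sv_assumed Assumed stroke volume (ml).
#' @param base Parameter set providing the remaining constants.
#' @return A validated [cardio_params()].
#' @export
init_guesses <- function(signal, sv_assumed = 70, base = params_table1()) {
  signal <- as_pressure_signal(signal)
  span <- max(signal$time) - min(signal$time)
  # mean angular rate from sub-sample upstroke times: the comparison windows
  # span many beats, so even a few-per-mille rate error de-phases the model
  # from the recording and corrupts the L2 objective
  omega0 <- 2 * pi / .cw_mean_period(signal, from = min(signal$time) + span / 3)
  # all beat-level summaries come from the portion clear of any initial
  # transient (10 beats, capped at a third of the recording)
  skip <- min(10 * 2 * pi / omega0, span / 3)
  settled <- segment_beats(signal_window(signal, from = min(signal$time) + skip))
  P_sys <- mean(settled$systolic)
  P_dia <- mean(settled$diastolic)
  pulse <- P_sys - P_dia
  if (pulse <= .Machine$double.eps^0.5 * max(P_sys, 1)) {
    stop("degenerate pulse pressure: systolic equals diastolic", call. = FALSE)
  }
  C_a <- sv_assumed / pulse
  resp <- tryCatch(respiratory_metrics(settled), error = function(e) NULL)
  c2 <- if (!is.null(resp) && is.finite(resp$beats_per_breath)) {
    resp$beats_per_breath
  } else {
    base$c2
  }
  p_a0 <- settled$diastolic[1]
  # respiratory elastance modulation as a fraction of systolic elastance,
  # from the measured relative systolic variation; kept small so the pump
  # stays positive-definite at any later (C_v, C_a) iterate
  rel_var <- if (!is.null(resp)) resp$sys_variation / (2 * P_sys) else 0.005
  c1_frac <- min(max(rel_var, 0.002), 0.02)
  vals <- unclass(base)
  vals[c("C_a", "C_e", "C_v", "E_d", "E_s0")] <-
    list(C_a, C_a, 20 * C_a, 1 / (20 * C_a), 1 / C_a)
  vals$c1 <- c1_frac / C_a
  vals[c("omega0", "phi", "c2", "dt0")] <-
    list(omega0, 1 / 3, c2, 0.1 * 2 * pi / omega0)
  vals[c("p_a0", "p_v0", "p_e0", "p_LV0")] <-
    list(p_a0, p_a0 / 3, p_a0, p_a0)
  p <- cardio_params(values = vals)
  validate_params(p)
  p
}

# The five-parameter estimation vector and its dependents. Setting theta
# updates (C_v, p_a0, C_a, R_LV, A1) plus the five tied values
# (E_d = 1/C_v, C_e = C_a, E_s0 = 1/C_a, p_e0 = p_LV0 = p_a0): ten in total.
.cw_theta_names <- c("C_v", "p_a0", "C_a", "R_LV", "A1")

.cw_apply_theta <- function(params, theta) {
  v <- unclass(params)
  v$C_v <- theta[[1]]; v$p_a0 <- theta[[2]]; v$C_a <- theta[[3]]
  v$R_LV <- theta[[4]]; v$A1 <- theta[[5]]
  v$E_d <- 1 / theta[[1]]
  v$C_e <- theta[[3]]
  v$E_s0 <- 1 / theta[[3]]
  v$p_e0 <- theta[[2]]
  v$p_LV0 <- theta[[2]]
  cardio_params(values = v)
}

# Comparison window: settle for `settle_beats` mean beats, then span
# `resp_cycles` respiratory cycles (2*pi*c2/omega0 each), clipped to the
# recording's extent (at least 3 beats are required).
.cw_fit_window <- function(params, settle_beats = 10, resp_cycles = 3,
                           signal = NULL) {
  T0 <- 2 * pi / params$omega0
  t0 <- settle_beats * T0
  W <- resp_cycles * 2 * pi * params$c2 / params$omega0
  to <- t0 + W
  if (!is.null(signal)) {
    to <- min(to, max(signal$time))
    if (to < t0 + 3 * T0) {
      stop("recording too short for the comparison window", call. = FALSE)
    }
  }
  c(from = t0, to = to)
}

# Simulate with `params` and return the arterial trace covering the window.
.cw_model_arterial <- function(params, to, fs, ...) {
  sim <- simulate_cardio(params, duration = to + 0.25, fs_out = fs, ...)
  arterial_signal(sim)
}

#' Central-difference gradient of a black-box objective
#'
#' The i-th component is
#' `(F(theta with theta_i*(1+h)) - F(theta with theta_i*(1-h))) / (2*h*theta_i)`
#' with relative step `h` (default 0.1, i.e. probes at 90% and 110% of the
#' current value). If the objective fails at a probe point the component is
#' set to 0 and flagged, so descent can fall back to the remaining
#' components.
#'
#' @param objective Function mapping a parameter vector to a scalar.
#' @param theta Numeric parameter vector (positive entries).
#' @param rel_step Relative probe step.
#' @return Numeric gradient vector with attribute `failed` (logical vector).
#' @export
approx_gradient <- function(objective, theta, rel_step = 0.1) {
  n <- length(theta)
  grad <- numeric(n)
  failed <- logical(n)
  for (i in seq_len(n)) {
    up <- theta; up[i] <- theta[i] * (1 + rel_step)
    dn <- theta; dn[i] <- theta[i] * (1 - rel_step)
    fu <- tryCatch(objective(up), error = function(e) NA_real_)
    fd <- tryCatch(objective(dn), error = function(e) NA_real_)
    if (is.finite(fu) && is.finite(fd)) {
      grad[i] <- (fu - fd) / (2 * rel_step * theta[i])
    } else {
      failed[i] <- TRUE
    }
  }
  attr(grad, "failed") <- failed
  grad
}

.cw_stage_result <- function(stage, params, objective, iterations, converged,
                             history = NULL, note = NULL) {
  list(stage = stage, params = params, objective = objective,
       iterations = iterations, converged = converged, history = history,
       note = note)
}

#' Stage 1: approximate gradient descent on signal moments
#'
#' Iterates `theta <- theta - alpha * grad(F)` on the five-parameter vector
#' `(C_v, p_a0, C_a, R_LV, A1)` (ten model values counting the tied
#' dependents). At each step the objective is the moment distance whose
#' normalised value is currently larger: `delta_mu` when
#' `delta_mu/mean(ref) > delta_sigma/sd(ref)`, else `delta_sigma`. The
#' iteration stops once both normalised distances fall below `tol`, or after
#' `max_iter` steps (non-convergence is reported, not raised).
#'
#' @param signal Reference arterial recording ([pressure_signal()]).
#' @param params Full parameter set supplying everything outside `theta`.
#' @param theta0 Start vector, default `c(50, 35, 1.5, 1.2, 0.5)`: the
#'   literature values of (C_v, C_a, R_LV, A1) plus a nominal p_a0.
#' @param alpha Step size.
#' @param max_iter Iteration cap.
#' @param tol Tolerance on the larger normalised moment distance.
#' @param rel_step Relative probe step for [approx_gradient()].
#' @param settle_beats,resp_cycles Comparison-window layout.
#' @return A stage-result list: final `params`, `objective` (tibble with
#'   `delta_mu`, `delta_sigma`), `iterations`, `converged` and a per-iteration
#'   `history` tibble.
#' @export
stage1_descent <- function(signal, params,
                           theta0 = c(C_v = 50, p_a0 = 35, C_a = 1.5,
                                      R_LV = 1.2, A1 = 0.5),
                           alpha = 0.001, max_iter = 100, tol = 0.02,
                           rel_step = 0.1, settle_beats = 10, resp_cycles = 3) {
  signal <- as_pressure_signal(signal)
  fs <- signal_fs(signal)
  win <- .cw_fit_window(params, settle_beats, resp_cycles, signal)
  ref <- signal_window(signal, win["from"], win["to"])
  ref_stats <- signal_stats(ref)
  theta <- as.numeric(theta0)
  if (any(theta <= 0)) stop("theta0 must be positive", call. = FALSE)

  moments <- function(th) {
    p <- .cw_apply_theta(params, th)
    validate_params(p)
    mod <- .cw_model_arterial(p, win["to"], fs)
    stat_distances(mod, ref)
  }
  objective_for <- function(which) {
    function(th) {
      d <- moments(th)
      if (which == "mu") d$delta_mu else d$delta_sigma
    }
  }

  history <- vector("list", max_iter + 1L)
  iterations <- 0L
  converged <- FALSE
  note <- NULL
  for (k in seq_len(max_iter + 1L)) {
    d <- tryCatch(moments(theta), error = function(e) e)
    if (inherits(d, "error")) {
      note <- paste("simulation failure mid-descent:", conditionMessage(d))
      break
    }
    dmu_n <- d$delta_mu / ref_stats$mean
    dsi_n <- d$delta_sigma / ref_stats$sd
    history[[k]] <- tibble::tibble(
      iter = k - 1L, delta_mu = d$delta_mu, delta_sigma = d$delta_sigma,
      norm_mu = dmu_n, norm_sigma = dsi_n,
      branch = if (dmu_n > dsi_n) "mu" else "sigma"
    )
    if (max(dmu_n, dsi_n) < tol) { converged <- TRUE; break }
    if (k == max_iter + 1L) break
    branch <- if (dmu_n > dsi_n) "mu" else "sigma"
    grad <- approx_gradient(objective_for(branch), theta, rel_step)
    step <- alpha * grad
    theta_new <- theta - step
    # keep the search inside the positive orthant (the model is undefined
    # otherwise); a clipped component is equivalent to a shortened step
    theta_new <- pmax(theta_new, 0.05 * theta)
    theta <- theta_new
    iterations <- k
  }
  hist <- dplyr::bind_rows(history[!vapply(history, is.null, logical(1))])
  final <- .cw_apply_theta(params, theta)
  d_final <- utils::tail(hist, 1)
  .cw_stage_result("stage1", final,
                   tibble::tibble(delta_mu = d_final$delta_mu,
                                  delta_sigma = d_final$delta_sigma),
                   iterations, converged, history = hist, note = note)
}

# Shared Nelder-Mead machinery for stages 2 and 3: minimise the windowed L2
# distance over log-transformed parameters (positivity without clipping).
# `init_step` sets the initial simplex displacement in log space: stage 3 is
# a local refinement of an already-close start, and large exploratory steps
# would slide along the objective's sloppy directions away from the
# physically meaningful optimum.
.cw_simplex <- function(signal, params, free, apply_free, settle_beats,
                        resp_cycles, max_eval_per_par = 200,
                        init_step = 0.1) {
  signal <- as_pressure_signal(signal)
  fs <- signal_fs(signal)
  win <- .cw_fit_window(params, settle_beats, resp_cycles, signal)
  ref <- signal_window(signal, win["from"], win["to"])
  obj <- function(logth) {
    p <- tryCatch({
      pp <- apply_free(params, exp(logth))
      validate_params(pp)
      pp
    }, error = function(e) NULL)
    if (is.null(p)) return(1e8)
    mod <- tryCatch(.cw_model_arterial(p, win["to"], fs),
                    error = function(e) NULL)
    if (is.null(mod)) return(1e8)
    l2_distance(mod, ref, from = win["from"], to = win["to"])
  }
  x0 <- log(free)
  f0 <- obj(x0)
  if (f0 >= 1e8) {
    stop("objective not evaluable at the stage's starting parameters",
         call. = FALSE)
  }
  opt <- stats::optim(x0, obj, method = "Nelder-Mead",
                      control = list(maxit = max_eval_per_par * length(free),
                                     reltol = 1e-4,
                                     parscale = rep(init_step / 0.1,
                                                    length(free))))
  best <- if (opt$value <= f0) exp(opt$par) else free
  list(free = best, value = min(opt$value, f0), initial = f0,
       evals = opt$counts[["function"]],
       converged = opt$convergence == 0)
}

#' Stage 2: Nelder-Mead refinement of the five significant parameters
#'
#' Derivative-free simplex minimisation of the windowed L2 distance over
#' `(C_v, p_a0, C_a, R_LV, A1)`, dependents re-tied at every evaluation.
#' The search runs in log space so all parameters stay positive.
#'
#' @inheritParams stage1_descent
#' @param max_eval_per_par Evaluation budget per free parameter.
#' @return A stage-result list (`objective` holds `delta2`).
#' @export
stage2_simplex <- function(signal, params, settle_beats = 10, resp_cycles = 3,
                           max_eval_per_par = 200) {
  free <- c(C_v = params$C_v, p_a0 = params$p_a0, C_a = params$C_a,
            R_LV = params$R_LV, A1 = params$A1)
  res <- .cw_simplex(signal, params, free,
                     function(p, th) .cw_apply_theta(p, th),
                     settle_beats, resp_cycles, max_eval_per_par)
  .cw_stage_result("stage2", .cw_apply_theta(params, res$free),
                   tibble::tibble(delta2 = res$value,
                                  delta2_initial = res$initial),
                   res$evals, res$converged)
}

# Stage-3 free set: every scalar except the measured quantities (omega0,
# phi, c2), the fixed numerical device eps1, and the inert V0.
.cw_stage3_free <- function() {
  setdiff(.cw_param_names, c("omega0", "phi", "c2", "eps1", "V0"))
}

#' Stage 3: Nelder-Mead over all free parameters, ties released
#'
#' The simplex now moves every model constant except the signal-measured
#' `omega0`, `phi` and `c2` (and the numerical device `eps1`): the
#' interdependence assumptions of the earlier stages (`E_d = 1/C_v` etc.)
#' are dropped. Convergence is reported, not required; starting this stage
#' without stages 1-2 typically fails to converge.
#'
#' @inheritParams stage2_simplex
#' @return A stage-result list (`objective` holds `delta2`).
#' @export
stage3_simplex_all <- function(signal, params, settle_beats = 10,
                               resp_cycles = 3, max_eval_per_par = 200) {
  free <- unlist(unclass(params)[.cw_stage3_free()])
  apply_free <- function(p, th) {
    v <- unclass(p)
    v[.cw_stage3_free()] <- as.list(th)
    cardio_params(values = v)
  }
  res <- .cw_simplex(signal, params, free, apply_free,
                     settle_beats, resp_cycles, max_eval_per_par,
                     init_step = 0.03)
  .cw_stage_result("stage3", apply_free(params, res$free),
                   tibble::tibble(delta2 = res$value,
                                  delta2_initial = res$initial),
                   res$evals, res$converged)
}

# Locate the dicrotic notch in a signal: the first interior local minimum of
# the beat-averaged cycle after the systolic peak. Returns NA if the dip is
# shallower than `min_depth_frac` of the pulse amplitude.
.cw_detect_notch <- function(signal, min_depth_frac = 0.01) {
  beats <- tryCatch(segment_beats(signal), error = function(e) NULL)
  if (is.null(beats) || nrow(beats) < 3) return(NA_real_)
  sig <- as_pressure_signal(signal)
  # use the median beat to suppress respiratory modulation
  b <- beats[ceiling(nrow(beats) / 2), ]
  seg <- sig[sig$time >= b$t_sys & sig$time <= b$t_start + b$period, ]
  p <- seg$pressure
  if (length(p) < 5) return(NA_real_)
  mins <- which(diff(sign(diff(p))) > 0) + 1L
  mins <- mins[mins < length(p) - 1L]
  pulse <- b$systolic - b$diastolic
  for (i in mins) {
    rebound <- max(p[i:length(p)]) - p[i]
    if (rebound >= min_depth_frac * pulse) return(seg$time[i])
  }
  NA_real_
}

#' Stage 4: coordinate refinement of the notch and respiration constants
#'
#' Automated counterpart of refining "one parameter at a time, up and down by
#' about 1%": a cyclic coordinate search over `(c4, c5, c6, c1)` accepting a
#' +/-1% move iff it reduces the L2 distance restricted to a +/-0.15 T window
#' around the detected dicrotic notch, repeated until a full pass accepts no
#' move (at most `max_passes` passes). If no notch is detectable in either
#' the recording or the model output the stage is skipped with a flag.
#'
#' @inheritParams stage2_simplex
#' @param step Relative coordinate step (default 0.01).
#' @param max_passes Pass limit.
#' @return A stage-result list; `note = "skipped"` when no notch is found.
#' @export
stage4_notch_refine <- function(signal, params, step = 0.01, max_passes = 20,
                                settle_beats = 10, resp_cycles = 3) {
  signal <- as_pressure_signal(signal)
  fs <- signal_fs(signal)
  win <- .cw_fit_window(params, settle_beats, resp_cycles, signal)
  ref <- signal_window(signal, win["from"], win["to"])
  T0 <- 2 * pi / params$omega0

  mod0 <- .cw_model_arterial(params, win["to"], fs)
  t_notch_ref <- .cw_detect_notch(ref)
  t_notch_mod <- .cw_detect_notch(signal_window(mod0, win["from"], win["to"]))
  if (is.na(t_notch_ref) && is.na(t_notch_mod)) {
    return(.cw_stage_result("stage4", params,
                            tibble::tibble(delta2_notch = NA_real_),
                            0L, TRUE, note = "skipped"))
  }
  t_notch <- if (!is.na(t_notch_ref)) t_notch_ref else t_notch_mod
  nwin <- c(max(t_notch - 0.15 * T0, win["from"]),
            min(t_notch + 0.15 * T0, win["to"]))

  obj <- function(p) {
    mod <- tryCatch(.cw_model_arterial(p, win["to"], fs),
                    error = function(e) NULL)
    if (is.null(mod)) return(Inf)
    l2_distance(mod, ref, from = nwin[1], to = nwin[2])
  }
  coords <- c("c4", "c5", "c6", "c1")
  cur <- params
  f_cur <- obj(cur)
  f_init <- f_cur
  moves <- 0L
  for (pass in seq_len(max_passes)) {
    accepted <- FALSE
    for (nm in coords) {
      for (fac in c(1 + step, 1 - step)) {
        cand <- cur
        cand[[nm]] <- cand[[nm]] * fac
        ok <- tryCatch({ validate_params(cand); TRUE },
                       error = function(e) FALSE)
        if (!ok) next
        f_cand <- obj(cand)
        if (f_cand < f_cur) {
          cur <- cand; f_cur <- f_cand
          accepted <- TRUE; moves <- moves + 1L
          break
        }
      }
    }
    if (!accepted) break
  }
  .cw_stage_result("stage4", cur,
                   tibble::tibble(delta2_notch = f_cur,
                                  delta2_notch_initial = f_init),
                   moves, TRUE)
}

#' Fit the model to an arterial recording (full pipeline)
#'
#' Runs initial guesses, then the four estimation stages in sequence:
#' moment-matching gradient descent on the five most influential parameters,
#' Nelder-Mead on the same five, Nelder-Mead over all free parameters with
#' the ties released, and the notch coordinate refinement. Deterministic
#' given its inputs: the only randomness in the whole pipeline would come
#' from noise added when generating a synthetic recording.
#'
#' @param signal Arterial recording ([pressure_signal()] or data frame with
#'   `time`/`pressure` columns).
#' @param sv_assumed Assumed stroke volume for the compliance guess (ml).
#' @param theta0 Stage-1 start for `(C_v, p_a0, C_a, R_LV, A1)`; `NULL` to
#'   derive it from [init_guesses()] instead of the default
#'   `c(50, 35, 1.5, 1.2, 0.5)`.
#' @param stages Which stages to run (subset of 1:4, in order).
#' @param settle_beats,resp_cycles Comparison-window layout: the objective
#'   windows start after `settle_beats` beats and span `resp_cycles`
#'   respiratory cycles.
#' @param max_eval_per_par Simplex budget per free parameter (stages 2-3).
#' @param verbose Print per-stage summaries.
#' @return An object of class `cardio_fit`: list with `params` (final),
#'   `init` (initial guesses), `stages` (per-stage results), `signal`, and
#'   `error` (message if a stage aborted; the partial fit is preserved).
#'   Methods: [tidy.cardio_fit()], [glance.cardio_fit()],
#'   [autoplot.cardio_fit()].
#' @export
fit_cardio <- function(signal, sv_assumed = 70,
                       theta0 = c(C_v = 50, p_a0 = 35, C_a = 1.5,
                                  R_LV = 1.2, A1 = 0.5),
                       stages = 1:4, settle_beats = 10, resp_cycles = 3,
                       max_eval_per_par = 200, verbose = FALSE) {
  signal <- as_pressure_signal(signal)
  if (nrow(signal) < 4) stop("signal too short to fit", call. = FALSE)
  init <- init_guesses(signal, sv_assumed)
  if (is.null(theta0)) {
    theta0 <- c(C_v = init$C_v, p_a0 = init$p_a0, C_a = init$C_a,
                R_LV = init$R_LV, A1 = init$A1)
  }
  params <- init
  results <- list()
  err <- NULL
  say <- function(...) if (verbose) message(sprintf(...))
  for (s in sort(stages)) {
    res <- tryCatch(switch(as.character(s),
      "1" = stage1_descent(signal, params, theta0 = theta0,
                           settle_beats = settle_beats,
                           resp_cycles = resp_cycles),
      "2" = stage2_simplex(signal, params, settle_beats, resp_cycles,
                           max_eval_per_par),
      "3" = stage3_simplex_all(signal, params, settle_beats, resp_cycles,
                               max_eval_per_par),
      "4" = stage4_notch_refine(signal, params,
                                settle_beats = settle_beats,
                                resp_cycles = resp_cycles)
    ), error = function(e) e)
    if (inherits(res, "error")) {
      err <- paste0("stage ", s, ": ", conditionMessage(res))
      break
    }
    results[[res$stage]] <- res
    params <- res$params
    say("%s: objective %s after %d iterations (converged: %s)", res$stage,
        paste(signif(unlist(res$objective), 4), collapse = "/"),
        res$iterations, res$converged)
  }
  structure(list(params = params, init = init, stages = results,
                 signal = signal, theta0 = theta0, error = err),
            class = "cardio_fit")
}

#' @export
print.cardio_fit <- function(x, ...) {
  cat("<cardio_fit> stages run:", paste(names(x$stages), collapse = ", "), "\n")
  if (!is.null(x$error)) cat("aborted:", x$error, "\n")
  print(glance.cardio_fit(x))
  invisible(x)
}

#' Tidy per-stage fit results
#'
#' @param x A `cardio_fit`.
#' @param ... Unused.
#' @return A tibble with one row per (stage, parameter) pair.
#' @export
tidy.cardio_fit <- function(x, ...) {
  purrr::map_dfr(x$stages, function(s) {
    dplyr::mutate(tidy.cardio_params(s$params), stage = s$stage, .before = 1)
  })
}

#' One-row fit summary
#'
#' @param x A `cardio_fit`.
#' @param ... Unused.
#' @return A tibble with the final objectives, iteration counts and
#'   convergence flags of the stages that ran.
#' @export
glance.cardio_fit <- function(x, ...) {
  row <- list(n_stages = length(x$stages),
              aborted = !is.null(x$error))
  for (s in x$stages) {
    obj <- s$objective
    for (nm in names(obj)) row[[paste0(s$stage, "_", nm)]] <- obj[[nm]][1]
    row[[paste0(s$stage, "_iterations")]] <- s$iterations
    row[[paste0(s$stage, "_converged")]] <- s$converged
  }
  tibble::as_tibble(row)
}

#' Plot fit overlay
#'
#' Model output at the fitted parameters overlaid on the recording, over the
#' comparison window.
#'
#' @param object A `cardio_fit`.
#' @param settle_beats,resp_cycles Window layout (as used in fitting).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cardio_fit <- function(object, settle_beats = 10, resp_cycles = 3, ...) {
  win <- .cw_fit_window(object$params, settle_beats, resp_cycles, object$signal)
  fs <- signal_fs(object$signal)
  mod <- .cw_model_arterial(object$params, win["to"], fs)
  df <- dplyr::bind_rows(
    dplyr::mutate(signal_window(object$signal, win["from"], win["to"]),
                  source = "recording"),
    dplyr::mutate(signal_window(mod, win["from"], win["to"]),
                  source = "model")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$pressure,
                                   colour = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "arterial pressure (mmHg)", colour = NULL) +
    ggplot2::theme_minimal()
}
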