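# Dependent-parameter groups: the venous compliance is tied reciprocally to
# the diastolic elastance (C_v = 1/E_d), the arterial/exit compliances to the
# baseline systolic elastance (C_a = C_e = 1/E_s0), the two valve open
# resistances to each other, and three of the four initial pressures to the
# arterial one. When a group member is scaled by k its proportional partners
# scale by k and its reciprocal partners by 1/k, so the nominal values are
# preserved and the relation's shape is honoured.
.cw_tie_groups <- list(
  E_d = list(members = c("E_d", "C_v"),
             recip = list(E_d = "C_v", C_v = "E_d")),
  E_s0 = list(members = c("E_s0", "C_a", "C_e"),
              recip = list(E_s0 = c("C_a", "C_e"), C_a = "E_s0", C_e = "E_s0"),
              prop = list(C_a = "C_e", C_e = "C_a")),
  R_e0 = list(members = c("R_e0", "R_v0"),
              prop = list(R_e0 = "R_v0", R_v0 = "R_e0")),
  p_a0 = list(members = c("p_a0", "p_e0", "p_LV0"),
              prop = list(p_a0 = c("p_e0", "p_LV0"), p_e0 = c("p_a0", "p_LV0"),
                          p_LV0 = c("p_a0", "p_e0")))
)

.cw_group_of <- function(name) {
  for (g in names(.cw_tie_groups)) {
    if (name %in% .cw_tie_groups[[g]]$members) return(g)
  }
  name
}

#' Scale one parameter (with its tied dependents) by a factor
#'
#' @param params A [cardio_params()] object.
#' @param name A scalar parameter name.
#' @param factor Multiplicative factor applied to `name`; tied proportional
#'   partners scale by the same factor and reciprocal partners by its inverse.
#'   Set `tie = FALSE` to move only the named parameter.
#' @param tie Apply the dependent-parameter ties (default `TRUE`).
#' @return A new `cardio_params` object.
#' @export
perturb_param <- function(params, name, factor, tie = TRUE) {
  if (!(name %in% names(params))) {
    stop("unknown parameter: ", name, call. = FALSE)
  }
  out <- unclass(params)
  out[[name]] <- out[[name]] * factor
  if (tie) {
    g <- .cw_group_of(name)
    if (g %in% names(.cw_tie_groups)) {
      spec <- .cw_tie_groups[[g]]
      for (nm in spec$prop[[name]]) out[[nm]] <- out[[nm]] * factor
      for (nm in spec$recip[[name]]) out[[nm]] <- out[[nm]] / factor
    }
  }
  cardio_params(values = out)
}

# Beat-boundary times of the nominal configuration, from the accumulated
# cardiac phase (beat k starts where Phi = 2*pi*k).
.cw_beat_time <- function(params, k) {
  f <- function(t) cardiac_phase(t, params) - 2 * pi * k
  upper <- 2 * pi * (k + 2) / max(params$omega0 - params$c3, 1e-6)
  stats::uniroot(f, c(0, upper), tol = 1e-10)$root
}

#' Perturb one parameter and measure the output change
#'
#' Integrates the model twice, with the chosen parameter (and its tied
#' dependents) scaled to `(1-q)` and `(1+q)` times nominal, and reports the
#' L2 distance between the two arterial pressure traces over a 20-beat window
#' placed after a 10-beat settling interval (beats 11-30 of the nominal
#' configuration). The nominal sensitivity configuration integrates with the
#' adaptive closure-delay mode, under which the initial delay `dt0` only
#' seeds the first cycle.
#'
#' @param name Scalar parameter name.
#' @param q Perturbation fraction (e.g. 0.05, 0.1, 0.2).
#' @param nominal Nominal [cardio_params()].
#' @param settle_beats,window_beats Window layout (beats of the nominal run).
#' @param fs Sampling rate for the comparison (Hz).
#' @param dt_mode,f_mode Passed to [simulate_cardio()].
#' @return A one-row tibble: `parameter`, `group`, `q`, `delta2`
#'   (mmHg·s^(1/2); `NA` with `failed = TRUE` if either run fails).
#' @export
perturb_and_compare <- function(name, q, nominal,
                                settle_beats = 10, window_beats = 20,
                                fs = 100, dt_mode = "adaptive",
                                f_mode = "sum") {
  if (q < 0) stop("q must be non-negative", call. = FALSE)
  t0 <- .cw_beat_time(nominal, settle_beats)
  t1 <- .cw_beat_time(nominal, settle_beats + window_beats)
  dur <- t1 + 0.5
  run <- function(factor) {
    p <- perturb_param(nominal, name, factor)
    validate_params(p)
    arterial_signal(simulate_cardio(p, duration = dur, fs_out = fs,
                                    dt_mode = dt_mode, f_mode = f_mode))
  }
  res <- tryCatch({
    lo <- run(1 - q)
    hi <- run(1 + q)
    list(delta2 = l2_distance(hi, lo, from = t0, to = t1), failed = FALSE)
  }, error = function(e) list(delta2 = NA_real_, failed = TRUE))
  tibble::tibble(parameter = name, group = .cw_group_of(name), q = q,
                 delta2 = res$delta2, failed = res$failed)
}

#' Parameter sensitivity ranking
#'
#' Perturbation sensitivity analysis of the arterial pressure output: every
#' scalar model parameter is scaled down and up by each fraction in `q`, the
#' model is integrated at both values (tied dependents moving with the
#' perturbed member), and parameters are ranked by the L2 distance between
#' the two resulting arterial traces. Tied groups (`C_v = 1/E_d`;
#' `C_a = C_e = 1/E_s0`; `R_v0 = R_e0`; `p_e0 = p_LV0 = p_a0`) are
#' represented by their largest-distance member, giving one row per
#' independent direction.
#'
#' @param nominal Nominal [cardio_params()]; defaults to [params_table1()].
#' @param q Perturbation fractions.
#' @param collapse_groups Represent each tied group once (default `TRUE`).
#' @param ... Passed to [perturb_and_compare()].
#' @return A tibble of class `cardio_sensitivity` with columns `parameter`,
#'   `group`, `q`, `delta2`, `failed` and `rank` (1 = most influential,
#'   per `q`).
#' @export
sensitivity_table <- function(nominal = params_table1(),
                              q = c(0.05, 0.1, 0.2),
                              collapse_groups = TRUE, ...) {
  if (length(q) == 0) stop("q must be non-empty", call. = FALSE)
  scan <- setdiff(names(nominal), "V0")
  grid <- tidyr::expand_grid(parameter = scan, q = q)
  res <- purrr::pmap_dfr(grid, function(parameter, q) {
    perturb_and_compare(parameter, q, nominal, ...)
  })
  if (collapse_groups) {
    res <- res |>
      dplyr::group_by(.data$group, .data$q) |>
      dplyr::slice_max(.data$delta2, n = 1, with_ties = FALSE, na_rm = FALSE) |>
      dplyr::ungroup()
  }
  res <- res |>
    dplyr::group_by(.data$q) |>
    dplyr::arrange(dplyr::desc(.data$delta2), .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$q, .data$rank)
  class(res) <- c("cardio_sensitivity", class(res))
  res
}

#' Plot a sensitivity table
#'
#' @param object A `cardio_sensitivity` tibble.
#' @param ... Unused.
#' @return A ggplot object (one bar panel per perturbation size).
#' @export
autoplot.cardio_sensitivity <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$parameter, .data$delta2),
                               y = .data$delta2)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~q, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = expression(delta[2] ~ "(mmHg" %.% s^{1/2} * ")")) +
    ggplot2::theme_minimal()
}
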