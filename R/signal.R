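#' Uniformly sampled pressure signal
#'
#' A `pressure_signal` is a tibble with columns `time` (s, uniform grid) and
#' `pressure` (mmHg), plus a sampling-rate attribute `fs` (Hz). It is the
#' unit of exchange between the simulator, the feature extractors and the
#' fitting pipeline.
#'
#' @param time Sample times (s), strictly increasing on a uniform grid
#'   (uniform within 1e-9 s).
#' @param pressure Pressures (mmHg), same length as `time`.
#' @return A tibble of class `pressure_signal`.
#' @export
#' @examples
#' s <- pressure_signal(seq(0, 1, by = 0.01), 90 + 20 * sin(seq(0, 1, by = 0.01)))
#' signal_fs(s)
pressure_signal <- function(time, pressure) {
  if (length(time) != length(pressure)) {
    stop("time and pressure must have the same length", call. = FALSE)
  }
  if (length(time) < 2) stop("a pressure signal needs at least 2 samples", call. = FALSE)
  dt <- diff(time)
  if (any(dt <= 0)) stop("sample times must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-9) {
    stop("sample times must be uniform within 1e-9 s", call. = FALSE)
  }
  out <- tibble::tibble(time = as.numeric(time), pressure = as.numeric(pressure))
  attr(out, "fs") <- 1 / mean(dt)
  class(out) <- c("pressure_signal", class(out))
  out
}

#' @rdname pressure_signal
#' @param x A data frame with `time` and `pressure` columns (or an object
#'   already of class `pressure_signal`).
#' @export
as_pressure_signal <- function(x) {
  if (inherits(x, "pressure_signal")) return(x)
  if (!all(c("time", "pressure") %in% names(x))) {
    stop("need columns 'time' and 'pressure'", call. = FALSE)
  }
  pressure_signal(x$time, x$pressure)
}

#' @rdname pressure_signal
#' @export
signal_fs <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) fs <- 1 / mean(diff(x$time))
  fs
}

#' Restrict a signal to a time window
#'
#' @param x A `pressure_signal`.
#' @param from,to Window bounds (s), inclusive.
#' @return A `pressure_signal` restricted to `[from, to]`.
#' @export
signal_window <- function(x, from = -Inf, to = Inf) {
  x <- as_pressure_signal(x)
  keep <- x$time >= from - 1e-12 & x$time <= to + 1e-12
  if (sum(keep) < 2) stop("window contains fewer than 2 samples", call. = FALSE)
  pressure_signal(x$time[keep], x$pressure[keep])
}

#' Resample a signal onto a reference grid
#'
#' Linear interpolation onto the sample times of `grid`; times outside the
#' support of `x` are an error.
#'
#' @param x A `pressure_signal` to resample.
#' @param grid A `pressure_signal` (or numeric vector of times) providing the
#'   target grid.
#' @return A `pressure_signal` on the target grid.
#' @export
resample_signal <- function(x, grid) {
  x <- as_pressure_signal(x)
  tt <- if (is.numeric(grid)) grid else as_pressure_signal(grid)$time
  if (min(tt) < min(x$time) - 1e-9 || max(tt) > max(x$time) + 1e-9) {
    stop("target grid extends outside the signal's time support", call. = FALSE)
  }
  pressure_signal(tt, stats::approx(x$time, x$pressure, xout = tt, rule = 2)$y)
}

#' Plot a pressure signal
#'
#' @param object A `pressure_signal`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pressure_signal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$pressure)) +
    ggplot2::geom_line(colour = "#b2182b") +
    ggplot2::labs(x = "time (s)", y = "pressure (mmHg)") +
    ggplot2::theme_minimal()
}
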