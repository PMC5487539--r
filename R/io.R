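#' Read and write waveform CSV files
#'
#' Waveforms are exchanged as two-column CSV with header `t_s,p_mmHg`.
#' Reading validates the header, numeric cells and monotone time (reporting
#' the offending line), and resamples non-uniform grids onto a uniform one
#' with a warning. A write-then-read round trip preserves values to 1e-9.
#'
#' @param path CSV file path.
#' @return A [pressure_signal()].
#' @export
read_signal_csv <- function(path) {
  if (!file.exists(path)) stop("signal file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (!identical(trimws(header), "t_s,p_mmHg")) {
    stop("line 1: expected header 't_s,p_mmHg', got '", header, "'",
         call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character")
  t <- suppressWarnings(as.numeric(raw$t_s))
  p <- suppressWarnings(as.numeric(raw$p_mmHg))
  bad <- which(!is.finite(t) | !is.finite(p))
  if (length(bad)) {
    stop("line ", bad[1] + 1L, ": non-numeric cell", call. = FALSE)
  }
  nonmono <- which(diff(t) <= 0)
  if (length(nonmono)) {
    stop("line ", nonmono[1] + 2L, ": non-monotone time", call. = FALSE)
  }
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-9) {
    warning("non-uniform time grid; resampling to the median interval",
            call. = FALSE)
    dt0 <- stats::median(dt)
    grid <- seq(t[1], t[length(t)], by = dt0)
    p <- stats::approx(t, p, xout = grid, rule = 2)$y
    t <- grid
  }
  pressure_signal(t, p)
}

#' @rdname read_signal_csv
#' @param signal A [pressure_signal()] (or coercible data frame).
#' @param digits Significant digits written (>= 12 keeps 1e-9 round trips).
#' @export
write_signal_csv <- function(signal, path, digits = 15) {
  signal <- as_pressure_signal(signal)
  lines <- c("t_s,p_mmHg",
             paste(format(signal$time, digits = digits, trim = TRUE,
                          scientific = FALSE),
                   format(signal$pressure, digits = digits, trim = TRUE,
                          scientific = FALSE),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Write a valve-event log as CSV
#'
#' Columns `n,t_n_s,dt_s`: event index, closure time, closure delay.
#'
#' @param events The `events` tibble of a `cardio_sim`.
#' @param path Output path.
#' @export
write_events_csv <- function(events, path) {
  df <- data.frame(n = events$n, t_n_s = events$t_n, dt_s = events$dt)
  utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' A single configuration object drives the simulator and all estimation
#' stages; command-line flags override configuration-file values, which
#' override these documented defaults. A copy of the effective configuration
#' is echoed alongside every CLI output so any run is reproducible from its
#' artefacts.
#'
#' @param ... Overrides of the defaults.
#' @return A named list of class `cw_config`.
#' @export
cw_config <- function(...) {
  defaults <- list(
    rtol = 1e-8,            # solver relative tolerance
    atol = 1e-8,            # solver absolute tolerance, mmHg
    fs = 100,               # sampling rate, Hz
    duration = 30,          # simulation length, s
    dt_mode = "fixed",      # closure-delay handling
    f_mode = "sum",         # notch-impulse accounting
    settle_beats = 10,      # beats discarded before any comparison window
    resp_cycles = 3,        # fitting-window length, respiratory cycles
    sens_window_beats = 20, # sensitivity comparison window, beats
    sv_assumed = 70,        # assumed stroke volume, ml
    stages = 1:4,           # estimation stages to run
    noise_sd = 0,           # pseudo-patient measurement noise, mmHg
    seed = NULL,            # RNG seed (only noise generation draws numbers)
    verbose = FALSE
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(defaults))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  defaults[names(dots)] <- dots
  structure(defaults, class = "cw_config")
}

.cw_read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(cw_config, vals)
}
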