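#' Load a packaged patient fixture
#'
#' Fitted per-patient parameter sets ship with the package together with the
#' descriptive expectations used in tests (steady systolic/diastolic pressure,
#' heart rate, whether a dicrotic notch is present, and — where stated — the
#' respiratory systolic variation). Available fixtures: `patient1` (normal
#' pressures, very small notch), `patient2` (hypotensive, fast heart rate,
#' no notch), `patient3` (normal pressures, large notch, ~5 mmHg respiratory
#' variation) and `table1_nominal` (literature constants with the package's
#' nominal initial pressures).
#'
#' @param name Fixture name.
#' @return An object of class `patient_fixture`: a list with `name`,
#'   `description`, `params` (a validated [cardio_params()]) and `expect`
#'   (a one-row tibble of expectations, or `NULL`).
#' @export
#' @examples
#' fx <- load_fixture("patient1")
#' fx$params$E_s0
load_fixture <- function(name) {
  available <- c("patient1", "patient2", "patient3", "table1_nominal")
  if (!is.character(name) || length(name) != 1 || !(name %in% available)) {
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; available: ", paste(available, collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", paste0(name, ".yaml"), package = "cardiowave",
                      mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  params <- cardio_params(values = raw$params)
  validate_params(params)
  expect <- NULL
  if (!is.null(raw$expect)) {
    e <- raw$expect
    expect <- tibble::tibble(
      systolic = e$systolic, diastolic = e$diastolic, hr = e$hr,
      notch = isTRUE(e$notch),
      resp_sys_variation = if (is.null(e$resp_sys_variation)) NA_real_ else e$resp_sys_variation,
      tol_pressure_frac = e$tol_pressure_frac, tol_hr_bpm = e$tol_hr_bpm
    )
  }
  structure(list(name = raw$name, description = raw$description,
                 params = params, expect = expect),
            class = "patient_fixture")
}

#' @export
print.patient_fixture <- function(x, ...) {
  cat("<patient_fixture> ", x$name, "\n", x$description, "\n", sep = "")
  invisible(x)
}

#' Generate a pseudo-patient arterial waveform
#'
#' Runs the forward model and returns the arterial trace with optional
#' additive i.i.d. Gaussian measurement noise, together with the generating
#' ground truth. This stands in for catheter recordings when testing the
#' feature extractors and the fitting pipeline: quasi-periodic beats whose
#' rate and systolic amplitude are modulated over a `c2`-beat respiratory
#' cycle, with a dicrotic notch whose prominence follows the notch constants.
#'
#' @param params A [cardio_params()] object (e.g. a fixture's).
#' @param duration Length of the recording (s).
#' @param fs Sampling rate (Hz).
#' @param noise_sd Measurement noise standard deviation (mmHg), >= 0.
#' @param seed RNG seed; required when `noise_sd > 0` for reproducibility.
#' @param ... Passed on to [simulate_cardio()].
#' @return An object of class `pseudo_patient`: list with `signal`
#'   (a [pressure_signal()]), `params` (the generating truth), `noise_sd`,
#'   `seed` and `sim` (the full `cardio_sim`).
#' @export
generate_pseudo_patient <- function(params, duration = 30, fs = 100,
                                    noise_sd = 0, seed = NULL, ...) {
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (noise_sd > 0 && is.null(seed)) {
    stop("a seed is required when noise_sd > 0", call. = FALSE)
  }
  sim <- simulate_cardio(params, duration = duration, fs_out = fs, ...)
  sig <- arterial_signal(sim)
  if (noise_sd > 0) {
    withr_seed <- function(seed, code) {
      old <- if (exists(".Random.seed", envir = globalenv())) {
        get(".Random.seed", envir = globalenv())
      } else NULL
      set.seed(seed)
      on.exit({
        if (is.null(old)) {
          rm(".Random.seed", envir = globalenv())
        } else {
          assign(".Random.seed", old, envir = globalenv())
        }
      })
      code()
    }
    noise <- withr_seed(seed, function() stats::rnorm(nrow(sig), 0, noise_sd))
    sig <- pressure_signal(sig$time, sig$pressure + noise)
  }
  structure(list(signal = sig, params = params, noise_sd = noise_sd,
                 seed = seed, sim = sim),
            class = "pseudo_patient")
}

#' @export
print.pseudo_patient <- function(x, ...) {
  cat(sprintf("<pseudo_patient> %.1f s at %g Hz, noise sd %g mmHg\n",
              max(x$signal$time), signal_fs(x$signal), x$noise_sd))
  invisible(x)
}
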