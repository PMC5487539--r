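#' Model parameter set
#'
#' Constructs and validates the full constant set of the four-compartment
#' circulation model, together with its four initial pressures. Pressures are
#' in mmHg, volumes in ml, resistances in s·mmHg/ml, compliances in ml/mmHg,
#' elastances in mmHg/ml, times in s and angular frequencies in rad/s.
#'
#' The compartments are the aortic exit region (`e`), the arterial tree (`a`),
#' the venous pool (`v`) and the left ventricle (`LV`). Blood flows
#' LV -> exit (aortic valve, resistance `R_e`), exit -> arteries (`R_a`),
#' arteries -> veins (systemic peripheral resistance `R_LV`) and
#' veins -> LV (mitral valve, open resistance `R_v0`). The aortic valve
#' resistance rises exponentially with the reverse pressure gradient and is
#' capped at `R_eM`; the mitral valve is a Heaviside switch between `R_v0`
#' (open) and `R_eM` (closed).
#'
#' @param ... Named scalar parameters overriding the literature defaults
#'   returned by [params_table1()]. Unknown names are an error.
#' @param values Optionally, a complete named list of parameter values
#'   (used instead of defaults + overrides).
#'
#' @return An object of class `cardio_params`: a named list with fields
#'   `R_e0, R_a, R_v0, R_LV, R_eM` (resistances), `C_e, C_a, C_v`
#'   (compliances), `E_d, E_s0` (diastolic and baseline systolic elastance),
#'   `c1` (elastance-height half-variation), `c2` (beats per breath),
#'   `c3` (angular-frequency half-variation), `c4, c5, c6` (notch impulse
#'   height, sharpness and centre position), `omega0` (mean angular heart
#'   frequency), `phi` (systolic fraction of the cycle), `eps1`
#'   (valve-softness factor), `A1` (valve-exponent gain), `dt0` (initial
#'   closure delay), `p_e0, p_a0, p_v0, p_LV0` (initial pressures) and
#'   `V0` (reference volume at zero pressure; does not enter the dynamics).
#' @export
#' @examples
#' p <- cardio_params(E_s0 = 2.5, omega0 = 8)
#' p$E_s0
cardio_params <- function(..., values = NULL) {
  if (is.null(values)) {
    values <- params_table1(as_params = FALSE)
    dots <- list(...)
    if (length(dots)) {
      bad <- setdiff(names(dots), names(values))
      if (length(bad)) {
        stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
      }
      values[names(dots)] <- dots
    }
  } else {
    values <- as.list(values)
    missing <- setdiff(.cw_param_names, names(values))
    if (length(missing)) {
      stop("missing parameter(s): ", paste(missing, collapse = ", "), call. = FALSE)
    }
    bad <- setdiff(names(values), .cw_param_names)
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    values <- values[.cw_param_names]
  }
  values <- lapply(values, as.numeric)
  structure(values, class = "cardio_params")
}

.cw_param_names <- c(
  "R_e0", "R_a", "R_v0", "R_LV", "R_eM",
  "C_e", "C_a", "C_v",
  "E_d", "E_s0",
  "c1", "c2", "c3", "c4", "c5", "c6",
  "omega0", "phi", "eps1", "A1", "dt0",
  "p_e0", "p_a0", "p_v0", "p_LV0", "V0"
)

#' Validate a parameter set
#'
#' Checks positivity of resistances, compliances and elastances, that the
#' systolic fraction lies in (0, 1), that `E_s0 > E_d` (the pump must be
#' positive-definite), that `R_e0 <= R_eM`, and `c2 >= 1`.
#'
#' @param params A [cardio_params()] object (or coercible named list).
#' @return The validated `cardio_params` object, invisibly usable in a pipe.
#' @export
validate_params <- function(params) {
  if (!inherits(params, "cardio_params")) params <- cardio_params(values = params)
  p <- params
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), logical(1))
  if (!all(num)) {
    stop("non-finite or non-scalar parameter(s): ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  }
  pos <- c("R_e0", "R_a", "R_v0", "R_LV", "R_eM", "C_e", "C_a", "C_v",
           "E_d", "E_s0", "omega0", "dt0")
  bad <- pos[vapply(pos, function(nm) p[[nm]] <= 0, logical(1))]
  if (length(bad)) {
    stop("parameter(s) must be strictly positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (p$phi <= 0 || p$phi >= 1) stop("phi must lie in (0, 1)", call. = FALSE)
  if (p$E_s0 <= p$E_d) stop("E_s0 must exceed E_d", call. = FALSE)
  if (p$R_e0 > p$R_eM) stop("R_e0 must not exceed R_eM", call. = FALSE)
  if (p$c2 < 1) stop("c2 (beats per breath) must be >= 1", call. = FALSE)
  if (p$eps1 <= 0 || p$eps1 >= 1) stop("eps1 must lie in (0, 1)", call. = FALSE)
  invisible(params)
}

#' @export
print.cardio_params <- function(x, ...) {
  cat("<cardio_params>\n")
  print(tidy.cardio_params(x), n = Inf)
  invisible(x)
}

#' Tidy a parameter set into a tibble
#'
#' @param x A `cardio_params` object.
#' @param ... Unused.
#' @return A tibble with columns `parameter` and `value`.
#' @export
tidy.cardio_params <- function(x, ...) {
  tibble::tibble(parameter = names(x), value = unlist(x, use.names = FALSE))
}

#' Literature default parameter values
#'
#' The typical constant set quoted in the compartment-modelling literature
#' for a resting adult: compliances 1.5/1.5/50 ml/mmHg, peripheral resistance
#' 1.2 s·mmHg/ml, elastances 0.06/3.0 mmHg/ml, heart rate ~72 bpm
#' (`omega0 = 7.54` rad/s), six beats per breath and a notch pulse of height
#' 500 ml/s with sharpness `4*log(100)`. Initial pressures default to
#' `p_e0 = p_a0 = p_LV0 = 35` and `p_v0 = 10` mmHg; the initial closure delay
#' defaults to a tenth of the mean heart period.
#'
#' @param as_params Return a `cardio_params` object (default) or a bare list.
#' @return A `cardio_params` object (or list).
#' @export
params_table1 <- function(as_params = TRUE) {
  v <- list(
    R_e0 = 0.016, R_a = 0.06, R_v0 = 0.016, R_LV = 1.2, R_eM = 10,
    C_e = 1.5, C_a = 1.5, C_v = 50,
    E_d = 0.06, E_s0 = 3.0,
    c1 = 0.1, c2 = 6, c3 = 0.01, c4 = 500, c5 = 4 * log(100), c6 = 7.5,
    omega0 = 7.54, phi = 1 / 3, eps1 = 1e-5, A1 = 0.5,
    dt0 = 0.1 * 2 * pi / 7.54,
    p_e0 = 35, p_a0 = 35, p_v0 = 10, p_LV0 = 35, V0 = 0
  )
  if (as_params) cardio_params(values = v) else v
}

#' Read or write a parameter file
#'
#' Parameter files are flat key/value documents (YAML or JSON, chosen by file
#' extension) whose keys are exactly the `cardio_params` field names. Unknown
#' keys are rejected.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @param params A `cardio_params` object (for writing).
#' @return `read_params()` returns a validated `cardio_params`;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported parameter file extension: .", ext, call. = FALSE)
  )
  vals <- as.list(vals)
  p <- cardio_params(values = vals)
  validate_params(p)
  p
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  validate_params(params)
  ext <- tolower(tools::file_ext(path))
  vals <- lapply(unclass(params), as.numeric)
  switch(ext,
    yaml = , yml = yaml::write_yaml(vals, path, precision = 12),
    json = jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported parameter file extension: .", ext, call. = FALSE)
  )
  invisible(path)
}
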