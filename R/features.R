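# Topographic prominence of local minima: for each candidate minimum walk
# outward until a strictly lower sample (or the signal edge) is met; the
# prominence is the lower of the two intervening maxima minus the minimum.
.cw_minima_prominence <- function(p) {
  n <- length(p)
  cand <- which(diff(sign(diff(p))) > 0) + 1L
  if (n >= 2 && p[1] < p[2]) cand <- c(1L, cand)
  if (n >= 2 && p[n] < p[n - 1]) cand <- c(cand, n)
  prom <- vapply(cand, function(i) {
    lmax <- -Inf
    j <- i - 1L
    while (j >= 1L && p[j] >= p[i]) { lmax <- max(lmax, p[j]); j <- j - 1L }
    if (j < 1L) lmax <- max(lmax, -Inf)
    rmax <- -Inf
    j <- i + 1L
    while (j <= n && p[j] >= p[i]) { rmax <- max(rmax, p[j]); j <- j + 1L }
    min(lmax, rmax) - p[i]
  }, numeric(1))
  list(idx = cand, prominence = prom)
}

#' Segment a pressure signal into beats
#'
#' Beats are delimited by diastolic minima, found as local minima whose
#' topographic prominence is at least `min_prominence` times the signal
#' range (robust to the secondary minimum created by the dicrotic notch).
#' Each beat runs from one accepted minimum to the next.
#'
#' @param signal A [pressure_signal()] (or data frame with `time`/`pressure`)
#'   spanning at least two beats, sampled at >= 20 Hz.
#' @param min_prominence Minimum prominence as a fraction of signal range.
#' @return A tibble of class `beat_table` with one row per beat:
#'   `beat`, `t_start` (s), `t_sys` (time of systolic peak, s),
#'   `systolic` and `diastolic` (mmHg), `period` (s) and `hr`
#'   (the signal-wide heart rate, 60 / mean period, bpm).
#' @export
segment_beats <- function(signal, min_prominence = 0.25) {
  signal <- as_pressure_signal(signal)
  if (signal_fs(signal) < 20) stop("sampling rate below 20 Hz", call. = FALSE)
  p <- signal$pressure
  rng <- diff(range(p))
  if (rng <= .Machine$double.eps^0.5) {
    stop("insufficient signal: no detectable beats in a constant signal",
         call. = FALSE)
  }
  mp <- .cw_minima_prominence(p)
  keep <- mp$idx[mp$prominence >= min_prominence * rng]
  # drop edge samples masquerading as minima
  keep <- keep[keep > 1L & keep < length(p)]
  if (length(keep) < 2) {
    stop("insufficient signal: fewer than 2 diastolic minima detected",
         call. = FALSE)
  }
  starts <- keep[-length(keep)]
  ends <- keep[-1]
  beats <- purrr::map2_dfr(starts, ends, function(i, j) {
    seg <- i:j
    k <- seg[which.max(p[seg])]
    tibble::tibble(
      t_start = signal$time[i],
      t_sys = signal$time[k],
      systolic = p[k],
      diastolic = min(p[seg]),
      period = signal$time[j] - signal$time[i]
    )
  })
  beats <- dplyr::mutate(beats,
    beat = dplyr::row_number(),
    hr = 60 / mean(.data$period),
    .before = 1
  )
  class(beats) <- c("beat_table", class(beats))
  beats
}

# Mean beat period from the systolic upstroke: sub-sample times at which the
# pressure crosses its own mean going up. The upstroke is the steepest part
# of the waveform, so these marks are far more precise than diastolic minima
# (which sit on a flat valley). Double crossings from a deep notch are
# removed by a minimum-separation filter.
.cw_mean_period <- function(signal, from = 0) {
  sig <- as_pressure_signal(signal)
  sig <- signal_window(sig, from = from)
  p <- sig$pressure
  m <- mean(p)
  i <- which(p[-length(p)] < m & p[-1] >= m)
  if (length(i) < 3) stop("insufficient signal: too few upstrokes to estimate the heart period",
                          call. = FALSE)
  tc <- sig$time[i] + (m - p[i]) / (p[i + 1] - p[i]) * (sig$time[i + 1] - sig$time[i])
  d <- diff(tc)
  med <- stats::median(d)
  ok <- d > 0.6 * med & d < 1.5 * med
  if (!all(ok)) {
    # merge split crossings, then re-difference over clean spans only
    d <- d[ok]
  }
  mean(d)
}

#' Signal moments
#'
#' Mean and standard deviation of a pressure signal, the two summary
#' statistics driving the first estimation stage.
#'
#' @param signal A [pressure_signal()] (or coercible data frame).
#' @return A tibble with columns `mean` and `sd` (mmHg).
#' @export
signal_stats <- function(signal) {
  signal <- as_pressure_signal(signal)
  if (nrow(signal) == 0) stop("empty signal", call. = FALSE)
  tibble::tibble(mean = mean(signal$pressure), sd = stats::sd(signal$pressure))
}

#' Moment distances between two signals
#'
#' Absolute differences of means and of standard deviations,
#' `delta_mu = |mu - mu_hat|` and `delta_sigma = |sigma - sigma_hat|`,
#' evaluated on the signals' common time window.
#'
#' @param signal,ref Two [pressure_signal()] objects with overlapping support.
#' @return A tibble with columns `delta_mu` and `delta_sigma` (mmHg).
#' @export
stat_distances <- function(signal, ref) {
  signal <- as_pressure_signal(signal)
  ref <- as_pressure_signal(ref)
  from <- max(min(signal$time), min(ref$time))
  to <- min(max(signal$time), max(ref$time))
  if (from >= to) stop("signals have disjoint time supports", call. = FALSE)
  s1 <- signal_stats(signal_window(signal, from, to))
  s2 <- signal_stats(signal_window(ref, from, to))
  tibble::tibble(delta_mu = abs(s1$mean - s2$mean),
                 delta_sigma = abs(s1$sd - s2$sd))
}

#' L2 distance between two signals
#'
#' `delta_2 = sqrt(integral (p - p_hat)^2 dt)` over a time window, using the
#' trapezoidal rule on the first signal's grid; the reference is linearly
#' resampled onto that grid if needed. Units mmHg·s^(1/2).
#'
#' @param signal,ref Two [pressure_signal()] objects.
#' @param from,to Window bounds (s); default the signals' common support.
#' @return Non-negative scalar; 0 iff the signals agree on the window.
#' @export
l2_distance <- function(signal, ref, from = NULL, to = NULL) {
  signal <- as_pressure_signal(signal)
  ref <- as_pressure_signal(ref)
  lo <- max(min(signal$time), min(ref$time))
  hi <- min(max(signal$time), max(ref$time))
  if (lo >= hi) stop("signals have disjoint time supports", call. = FALSE)
  from <- if (is.null(from)) lo else max(from, lo)
  to <- if (is.null(to)) hi else min(to, hi)
  if (from >= to) stop("empty comparison window", call. = FALSE)
  s <- signal_window(signal, from, to)
  r <- resample_signal(ref, s)
  d2 <- (s$pressure - r$pressure)^2
  tt <- s$time
  sqrt(sum(diff(tt) * (d2[-1] + d2[-length(d2)]) / 2))
}

#' Respiratory modulation metrics of a beat series
#'
#' The peak-to-peak variation of per-beat systolic pressure, and the number
#' of beats per breath estimated as the reciprocal of the dominant
#' low-frequency component (zero-padded periodogram, 2 to 30 beats/cycle) of
#' the mean-removed systolic series.
#'
#' @param beats A `beat_table` from [segment_beats()], spanning at least two
#'   respiratory cycles.
#' @param min_beats Minimum number of beats required.
#' @return A tibble with columns `sys_variation` (mmHg) and
#'   `beats_per_breath` (NA when the systolic series is constant).
#' @export
respiratory_metrics <- function(beats, min_beats = 8) {
  if (nrow(beats) < min_beats) {
    stop("too few beats (", nrow(beats), ") for respiratory metrics", call. = FALSE)
  }
  s <- beats$systolic
  variation <- max(s) - min(s)
  if (variation <= .Machine$double.eps^0.5 * max(abs(s), 1)) {
    return(tibble::tibble(sys_variation = 0, beats_per_breath = NA_real_))
  }
  # remove the mean and any settling trend so the respiratory line dominates
  k <- seq_along(s)
  x <- stats::residuals(stats::lm(s ~ k))
  nfft <- 2048L
  spec <- Mod(stats::fft(c(x, rep(0, nfft - length(x)))))[seq_len(nfft %/% 2)]
  freq <- (seq_len(nfft %/% 2) - 1) / nfft  # cycles per beat
  band <- freq >= 1 / 15 & freq <= 1 / 2    # 2-15 beats per breath
  fpeak <- freq[band][which.max(spec[band])]
  tibble::tibble(sys_variation = variation, beats_per_breath = 1 / fpeak)
}

#' Per-beat summaries of a simulation after settling
#'
#' Convenience wrapper: extract the arterial trace of a simulation, drop the
#' settling interval, segment beats, and report mean per-beat systolic and
#' diastolic pressures.
#'
#' @param sim A `cardio_sim`.
#' @param discard Initial interval to discard (s).
#' @return A tibble with `systolic`, `diastolic` (mean per-beat, mmHg),
#'   `hr` (bpm) and `n_beats`.
#' @export
steady_pressures <- function(sim, discard = 10) {
  sig <- signal_window(arterial_signal(sim), from = discard)
  beats <- segment_beats(sig)
  tibble::tibble(
    systolic = mean(beats$systolic),
    diastolic = mean(beats$diastolic),
    hr = beats$hr[1],
    n_beats = nrow(beats)
  )
}
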