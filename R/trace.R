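#' Breathing-trace generator parameters
#'
#' Parameters of the synthetic chest-height surrogate signal. Each breath is a
#' raised-cosine pulse raised to `dwell_power` (a Lujan-type waveform: for
#' `dwell_power > 1` the patient dwells longer near exhale, which is the
#' clinically typical asymmetry; `dwell_power = 1` gives a pure sinusoid).
#' Per-breath periods are drawn from a truncated normal, per-breath amplitudes
#' are modulated by a lognormal-ish factor, and a linear baseline drift plus
#' additive Gaussian sensor noise are superimposed. An optional irregular
#' episode (default length 20 s) rescales period and amplitude breath-by-breath
#' to emulate coughing / erratic breathing.
#'
#' @param period_s mean breath period, seconds.
#' @param period_sd_s per-breath period standard deviation, seconds.
#' @param amplitude_mm mean peak-to-trough surrogate amplitude, mm.
#' @param amplitude_sd_frac per-breath fractional amplitude variation.
#' @param baseline_mm resting chest height offset, mm.
#' @param drift_mm_per_min linear baseline drift, mm per minute.
#' @param noise_sd_mm additive white sensor noise, mm.
#' @param dwell_power exponent of the raised-cosine waveform (>= 1).
#' @param sample_rate_hz surrogate sampling rate, Hz.
#' @param n_bins number of respiratory bins for the ground-truth labels.
#' @param irregular `NULL`, or a list with `start_s`, `duration_s`
#'   (default 20), `period_factor_range`, `amplitude_factor_range` describing
#'   an episode of irregular breathing.
#' @return A list of class `trace_params`.
#' @export
trace_params <- function(period_s = 4, period_sd_s = 0.25,
                         amplitude_mm = 10, amplitude_sd_frac = 0.05,
                         baseline_mm = 0, drift_mm_per_min = 0.5,
                         noise_sd_mm = 0.2, dwell_power = 2,
                         sample_rate_hz = 30, n_bins = 10,
                         irregular = NULL) {
  if (period_s <= 0) stop("period_s must be positive")
  if (amplitude_mm <= 0) stop("amplitude_mm must be positive")
  if (period_sd_s < 0 || noise_sd_mm < 0 || amplitude_sd_frac < 0)
    stop("spread parameters must be nonnegative")
  if (dwell_power < 1) stop("dwell_power must be >= 1")
  if (!is.null(irregular)) {
    irregular <- modifyList(list(start_s = 40, duration_s = 20,
                                 period_factor_range = c(0.5, 1.8),
                                 amplitude_factor_range = c(0.3, 1.5)),
                            irregular)
  }
  structure(list(period_s = period_s, period_sd_s = period_sd_s,
                 amplitude_mm = amplitude_mm,
                 amplitude_sd_frac = amplitude_sd_frac,
                 baseline_mm = baseline_mm,
                 drift_mm_per_min = drift_mm_per_min,
                 noise_sd_mm = noise_sd_mm, dwell_power = dwell_power,
                 sample_rate_hz = sample_rate_hz, n_bins = as.integer(n_bins),
                 irregular = irregular),
            class = "trace_params")
}

## raised-cosine breath waveform: 1 at peak inhale (phi = 0, 1), 0 at exhale
breath_waveform <- function(phi, dwell_power) {
  ((1 + cos(2 * pi * phi)) / 2)^dwell_power
}

#' Generate a synthetic surrogate breathing trace
#'
#' Produces a uniformly sampled chest-height surrogate y(t) with ground-truth
#' respiratory phase labels. Bin 1 starts at peak inhale and the `n_bins`
#' labels advance in equal time fractions of each breath, cycling
#' `1, 2, ..., n_bins, 1, ...`.
#'
#' @param params a [trace_params] object.
#' @param duration_s trace length in seconds (must exceed one breath period).
#' @param seed integer seed; identical `(params, seed)` give identical traces.
#' @return An object of class `breathing_trace` with fields `times`,
#'   `amplitude`, `true_phase`, `breath_starts` (peak-inhale times) and
#'   `params`.
#' @export
generate_breathing_trace <- function(params, duration_s, seed = 1L) {
  stopifnot(inherits(params, "trace_params"))
  if (duration_s <= params$period_s)
    stop("duration_s must exceed one breath period")
  set.seed(seed)
  p <- params
  ## draw per-breath periods/amplitudes until duration is covered
  starts <- numeric(0)   # breath start times (peak inhale)
  periods <- numeric(0)
  amps <- numeric(0)
  t0 <- 0
  lo <- max(p$period_s - 3 * p$period_sd_s, 0.3 * p$period_s)
  hi <- p$period_s + 3 * p$period_sd_s
  while (t0 < duration_s) {
    Ti <- if (p$period_sd_s == 0) p$period_s else {
      x <- rnorm(1, p$period_s, p$period_sd_s)
      while (x < lo || x > hi) x <- rnorm(1, p$period_s, p$period_sd_s)
      x
    }
    Ai <- p$amplitude_mm * exp(rnorm(1, 0, p$amplitude_sd_frac))
    if (p$amplitude_sd_frac == 0) Ai <- p$amplitude_mm
    if (!is.null(p$irregular)) {
      ir <- p$irregular
      if (t0 >= ir$start_s && t0 < ir$start_s + ir$duration_s) {
        Ti <- Ti * runif(1, ir$period_factor_range[1], ir$period_factor_range[2])
        Ai <- Ai * runif(1, ir$amplitude_factor_range[1], ir$amplitude_factor_range[2])
      }
    }
    starts <- c(starts, t0); periods <- c(periods, Ti); amps <- c(amps, Ai)
    t0 <- t0 + Ti
  }
  ## pad a final amplitude for within-breath amplitude interpolation
  amps_next <- c(amps[-1], amps[length(amps)])

  times <- seq(0, duration_s, by = 1 / p$sample_rate_hz)
  idx <- findInterval(times, starts)
  idx[idx < 1] <- 1L
  phi <- (times - starts[idx]) / periods[idx]
  phi <- pmin(pmax(phi, 0), 1 - 1e-12)
  ## amplitude interpolated across the breath so consecutive peaks join
  A <- amps[idx] * (1 - phi) + amps_next[idx] * phi
  y <- p$baseline_mm + p$drift_mm_per_min / 60 * times +
    A * breath_waveform(phi, p$dwell_power)
  if (p$noise_sd_mm > 0) y <- y + rnorm(length(y), 0, p$noise_sd_mm)
  bins <- pmin(floor(phi * p$n_bins) + 1L, p$n_bins)

  structure(list(times = times, amplitude = y,
                 displacement = 1 - breath_waveform(phi, p$dwell_power),
                 true_phase = as.integer(bins),
                 breath_starts = starts, breath_periods = periods,
                 params = p, seed = as.integer(seed)),
            class = "breathing_trace")
}

#' @export
print.breathing_trace <- function(x, ...) {
  cat(sprintf("<breathing_trace> %.1f s at %g Hz, %d breaths, %d bins\n",
              max(x$times), x$params$sample_rate_hz,
              length(x$breath_starts), x$params$n_bins))
  invisible(x)
}

#' Detect peak-inhale times in a surrogate trace
#'
#' Peak detection on the (detrended, lightly smoothed) surrogate amplitude.
#' Used to define the retrospective ground-truth phase and to estimate
#' per-breath periods.
#'
#' @param trace a [breathing_trace] (or a list with `times` and `amplitude`).
#' @param min_period_s minimum credible breath period, seconds.
#' @return numeric vector of peak times (s).
#' @export
breath_peak_times <- function(trace, min_period_s = 1.5) {
  t <- trace$times; y <- trace$amplitude
  dt <- t[2] - t[1]
  ## detrend and smooth over ~0.2 s
  y0 <- y - (stats::lm.fit(cbind(1, t), y)$fitted.values)
  k <- max(1L, round(0.2 / dt))
  if (k %% 2L == 0L) k <- k + 1L   # odd width: zero-phase moving average
  if (k > 1) y0 <- stats::filter(y0, rep(1 / k, k), sides = 2)
  y0[is.na(y0)] <- 0
  y0 <- as.numeric(y0)
  n <- length(y0)
  ## plateau-tolerant local maxima: first sample of any flat top counts
  left <- c(-Inf, y0[-n]); right <- c(y0[-1], -Inf)
  cand <- which(y0 > left & y0 >= right)
  cand <- cand[y0[cand] >= stats::quantile(y0, 0.6)]
  if (length(cand) < 2L) stop("no detectable breathing peaks")
  ## enforce a minimum peak distance, keeping the higher peak
  keep <- logical(length(y0))
  min_gap <- max(1L, round(min_period_s / dt))
  for (i in cand[order(y0[cand], decreasing = TRUE)]) {
    lo <- max(1L, i - min_gap); hi <- min(n, i + min_gap)
    if (!any(keep[lo:hi])) keep[i] <- TRUE
  }
  peaks <- sort(which(keep))
  if (length(peaks) < 2L) stop("no detectable breathing peaks")
  ## sub-sample refinement: parabola through the three samples at the peak
  tp <- vapply(peaks, function(i) {
    if (i <= 1L || i >= n) return(t[i])
    den <- y0[i - 1] - 2 * y0[i] + y0[i + 1]
    if (abs(den) < 1e-12) return(t[i])
    t[i] + dt * 0.5 * (y0[i - 1] - y0[i + 1]) / den
  }, 0)
  sort(tp)
}

#' Retrospective ground-truth phase binning
#'
#' Assigns every sample a respiratory bin 1..`n_bins` by normalized time
#' between consecutive peak-inhale events (bin 1 starts at peak inhale). This
#' retrospective labeling is the reference against which real-time phase
#' prediction is scored.
#'
#' @param trace a [breathing_trace].
#' @param n_bins number of respiratory bins.
#' @return integer vector of bin labels, one per sample.
#' @export
retrospective_phase_bins <- function(trace, n_bins) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be >= 1")
  if (n_bins == 1L) return(rep(1L, length(trace$times)))
  peaks <- breath_peak_times(trace)
  t <- trace$times
  idx <- findInterval(t, peaks)
  periods <- diff(peaks)
  phi <- numeric(length(t))
  inside <- idx >= 1L & idx < length(peaks)
  phi[inside] <- (t[inside] - peaks[idx[inside]]) / periods[idx[inside]]
  before <- idx < 1L
  phi[before] <- ((t[before] - peaks[1]) / periods[1]) %% 1
  after <- idx >= length(peaks)
  phi[after] <- ((t[after] - peaks[length(peaks)]) / periods[length(periods)]) %% 1
  phi <- pmin(pmax(phi, 0), 1 - 1e-12)
  as.integer(pmin(floor(phi * n_bins) + 1L, n_bins))
}

## ground-truth bin and displacement of a generated trace at arbitrary times;
## falls back to nearest-sample lookup for traces without generator metadata
trace_state_at <- function(trace, t) {
  if (!is.null(trace$breath_starts)) {
    idx <- pmax(findInterval(t, trace$breath_starts), 1L)
    phi <- (t - trace$breath_starts[idx]) / trace$breath_periods[idx]
    phi <- pmin(pmax(phi, 0), 1 - 1e-12)
    nb <- trace$params$n_bins
    list(bin = as.integer(pmin(floor(phi * nb) + 1L, nb)),
         u = 1 - breath_waveform(phi, trace$params$dwell_power))
  } else {
    i <- pmin(pmax(findInterval(t, trace$times), 1L), length(trace$times))
    u <- if (!is.null(trace$displacement)) trace$displacement[i] else {
      y <- trace$amplitude
      qs <- stats::quantile(y, c(0.02, 0.98))
      pmin(pmax(1 - (y[i] - qs[1]) / max(qs[2] - qs[1], 1e-9), 0), 1)
    }
    list(bin = trace$true_phase[i], u = u)
  }
}
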