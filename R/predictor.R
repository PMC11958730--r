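#' Phase predictor configuration
#'
#' @param omega lag (s) of the surrogate lag plot.
#' @param tau system latency (s): the horizon at which phase must be known.
#' @param window_s sliding fit window (s); should span at least two breaths.
#' @param n_bins respiratory bins.
#' @return list of class `predictor_config`.
#' @export
predictor_config <- function(omega = 0.5, tau = 0.4, window_s = 10,
                             n_bins = 10) {
  if (omega <= 0) stop("omega must be positive")
  if (tau < 0) stop("tau must be nonnegative")
  if (window_s <= 0) stop("window_s must be positive")
  structure(list(omega = omega, tau = tau, window_s = window_s,
                 n_bins = as.integer(n_bins)),
            class = "predictor_config")
}

#' Streaming respiratory phase predictor
#'
#' Real-time phase estimation from a chest-height surrogate. Samples are fed
#' one at a time (no lookahead); at any moment the predictor can be queried
#' for the phase bin at `t + tau`. Internally it maintains a sliding window,
#' refits the lag-plot ellipse, tracks the elliptical angle, estimates the
#' angular speed as a robust (median) finite difference of the unwrapped
#' angle over the last second, and infers the traversal direction from the
#' sign of successive angle increments (equivalently, the cross product of
#' successive radius vectors). Because the lag-plot point `(y(t), y(t-omega))`
#' reflects the breathing state at the midpoint time `t - omega/2`, queries
#' extrapolate the angle by `speed * (tau + omega/2)`.
#'
#' The predictor also tracks the times at which the angle crosses the
#' positive major axis (peak inhale) and the implied breath period; these
#' support waveform-robust bin-entry-time estimates used by the acquisition
#' controller.
#'
#' @param cfg a [predictor_config].
#' @return An object of class `phase_predictor`: an environment with
#'   functions `feed(t, y)`, `predict_bin(at = NULL)`,
#'   `next_bin_entry(bin, after)`, `period()` and `state()`.
#' @export
phase_predictor <- function(cfg = predictor_config()) {
  stopifnot(inherits(cfg, "predictor_config"))
  e <- new.env(parent = emptyenv())
  e$cfg <- cfg
  e$t <- numeric(0); e$y <- numeric(0)
  e$model <- NULL
  e$direction <- 1
  e$speed <- NA_real_        # rad/s in traversal direction
  e$angle <- NA_real_        # current elliptical angle [0, 2pi)
  e$angle_t <- NA_real_
  e$crossings <- numeric(0)  # peak-inhale times (midpoint-corrected)
  e$ok <- FALSE              # TRUE when a valid ellipse + speed are available
  e$last_bin <- 1L
  e$refit_every <- 5L        # refit cadence in samples (~6 Hz at 30 Hz input)
  e$n_fed <- 0L

  lag_pairs <- function() {
    dt <- stats::median(diff(e$t))
    k <- max(1L, round(cfg$omega / dt))
    n <- length(e$y)
    if (n <= k + 6L) return(NULL)
    cbind(e$y[(k + 1L):n], e$y[1:(n - k)])
  }

  refit <- function() {
    pts <- lag_pairs()
    if (is.null(pts)) { e$ok <- FALSE; return(invisible()) }
    m <- tryCatch(fit_ellipse(pts), error = function(err) NULL)
    if (is.null(m) || m$semi_axes[1] < 0.25) { # flat / sub-noise signal guard (mm)
      e$ok <- FALSE
      return(invisible())
    }
    e$model <- m
    ## angle track over the last second
    dt <- stats::median(diff(e$t))
    k <- max(1L, round(cfg$omega / dt))
    n <- length(e$y)
    m_back <- min(n - k, max(4L, round(1 / dt)))
    idx <- (n - m_back + 1L):n
    ang_raw <- vapply(idx, function(i)
      ellipse_angle(m, c(e$y[i], e$y[i - k]), direction = 1), 0)
    ang_un <- unwrap_angles(ang_raw)
    d_ang <- diff(ang_un)
    if (length(d_ang) == 0 || all(d_ang == 0)) { e$ok <- FALSE; return(invisible()) }
    dir_new <- sign(stats::median(d_ang))
    if (dir_new == 0) dir_new <- e$direction
    e$direction <- dir_new
    sp <- stats::median(d_ang) / dt * dir_new   # positive in traversal sense
    if (!is.finite(sp) || sp <= 1e-3) { e$ok <- FALSE; return(invisible()) }
    e$speed <- sp
    ang_dir <- (dir_new * ang_un) %% (2 * pi)
    prev_angle <- e$angle; prev_t <- e$angle_t
    e$angle <- ang_dir[length(ang_dir)]
    e$angle_t <- e$t[n]
    ## major-axis (peak inhale) crossing tracking between refits
    if (is.finite(prev_angle) && !is.na(prev_t) && e$angle_t > prev_t) {
      adv <- (e$angle - prev_angle) %% (2 * pi)
      if (adv > 0 && adv < pi && prev_angle + adv >= 2 * pi) {
        frac <- (2 * pi - prev_angle) / adv
        t_cross <- prev_t + frac * (e$angle_t - prev_t)
        t_peak <- t_cross - cfg$omega / 2
        if (length(e$crossings) == 0 ||
            t_peak - tail(e$crossings, 1) > 0.6 * 2 * pi / e$speed)
          e$crossings <- c(tail(e$crossings, 7), t_peak)
      }
    }
    e$ok <- TRUE
    invisible()
  }

  e$feed <- function(t, y) {
    e$t <- c(e$t, t); e$y <- c(e$y, y)
    keep <- e$t >= t - cfg$window_s
    e$t <- e$t[keep]; e$y <- e$y[keep]
    e$n_fed <- e$n_fed + 1L
    if (e$n_fed %% e$refit_every == 0L) refit()
    invisible()
  }

  e$period <- function() {
    if (length(e$crossings) >= 3) {
      stats::median(diff(e$crossings))
    } else if (e$ok) 2 * pi / e$speed else NA_real_
  }

  ## predicted bin at time `at` (default now + tau); list(bin, confident, y)
  e$predict_bin <- function(at = NULL) {
    t_now <- if (length(e$t)) tail(e$t, 1) else 0
    if (is.null(at)) at <- t_now + cfg$tau
    if (!e$ok || !is.finite(e$angle)) {
      return(list(bin = e$last_bin, confident = FALSE, y = NA_real_))
    }
    ## extrapolate from the time the stored angle refers to; the lag-plot
    ## point reflects the breathing state omega/2 earlier
    horizon <- at - e$angle_t
    ang <- (e$angle + e$speed * (horizon + cfg$omega / 2)) %% (2 * pi)
    bin <- as.integer(pmin(floor(ang / (2 * pi) * cfg$n_bins) + 1L, cfg$n_bins))
    e$last_bin <- bin
    ## predicted surrogate value from the ellipse parameterization
    th <- model_param_angle(e$model, ang, e$direction)
    y_pred <- e$model$center[1] +
      e$model$semi_axes[1] * cos(th) * cos(e$model$orientation) -
      e$model$semi_axes[2] * sin(th) * sin(e$model$orientation)
    list(bin = bin, confident = TRUE, y = y_pred)
  }

  ## earliest entry time (>= `after`) of `bin`, using peak-inhale crossing
  ## times + the period estimate (time-uniform phase, waveform-robust)
  e$next_bin_entry <- function(bin, after) {
    Tp <- e$period()
    if (!e$ok || !is.finite(Tp) || length(e$crossings) < 1)
      return(NA_real_)
    t_peak <- tail(e$crossings, 1)
    target <- t_peak + (bin - 1) / cfg$n_bins * Tp
    if (target < after)
      target <- target + ceiling((after - target) / Tp) * Tp
    target
  }

  e$state <- function() {
    list(model = e$model, direction = e$direction, speed = e$speed,
         angle = e$angle, ok = e$ok, period = e$period(),
         crossings = e$crossings)
  }
  class(e) <- c("phase_predictor", "environment")
  e
}

## ellipse parameter angle giving a requested traversal-direction angle
model_param_angle <- function(model, ang_dir, direction) {
  ang <- if (direction < 0) -ang_dir else ang_dir
  ang
}

unwrap_angles <- function(a) {
  d <- diff(a)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(a[1], d))
}

#' Predict the respiratory bin at a latency horizon
#'
#' Convenience wrapper over [phase_predictor] matching the batch interface:
#' feeds the trailing history (samples at or before `t_now` only) into a
#' fresh predictor and queries the bin at `t_now + cfg$tau`. On fit failure
#' (e.g. a flat signal) the current bin is held and `confident = FALSE` is
#' returned rather than an error.
#'
#' @param history a [breathing_trace] or list with `times`/`amplitude`.
#' @param cfg a [predictor_config].
#' @param t_now current time (s); defaults to the last history sample.
#' @return list with `bin`, `confident`, and predicted surrogate value `y`.
#' @export
predict_phase <- function(history, cfg = predictor_config(), t_now = NULL) {
  if (is.null(t_now)) t_now <- max(history$times)
  sel <- history$times <= t_now
  p <- phase_predictor(cfg)
  tt <- history$times[sel]; yy <- history$amplitude[sel]
  for (i in seq_along(tt)) p$feed(tt[i], yy[i])
  p$predict_bin(t_now + cfg$tau)
}
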