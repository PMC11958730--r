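## shared fixtures: everything is generated in code at test time

## a perfectly regular, noiseless breather (the "regular" study condition)
regular_params <- function(dwell_power = 2) {
  trace_params(period_s = 4, period_sd_s = 0, amplitude_sd_frac = 0,
               drift_mm_per_min = 0, noise_sd_mm = 0,
               dwell_power = dwell_power)
}

regular_trace <- function(duration_s = 130, seed = 1, dwell_power = 2) {
  generate_breathing_trace(regular_params(dwell_power), duration_s, seed)
}

## small grids keep unit tests fast; acceptance tests use the 64^3 default
small_grid <- function() grid_spec(34, 8)

## an antialiased uniform sphere rendered on its own fine grid
sphere_volume <- function(radius = 40, mu = 0.02, n = 64, spacing = 2) {
  g <- grid_spec(n, spacing)
  gx <- g$origin[1] + (seq_len(n) - 1) * spacing
  r <- sqrt(outer(outer(gx^2, gx^2, "+"), gx^2, "+"))
  volume3d(mu * pmin(pmax((radius - r) / spacing + 0.5, 0), 1), spacing)
}

## center of mass of the thresholded bright region near an expected center
com_near <- function(vol, center, radius = 18, frac = 0.5) {
  g <- vol_grid_pub(vol)
  roi <- roi_sphere(vol, center, radius)
  d <- vol$data
  d[!roi] <- 0
  idx <- which(d >= frac * max(d), arr.ind = TRUE)
  sapply(1:3, function(a) mean((idx[, a] - 1) * g$spacing[a] + g$origin[a]))
}

vol_grid_pub <- function(v) grid_spec(dim(v$data), v$spacing, v$origin)

## lighter registration settings for unit tests
fast_reg <- function(...) {
  do.call(reg_config, modifyList(list(iterations = 200, n_samples = 30000),
                                 list(...)))
}

## a phantom small enough to sit fully inside the small test grids and the
## reduced detector field of view
compact_phantom <- function(tumor_amp = c(0, 0, 12),
                            dia_amp = c(0, 0, 20)) {
  make_phantom(list(
    body = list(center = c(0, 0, 0), semi_axes = c(100, 80, 110), mu = 0.02),
    lungs = list(
      list(center = c(-45, 0, 10), semi_axes = c(38, 50, 65), mu = 0.004),
      list(center = c(45, 0, 10), semi_axes = c(38, 50, 65), mu = 0.004)),
    tumor = list(center = c(45, 0, 0), radius = 9, mu = 0.024,
                 amplitude = tumor_amp),
    diaphragm = list(center = c(45, 0, -105), radius = 60, mu = 0.024,
                     amplitude = dia_amp)))
}

## streaming predictor run over a whole trace; returns predictions aligned
## to sample times (NA during warm-up)
run_predictor <- function(trace, cfg = predictor_config(), warmup_s = 12) {
  p <- phase_predictor(cfg)
  n <- length(trace$times)
  pred <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    p$feed(trace$times[i], trace$amplitude[i])
    if (trace$times[i] > warmup_s)
      pred[i] <- p$predict_bin(trace$times[i] + cfg$tau)$bin
  }
  pred
}

## projection subsetting without touching package internals
subset_projections_pub <- function(p, idx) {
  out <- p
  out$stack <- p$stack[, , idx, drop = FALSE]
  out$meta <- p$meta[idx, , drop = FALSE]
  out
}

zero_dvf_pub <- function(g) dvf(array(0, c(g$shape, 3)), g$spacing, g$origin)

## bare schedule with given angles, for metric arithmetic tests
new_sched_pub <- function(angles) {
  structure(data.frame(k = seq_along(angles), t_s = NA_real_,
                       angle_deg = angles, bin = NA_integer_,
                       acquired = TRUE),
            class = c("acquisition_schedule", "data.frame"))
}

sd_pool_pub <- function(dat, a, b) {
  n1 <- sum(a); n2 <- sum(b)
  sqrt(((n1 - 1) * var(dat[a]) + (n2 - 1) * var(dat[b])) / (n1 + n2 - 2))
}
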