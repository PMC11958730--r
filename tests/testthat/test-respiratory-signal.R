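## lag-plot pairs of a sampled signal
lag_pairs <- function(t, y, omega) {
  dt <- t[2] - t[1]
  k <- round(omega / dt)
  cbind(y[(k + 1):length(y)], y[1:(length(y) - k)])
}

test_that("the lag plot of a sinusoid is fitted exactly", {
  t <- seq(0, 12, by = 1 / 30)
  y <- sin(2 * pi * t / 4)
  m <- fit_ellipse(lag_pairs(t, y, 0.5))
  expect_lt(max(abs(m$center)), 1e-6)
  expect_lt(m$fit_residual, 1e-6)
  expect_gte(m$semi_axes[1], m$semi_axes[2])
  expect_true(m$orientation >= 0 && m$orientation < pi)
  ## translation equivariance
  m2 <- fit_ellipse(lag_pairs(t, y, 0.5) + 5)
  expect_equal(m2$center, m$center + 5, tolerance = 1e-6)
  expect_equal(m2$semi_axes, m$semi_axes, tolerance = 1e-6)
})

test_that("degenerate point sets are rejected as no breathing", {
  pts <- cbind(1:10, 2 * (1:10) + 3)      # collinear
  expect_error(fit_ellipse(pts), "no breathing")
  expect_error(fit_ellipse(cbind(1:4, 1:4)), "at least 6")
})

test_that("phase sectors start at the major axis and advance in order", {
  t <- seq(0, 12, by = 1 / 30)
  y <- sin(2 * pi * t / 4)
  m <- fit_ellipse(lag_pairs(t, y, 0.5))
  ## point on the positive major axis -> bin 1
  p_maj <- m$center + m$semi_axes[1] *
    c(cos(m$orientation), sin(m$orientation))
  expect_identical(phase_from_point(m, p_maj, 1, 10), 1L)
  ## over one period the emitted bins are 1..10 in cyclic order with equal
  ## dwell (+- 1 sample)
  pts <- lag_pairs(t, y, 0.5)
  n_per <- 4 * 30
  one <- pts[31:(30 + n_per), ]
  bins <- apply(one, 1, function(p) phase_from_point(m, p, 1, 10))
  runs <- rle(bins)
  interior <- runs$lengths[2:(length(runs$lengths) - 1)]
  expect_true(all(abs(interior - n_per / 10) <= 1))
  ## cyclic successor: each run is followed by the next bin modulo 10
  v <- runs$values
  expect_true(all((v[-1] - v[-length(v)]) %% 10 == 1))
  ## N_b = 2: exactly two flips per period (at the major/minor axis
  ## crossings), so one period contains 3 runs of the two sectors
  bins2 <- apply(one, 1, function(p) phase_from_point(m, p, 1, 2))
  r2 <- rle(bins2)
  expect_lte(length(r2$lengths), 4)
  expect_gte(length(r2$lengths), 3)
  expect_setequal(unique(bins2), 1:2)
})

test_that("prediction matches ground truth on a noiseless sinusoid", {
  tr <- regular_trace(60, seed = 1, dwell_power = 1)
  cfg <- predictor_config(tau = 0.4)
  pred <- run_predictor(tr, cfg)
  truth <- retrospective_phase_bins(tr, 10)
  at <- tr$times + cfg$tau
  idx_t <- round(at * tr$params$sample_rate_hz) + 1
  ok <- !is.na(pred) & idx_t <= length(truth)
  acc <- mean(pred[ok] == truth[idx_t[ok]])
  expect_gte(acc, 0.95)
})

test_that("a zero-latency query returns the current ground-truth bin", {
  tr <- regular_trace(60, seed = 1, dwell_power = 1)
  cfg <- predictor_config(tau = 0)
  pred <- run_predictor(tr, cfg)
  truth <- retrospective_phase_bins(tr, 10)
  ok <- !is.na(pred)
  expect_gte(mean(pred[ok] == truth[ok]), 0.95)
})

test_that("prediction degrades with surrogate noise but the ellipse tracks drift", {
  accs <- sapply(c(0, 0.8, 2.5), function(ns) {
    p <- trace_params(period_sd_s = 0, amplitude_sd_frac = 0,
                      drift_mm_per_min = 0, noise_sd_mm = ns, dwell_power = 1)
    tr <- generate_breathing_trace(p, 60, seed = 3)
    pred <- run_predictor(tr, predictor_config())
    truth <- retrospective_phase_bins(tr, 10)
    at_idx <- round((tr$times + 0.4) * 30) + 1
    ok <- !is.na(pred) & at_idx <= length(truth)
    mean(pred[ok] == truth[at_idx[ok]])
  })
  expect_gte(accs[1], 0.95)
  expect_gt(accs[1], accs[3])

  ## center of the fitted ellipse follows a linear baseline drift
  drift <- 30  # mm/min, exaggerated to dominate the fit
  p <- trace_params(period_sd_s = 0, amplitude_sd_frac = 0,
                    drift_mm_per_min = drift, noise_sd_mm = 0,
                    dwell_power = 1)
  tr <- generate_breathing_trace(p, 60, seed = 1)
  pp <- phase_predictor(predictor_config(window_s = 10))
  for (i in seq_along(tr$times)) pp$feed(tr$times[i], tr$amplitude[i])
  st <- pp$state()
  ## at the end of the trace the window is centered ~ t_end - 5 s
  expected <- p$baseline_mm + p$amplitude_mm / 2 +
    drift / 60 * (max(tr$times) - 5)
  expect_lt(abs(mean(st$model$center) - expected),
            0.1 * drift / 60 * max(tr$times) + 1)
})

test_that("a flat signal yields a low-confidence hold, not an error", {
  pp <- phase_predictor(predictor_config())
  for (t in seq(0, 15, by = 1 / 30)) pp$feed(t, 5)
  out <- pp$predict_bin()
  expect_false(out$confident)
  expect_true(out$bin %in% 1:10)
})

test_that("the predictor is strictly causal (no lookahead)", {
  tr <- regular_trace(40, seed = 2)
  cfg <- predictor_config()
  ## predictions collected while streaming
  p1 <- phase_predictor(cfg)
  live <- NA
  n_cut <- 900                       # query at sample 900, t = 30 s
  for (i in 1:n_cut) p1$feed(tr$times[i], tr$amplitude[i])
  live <- p1$predict_bin(tr$times[n_cut] + cfg$tau)
  ## a predictor that saw the whole trace up to the same point agrees,
  ## and future samples cannot change an already-made query
  p2 <- phase_predictor(cfg)
  for (i in seq_along(tr$times)) {
    p2$feed(tr$times[i], tr$amplitude[i])
    if (i == n_cut) stored <- p2$predict_bin(tr$times[i] + cfg$tau)
  }
  expect_identical(live$bin, stored$bin)
})
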