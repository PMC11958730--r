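test_that("degenerate parameters give a perfectly periodic trace", {
  tr <- regular_trace(40, seed = 1)
  rate <- tr$params$sample_rate_hz
  per <- tr$params$period_s * rate          # samples per breath (integer: 120)
  one <- tr$amplitude[1:per]
  for (b in 1:7) {
    expect_equal(tr$amplitude[(b * per + 1):(b * per + per)], one,
                 tolerance = 1e-12)
  }
  expect_true(all(is.finite(tr$amplitude)))
  expect_equal(unique(round(diff(tr$times), 9)), 1 / rate)
})

test_that("ground-truth phase labels cycle 1..N_b anchored at peak inhale", {
  tr <- regular_trace(60, seed = 1)
  ph <- tr$true_phase
  d <- diff(ph)
  expect_true(all(d %in% c(0L, 1L, 1L - tr$params$n_bins)))
  ## bin 1 starts at each breath start (peak inhale)
  starts <- round(tr$breath_starts * tr$params$sample_rate_hz) + 1
  starts <- starts[starts <= length(ph)]
  expect_true(all(ph[starts] == 1L))
})

test_that("the irregular episode visibly disrupts per-breath periods", {
  p <- trace_params(period_sd_s = 0.1, noise_sd_mm = 0,
                    irregular = list(start_s = 40, duration_s = 20))
  tr <- generate_breathing_trace(p, 100, seed = 5)
  peaks <- breath_peak_times(tr)
  periods <- diff(peaks)
  mid <- peaks[-length(peaks)]
  inside <- periods[mid >= 40 & mid <= 60]
  expect_gt(max(abs(inside - p$period_s)), 2 * p$period_sd_s)
})

test_that("trace generation is deterministic under the seed contract", {
  p <- trace_params()
  a <- generate_breathing_trace(p, 50, seed = 1)
  b <- generate_breathing_trace(p, 50, seed = 1)
  c <- generate_breathing_trace(p, 50, seed = 2)
  expect_identical(a$amplitude, b$amplitude)
  expect_false(identical(a$amplitude, c$amplitude))
})

test_that("invalid generator parameters are rejected", {
  expect_error(trace_params(period_s = 0), "period")
  expect_error(trace_params(amplitude_mm = -1), "amplitude")
  expect_error(generate_breathing_trace(trace_params(), 2), "duration")
})

test_that("the default phantom is valid and degenerate variants behave", {
  ph <- make_phantom()
  expect_s3_class(ph, "phantom_model")
  ## tumor of zero radius: valid, no contrast
  ph0 <- make_phantom(list(tumor = list(radius = 0)))
  v0 <- phantom_volume(ph0, 0.5, small_grid())
  ph1 <- make_phantom(list(tumor = list(radius = 1e-9, mu = 0.0201)))
  expect_s3_class(ph0, "phantom_model")
  ## tumor pushed to the lung boundary with motion beyond clearance
  expect_error(make_phantom(list(tumor = list(center = c(60, 0, 90)))),
               "lung")
  ## attenuation ordering enforced
  expect_error(make_phantom(list(body = list(mu = 0.001))), "ordering")
})

test_that("rendered phantom is deterministic and zero when attenuations are zero", {
  ph <- make_phantom()
  g <- small_grid()
  expect_identical(phantom_volume(ph, 0, g)$data, phantom_volume(ph, 0, g)$data)
  ph_zero <- make_phantom()
  ph_zero$body$mu <- 0; ph_zero$tumor$mu <- 0; ph_zero$diaphragm$mu <- 0
  for (i in seq_along(ph_zero$lungs)) ph_zero$lungs[[i]]$mu <- 0
  expect_equal(max(abs(phantom_volume(ph_zero, 0, g)$data)), 0)
})

test_that("tumor center of mass moves by the configured amplitude", {
  ph <- make_phantom()
  g <- grid_spec(64, 4)
  v0 <- phantom_volume(ph, 0, g)
  v1 <- phantom_volume(ph, 1, g)
  c0 <- com_near(v0, tumor_center(ph, 0))
  c1 <- com_near(v1, tumor_center(ph, 1))
  shift <- c1 - c0
  expect_equal(shift[3], ph$tumor$amplitude[3], tolerance = 4)  # 1 voxel
  expect_lt(abs(shift[1]), 4)
  expect_lt(abs(shift[2]), 4)
})

test_that("off-grid rendering warns about transaxial truncation", {
  ph <- make_phantom()
  expect_warning(phantom_volume(ph, 0, grid_spec(16, 4)), "truncated")
})

test_that("retrospective binning splits each cycle into equal bins", {
  tr <- regular_trace(60, seed = 1, dwell_power = 1)  # sinusoidal
  bins <- retrospective_phase_bins(tr, 10)
  ## within one full interior cycle each bin holds 10% of samples (+- 1)
  peaks <- breath_peak_times(tr)
  rate <- tr$params$sample_rate_hz
  i0 <- round(peaks[3] * rate) + 1
  i1 <- round(peaks[4] * rate)
  counts <- tabulate(bins[i0:i1], 10)
  expect_true(all(abs(counts - (i1 - i0 + 1) / 10) <= 1.5))
  ## cyclic succession invariant
  d <- diff(bins)
  expect_true(all(d %in% c(0L, 1L, -9L)))
  expect_identical(retrospective_phase_bins(tr, 1), rep(1L, length(tr$times)))
})

test_that("peak detection fails gracefully on a flat signal", {
  flat <- list(times = seq(0, 30, by = 1 / 30),
               amplitude = rep(1, 901))
  expect_error(breath_peak_times(flat), "peak")
})
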