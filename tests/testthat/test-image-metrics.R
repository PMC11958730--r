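test_that("schedule MAE is the mean absolute angular deviation", {
  mk <- function(a) new_sched_pub(a)
  expect_equal(schedule_mae(mk(c(0, 1, 2)), mk(c(0, 1, 2))), 0)
  expect_equal(schedule_mae(mk(c(1, 2, 3)), mk(c(0, 1, 2))), 1)
  expect_equal(schedule_mae(mk(c(0.5, 1, 2.5)), mk(c(0, 1, 2))), 1 / 3)
  ## exactly linear in a uniform offset
  base <- runif(50) * 200
  for (off in c(0.3, 1.7)) {
    expect_equal(schedule_mae(mk(base + off), mk(base)), off)
  }
  expect_error(schedule_mae(mk(1:4), mk(1:5)), "lengths differ")
})

test_that("interbin separation extracts per-bin angular gaps", {
  s <- ideal_schedule(scan_protocol(200, 10, mode = "STO"))
  gaps <- interbin_separation(s)
  expect_length(gaps, 10)
  expect_true(all(abs(unlist(gaps) - 10) < 1e-9))
  ## one projection per bin: no gaps
  s1 <- ideal_schedule(scan_protocol(10, 10, mode = "STO"))
  expect_true(all(lengths(interbin_separation(s1)) == 0))
})

test_that("CNR follows the pooled-deviation formula", {
  g <- grid_spec(16, 4)
  dat <- array(0, c(16, 16, 16))
  roi_a <- array(FALSE, c(16, 16, 16)); roi_a[1:8, , ] <- TRUE
  roi_b <- !roi_a
  ## construct exact means and pooled deviations
  dat[roi_a] <- 100 + rep(c(-10, 10), length.out = sum(roi_a))
  dat[roi_b] <- 50 + rep(c(-10, 10), length.out = sum(roi_b))
  v <- volume3d(dat, 4)
  sdev <- sqrt(10^2 * sum(roi_a) / (sum(roi_a) + sum(roi_b) - 2) +
                 10^2 * (sum(roi_b) - 2) / (sum(roi_a) + sum(roi_b) - 2))
  expect_equal(cnr(v, roi_a, roi_b), 50 / sd_pool_pub(dat, roi_a, roi_b),
               tolerance = 1e-10)
  ## identical statistics -> zero
  dat2 <- dat; dat2[roi_b] <- dat2[roi_a]
  expect_equal(cnr(volume3d(dat2, 4), roi_a, roi_b), 0)
  expect_error(cnr(v, roi_a, array(FALSE, c(16, 16, 16))), "empty")
  expect_error(cnr(v, roi_a, roi_a), "disjoint")
})

test_that("CNR estimates the known population value on Gaussian ROIs", {
  set.seed(7)
  g <- grid_spec(16, 4)
  dat <- array(0, c(16, 16, 16))
  roi_a <- array(FALSE, c(16, 16, 16)); roi_a[, , 1:4] <- TRUE   # 1024 > 500
  roi_b <- array(FALSE, c(16, 16, 16)); roi_b[, , 9:12] <- TRUE
  dat[roi_a] <- rnorm(sum(roi_a), 0.02, 0.01)
  dat[roi_b] <- rnorm(sum(roi_b), 0.05, 0.01)
  expect_equal(cnr(volume3d(dat, 4), roi_a, roi_b), -3.0, tolerance = 0.3)
})

test_that("TIW recovers known logistic edge widths", {
  n <- 64; sp <- 2
  gz <- ((1:n) - (n + 1) / 2) * sp
  for (s_vox in c(1, 2, 4)) {
    s_mm <- s_vox * sp
    prof <- 1 / (1 + exp(-gz / s_mm))
    dat <- array(rep(prof, each = n * n), c(n, n, n))  # varies along z
    v <- volume3d(0.02 * dat, sp)
    w <- tiw(v, list(center = c(0, 0, 0), direction = c(0, 0, 1),
                     n_along = 60, n_across = 5))
    expect_equal(as.numeric(w), 2 * log(9) * s_mm,
                 tolerance = 0.05 * 2 * log(9) * s_mm)
  }
  ## an ideal step edge fits within the resolution bound
  step <- array(rep(as.numeric(gz > 0), each = n * n), c(n, n, n))
  ws <- tiw(volume3d(step, sp), list(center = c(0, 0, 0),
                                     direction = c(0, 0, 1),
                                     n_along = 30, n_across = 3))
  expect_lte(as.numeric(ws), 2 * sp)
})

test_that("TIW grows monotonically with blur and rejects incoherent data", {
  n <- 48; sp <- 2
  gz <- ((1:n) - (n + 1) / 2) * sp
  widths <- sapply(c(1, 2.5, 5), function(s_mm) {
    prof <- 1 / (1 + exp(-gz / s_mm))
    dat <- array(rep(prof, each = n * n), c(n, n, n))
    as.numeric(tiw(volume3d(dat, sp),
                   list(center = c(0, 0, 0), direction = c(0, 0, 1),
                        n_along = 40, n_across = 3)))
  })
  expect_true(all(diff(widths) > 0))
  set.seed(1)
  noise <- volume3d(array(rnorm(n^3), c(n, n, n)), sp)
  expect_error(tiw(noise, list(center = c(0, 0, 0), direction = c(0, 0, 1),
                               n_along = 40, n_across = 5)),
               "no coherent interface")
})

test_that("dose reduction reproduces the protocol bookkeeping", {
  expect_equal(round(dose_reduction(600, 1320)), 55)
  expect_equal(round(dose_reduction(200, 1320)), 85)
  expect_equal(dose_reduction(600, 1320), 100 * (1 - 600 / 1320))
  expect_equal(dose_reduction(1320, 1320), 0)
  expect_error(dose_reduction(100, 0), "positive")
})

test_that("motion robustness reports masked displacement statistics", {
  ph <- make_phantom()
  g <- grid_spec(52, 5)
  ref <- phantom_volume(ph, 0, g)
  mask <- roi_sphere(g, c(60, 0, 10), 9)
  ## identical inputs: negligible displacement
  r0 <- motion_robustness(ref, ref, mask, fast_reg())
  expect_lt(r0$total_mean_mm, 0.5 * min(g$spacing))
  ## known 3 mm shift: total displacement ~ 3 mm within a voxel
  shift <- array(0, c(52, 52, 52, 3)); shift[, , , 3] <- -3
  moved <- warp_volume(ref, dvf(shift, 5))
  r3 <- motion_robustness(moved, ref, mask, fast_reg())
  expect_equal(r3$total_mean_mm, 3, tolerance = min(g$spacing))
  expect_identical(r3$n_voxels, sum(mask))
})
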