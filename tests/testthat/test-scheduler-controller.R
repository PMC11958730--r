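test_that("the ideal schedule interleaves angle and phase evenly", {
  p600 <- scan_protocol(600, 10, mode = "STO")
  s600 <- ideal_schedule(p600)
  gaps <- unlist(interbin_separation(s600))
  expect_equal(unique(round(gaps, 9)), 200 / 60)        # 3.33 deg
  expect_equal(round(200 / 60, 1), 3.3)

  p200 <- scan_protocol(200, 10, mode = "STO")
  s200 <- ideal_schedule(p200)
  expect_equal(unique(round(unlist(interbin_separation(s200)), 9)), 10)
  expect_identical(s200$bin, rep(1:10, 20))
  expect_equal(diff(s200$angle_deg), rep(1, 199))

  ## one projection per bin: consecutive spacing arc/N_b
  p10 <- scan_protocol(10, 10, mode = "STO")
  s10 <- ideal_schedule(p10)
  expect_equal(diff(s10$angle_deg), rep(20, 9))
  expect_error(scan_protocol(201, 10, mode = "STO"), "divisible")
})

test_that("the conventional schedule is evenly spaced in angle and time", {
  p <- scan_protocol(1320, mode = "conventional")
  s <- conventional_schedule(p)
  th <- unique(round(diff(s$angle_deg), 9))
  expect_equal(th, 200 / 1320)
  expect_lt(th, 0.2)
  dt <- unique(round(diff(s$t_s), 9))
  expect_equal(dt, round(240 / 1320, 9))
  expect_equal(240 / 1320, 1 / 5.5, tolerance = 1e-12)
  expect_true(all(is.na(s$bin)))

  s1 <- conventional_schedule(scan_protocol(1, mode = "conventional"))
  expect_equal(s1$angle_deg, 200)
  expect_equal(s1$t_s, 240)
})

test_that("control_step gates on the required bin and paces to the target", {
  p <- scan_protocol(200, 10, mode = "STO")
  ## on track: at 9 deg moving at pace, next target k*=10 (bin 10) in 0.4 s
  st <- list(time = 10, angle = 9.0, speed = 2.5)
  cmd <- control_step(st, predicted_bin = 10L, progress = 10L, p,
                      t_acquire = 10.4)
  expect_true(cmd$gate_open)
  expect_equal(cmd$speed_setpoint, 2.5, tolerance = 0.1)
  expect_false(cmd$saturated)
  ## wrong predicted bin: gate shut
  cmd2 <- control_step(st, predicted_bin = 3L, progress = 10L, p,
                       t_acquire = 10.4)
  expect_false(cmd2$gate_open)
  ## unreachable target: saturate at v_max and flag
  cmd3 <- control_step(list(time = 0, angle = 0, speed = 0), 1L, 1L, p,
                       t_acquire = 0.1)
  expect_equal(cmd3$speed_setpoint, p$v_max)
  expect_true(cmd3$saturated)
  ## commanded speed never below the abort threshold
  cmd4 <- control_step(list(time = 0, angle = 5, speed = 0.4), 1L, 1L, p,
                       t_acquire = 4)
  expect_gte(cmd4$speed_setpoint, p$v_abort)
})

test_that("constraint validation flags reversals, speeding and acceleration", {
  p <- scan_protocol(200, 10, mode = "STO")
  tgrid <- seq(0, 2, by = 1 / 30)
  ok <- data.frame(time = tgrid, angle = 2 * tgrid, speed = 2)
  expect_identical(nrow(validate_constraints(ok, p)), 0L)

  rev <- ok; rev$angle[20] <- rev$angle[19] - 0.5
  r <- validate_constraints(rev, p)
  expect_identical(sum(r$type == "reversal"), 1L)

  fast <- ok; fast$speed[10] <- 7
  expect_true("speed" %in% validate_constraints(fast, p)$type)

  jump <- ok; jump$speed <- c(rep(0, 30), rep(6, length(tgrid) - 30))
  expect_true("acceleration" %in% validate_constraints(jump, p)$type)

  slow <- data.frame(time = seq(0, 8, by = 1 / 30), angle = 0, speed = 0.1)
  slow$angle <- cumsum(slow$speed) / 30
  expect_true("abort" %in% validate_constraints(slow, p)$type)
})

test_that("trajectories emitted by the closed-loop controller are compliant", {
  p <- scan_protocol(60, 10, mode = "STO")
  ph <- make_phantom()
  for (seed in 1:3) {
    tr <- generate_breathing_trace(trace_params(), 60, seed = seed)
    sim <- simulate_scan(ph, tr, p, scan_geometry(), predictor_config(),
                         small_grid(), project = FALSE)
    rep <- validate_constraints(sim$trajectory, p, sim$schedule)
    expect_identical(nrow(rep), 0L)
  }
})

test_that("a missed bin window is retargeted without breaking bin order", {
  ## irregular breathing forces misses; the target sequence still follows
  ## the cyclic ideal order and never acquires more than N_p projections
  p <- scan_protocol(100, 10, mode = "STO")
  tr <- generate_breathing_trace(
    trace_params(irregular = list(start_s = 30, duration_s = 20)), 120,
    seed = 11)
  sim <- simulate_scan(make_phantom(), tr, p, scan_geometry(),
                       predictor_config(), small_grid(), project = FALSE)
  expect_lte(nrow(sim$schedule), 100)
  if (!sim$aborted) {
    expect_identical(nrow(sim$schedule), 100L)
    ## angles are strictly nondecreasing (unidirectional)
    expect_true(all(diff(sim$schedule$angle_deg) >= -1e-9))
  }
})
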