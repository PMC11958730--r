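## a small STO-structured scan of the phantom, shared across tests
local_sto_scan <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- make_phantom()
      g <- small_grid()
      geom <- scan_geometry(det_rows = 48, det_cols = 64, det_pitch = 6)
      ang <- seq(1, 200, length.out = 60)
      u <- sapply(rep(1:10, 6), function(j)
        stocbct:::bin_displacement(trace_params(), j, 10))
      stack <- array(0, c(64, 48, 60))
      for (uu in unique(u)) {
        idx <- which(u == uu)
        stack[, , idx] <-
          forward_project(phantom_volume(ph, uu, g), geom, ang[idx])$stack
      }
      d <- projection_set(stack, ang, geom, bins = rep(1:10, 6))
      cache <<- list(d = d, g = g, ph = ph)
    }
    cache
  }
})

test_that("affine intensity matching is exact and matches normal equations", {
  g <- grid_spec(12, 4)
  set.seed(2)
  xs <- volume3d(array(rnorm(12^3), c(12, 12, 12)), 4)
  expect_equal(unclass(affine_scale(xs, xs))[c("a", "b")], list(a = 0, b = 1),
               tolerance = 1e-12)
  xt <- volume3d(2 * xs$data + 3, 4)
  sc <- affine_scale(xs, xt)
  expect_equal(sc$a, 3, tolerance = 1e-10)
  expect_equal(sc$b, 2, tolerance = 1e-10)
  ## random pair vs explicit least-squares solve
  xt2 <- volume3d(array(rnorm(12^3), c(12, 12, 12)), 4)
  sc2 <- affine_scale(xs, xt2)
  X <- cbind(1, as.numeric(xs$data))
  beta <- solve(crossprod(X), crossprod(X, as.numeric(xt2$data)))
  expect_equal(sc2$a, beta[1], tolerance = 1e-10)
  expect_equal(sc2$b, beta[2], tolerance = 1e-10)
  ## constant input falls back with a flag
  xc <- volume3d(array(1, c(12, 12, 12)), 4)
  scc <- affine_scale(xc, xt2)
  expect_true(scc$degenerate)
  expect_equal(scc$b, 1)
  expect_equal(scc$a, mean(xt2$data - 1), tolerance = 1e-12)
})

test_that("simulated bin projections reproduce the acquired metadata", {
  sc <- local_sto_scan()
  fdk <- reconstruct_fdk(sc$d, sc$g)
  ds <- simulate_bin_projections(fdk, sc$d)
  expect_length(ds, 10)
  for (j in c(1, 5, 10)) {
    expect_equal(ds[[paste0("bin", j)]]$meta$angle_deg,
                 sc$d$meta$angle_deg[sc$d$meta$bin == j])
  }
  z <- volume3d(array(0, dim(fdk$data)), fdk$spacing, fdk$origin)
  dz <- simulate_bin_projections(z, sc$d)
  expect_equal(max(abs(dz$bin1$stack)), 0)
})

test_that("MKB collapses to the blurred reconstruction for a static phantom", {
  ph <- compact_phantom(c(0, 0, 0), c(0, 0, 0))
  g <- grid_spec(36, 7)
  geom <- scan_geometry(det_rows = 40, det_cols = 64, det_pitch = 6)
  ang <- seq(1, 200, length.out = 120)
  d <- forward_project(phantom_volume(ph, 0, g), geom, ang)
  d$meta$bin <- rep(1:10, 12)
  mk <- mkb_reconstruct(d, 10, g)
  ## agreement is limited by the band-limit self-consistency of the FDK
  ## chain (re-projecting a windowed-ramp reconstruction cannot reproduce
  ## the measured data at structure edges), not by the perturbation logic;
  ## frames must agree far below the per-bin streak level (~0.5)
  m <- fov_mask(g, scan_geometry(det_rows = 40, det_cols = 64,
                                 det_pitch = 6))
  for (j in seq(1, 10, by = 3)) {
    nrmsd <- sqrt(mean((mk$mkb$frames[[j]]$data[m] - mk$fdk$data[m])^2)) /
      sd(mk$fdk$data[m])
    expect_lt(nrmsd, 0.2)
  }
  ## zero data -> zero frames
  dz <- d; dz$stack <- array(0, dim(d$stack))
  mkz <- mkb_reconstruct(dz, 10, g)
  expect_equal(max(abs(mkz$mkb$frames[[4]]$data)), 0)
})

test_that("MKB frames track the moving tumor at full amplitude", {
  sc <- local_sto_scan()
  mk <- mkb_reconstruct(sc$d, 10, sc$g)
  ## the most displaced frame shows the tumor near its displaced position
  j <- 6
  u <- stocbct:::bin_displacement(trace_params(), j, 10)
  truth <- tumor_center(sc$ph, u)
  com <- com_near(mk$mkb$frames[[j]], truth, radius = 16, frac = 0.8)
  expect_lt(abs(com[3] - truth[3]), 8)   # one voxel on this grid
})

test_that("identity and translation registrations behave", {
  ph <- make_phantom()
  g <- grid_spec(52, 5)
  tv <- phantom_volume(ph, 0, g)
  V0 <- register_deformable(tv, tv, fast_reg())
  mag <- sqrt(apply(V0$disp^2, 1:3, sum))
  expect_lt(quantile(mag, 0.95), 0.5 * min(g$spacing))
  ## known translation: the recovered pull-back field is -t inside the body
  shift <- array(0, c(52, 52, 52, 3)); shift[, , , 3] <- 6
  moved <- warp_volume(tv, dvf(shift, 5))
  V6 <- register_deformable(moved, tv, fast_reg())
  body <- tv$data > 0.01
  err <- sqrt(V6$disp[, , , 1][body]^2 + V6$disp[, , , 2][body]^2 +
                (V6$disp[, , , 3][body] + 6)^2)
  expect_lt(mean(err), 1.5)
  ## registration is deterministic
  V6b <- register_deformable(moved, tv, fast_reg())
  expect_identical(V6$disp, V6b$disp)
})

test_that("registration survives a pure-noise pair", {
  set.seed(8)
  a <- volume3d(array(rnorm(20^3), c(20, 20, 20)), 8)
  b <- volume3d(array(rnorm(20^3), c(20, 20, 20)), 8)
  expect_no_error(register_deformable(a, b,
                                      fast_reg(iterations = 50,
                                               n_samples = 4000)))
})

test_that("displacement-field inversion satisfies the composition identity", {
  g <- grid_spec(32, 4)
  ## zero and constant fields invert exactly
  z <- zero_dvf_pub(g)
  expect_equal(max(abs(invert_dvf(z)$disp)), 0)
  cst <- z; cst$disp[, , , 2] <- 5
  expect_equal(unique(as.numeric(invert_dvf(cst)$disp[, , , 2])), -5,
               tolerance = 1e-9)
  ## smooth field with ~2 voxel amplitude (separable low-frequency modes)
  co <- (0:31) * 4
  disp <- array(0, c(32, 32, 32, 3))
  for (a in 1:3) {
    disp[, , , a] <- 8 * outer(outer(sin(2 * pi * co / 180 + a),
                                     cos(2 * pi * co / 210 + 2 * a), "*"),
                               sin(2 * pi * co / 250 + 0.5 * a), "*")
  }
  V <- dvf(disp, 4)
  Vi <- invert_dvf(V)
  ## residual r(x) = Vi(x) + V(x + Vi(x)) should vanish
  resid <- array(0, c(32, 32, 32, 3))
  for (a in 1:3) {
    comp <- warp_volume(volume3d(V$disp[, , , a], 4), Vi)
    resid[, , , a] <- Vi$disp[, , , a] + comp$data
  }
  rmag <- sqrt(apply(resid^2, 1:3, sum))
  expect_lt(quantile(rmag, 0.95), 0.2 * 4)
})

test_that("warping is exact for translations and linear in intensities", {
  g <- grid_spec(32, 4)
  sph <- sphere_volume(20, 1, n = 32, spacing = 4)
  z <- zero_dvf_pub(g)
  expect_equal(warp_volume(sph, z)$data, sph$data, tolerance = 1e-12)
  tr <- z; tr$disp[, , , 1] <- 8     # pull-back by +8mm: content moves -8mm
  w <- warp_volume(sph, tr)
  com <- com_near(w, c(-8, 0, 0), radius = 30)
  expect_lt(abs(com[1] + 8), 2)
  ## linearity in intensities
  a <- sph; a$data <- array(rnorm(32^3), c(32, 32, 32))
  b <- sph; b$data <- array(rnorm(32^3), c(32, 32, 32))
  ab <- sph; ab$data <- 2 * a$data + b$data
  expect_equal(warp_volume(ab, tr)$data,
               2 * warp_volume(a, tr)$data + warp_volume(b, tr)$data,
               tolerance = 1e-10)
})

test_that("adaptive reconstruction is consistent for static anatomy", {
  ph <- compact_phantom(c(0, 0, 0), c(0, 0, 0))
  g <- grid_spec(36, 7)
  geom <- scan_geometry(det_rows = 40, det_cols = 64, det_pitch = 6)
  ang <- seq(1, 200, length.out = 120)
  d <- forward_project(phantom_volume(ph, 0, g), geom, ang)
  d$meta$bin <- rep(1:10, 12)
  rec <- adaptive_reconstruct(d, 10, fast_reg(), g)
  ## same band-limit bound as the MKB degeneracy check
  m <- fov_mask(g, scan_geometry(det_rows = 40, det_cols = 64,
                                 det_pitch = 6))
  for (j in c(1, 4, 9)) {
    nrmsd <- sqrt(mean((rec$adaptive$frames[[j]]$data[m] - rec$fdk$data[m])^2)) /
      sd(rec$fdk$data[m])
    expect_lt(nrmsd, 0.2)
  }
  expect_length(rec$dvfs, 10)
  expect_identical(rec$adaptive$bins, 1:10)
  ## the reference bin carries the zero field by construction
  expect_equal(max(abs(rec$dvfs[[1]]$disp)), 0)
})

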