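test_that("sphere projections match the closed-form chord length", {
  R <- 40; mu <- 0.02
  vol <- sphere_volume(R, mu)
  geom <- scan_geometry()
  ps <- forward_project(vol, geom, c(0, 45, 120))
  ## central ray: average the four pixels around the detector center
  ctr <- mean(ps$stack[48:49, 48:49, 1])
  expect_equal(ctr, mu * 2 * R, tolerance = 0.02 * mu * 2 * R)
  ## off-axis ray at impact parameter rho (in the isocenter plane)
  u_iso <- ((1:96) - 48.5) * 4 * geom$sad / geom$sdd
  for (rho in c(15, 25)) {
    iu <- which.min(abs(u_iso - rho))
    chord <- mu * 2 * sqrt(R^2 - u_iso[iu]^2)
    expect_equal(mean(ps$stack[iu, 48:49, 2]), chord, tolerance = 0.03 * chord)
  }
})

test_that("projection, filtering and backprojection are linear operators", {
  vol <- sphere_volume(30, 0.01, n = 32, spacing = 4)
  geom <- scan_geometry(det_rows = 48, det_cols = 48)
  ang <- seq(0, 199, by = 10)
  p1 <- forward_project(vol, geom, ang)
  v2 <- volume3d(2 * vol$data, vol$spacing, vol$origin)
  p2 <- forward_project(v2, geom, ang)
  expect_equal(p2$stack, 2 * p1$stack, tolerance = 1e-12)
  ## zero volume -> zero projections
  z <- volume3d(array(0, dim(vol$data)), vol$spacing, vol$origin)
  expect_equal(max(abs(forward_project(z, geom, ang)$stack)), 0)

  ## filter linearity to machine precision, zero in -> zero out
  pa <- p1; pa$stack <- array(rnorm(length(p1$stack)), dim(p1$stack))
  pb <- p1; pb$stack <- array(rnorm(length(p1$stack)), dim(p1$stack))
  pc <- p1; pc$stack <- 2 * pa$stack - 3 * pb$stack
  fa <- fdk_filter(pa)$stack; fb <- fdk_filter(pb)$stack
  fc <- fdk_filter(pc)$stack
  expect_equal(fc, 2 * fa - 3 * fb, tolerance = 1e-10)
  pz <- p1; pz$stack <- array(0, dim(p1$stack))
  expect_equal(max(abs(fdk_filter(pz)$stack)), 0)

  ## reconstruction linearity
  g <- grid_spec(32, 4)
  ra <- reconstruct_fdk(pa, g)$data
  rb <- reconstruct_fdk(pb, g)$data
  rc <- reconstruct_fdk(pc, g)$data
  expect_equal(rc, 2 * ra - 3 * rb, tolerance = 1e-8)
})

test_that("the ramp filter kills constant rows away from the edges", {
  geom <- scan_geometry(det_rows = 16, det_cols = 64)
  stack <- array(1, c(64, 16, 40))
  ps <- projection_set(stack, seq(0, 195, length.out = 40), geom)
  q <- fdk_filter(ps, apodization = "none")$stack
  ## compare interior response with the input scale (cosine-weighted ~1)
  interior <- q[24:40, 8, 3]
  expect_lt(max(abs(interior)), 0.02 * max(abs(stack)))
})

test_that("ray-driven projection and splat backprojection are exact adjoints", {
  set.seed(4)
  g <- grid_spec(24, 6)
  vol <- volume3d(array(runif(24^3), c(24, 24, 24)), 6)
  geom <- scan_geometry(det_rows = 32, det_cols = 32, det_pitch = 6)
  ang <- c(0, 60, 130)
  Ax <- forward_project(vol, geom, ang)
  p <- Ax; p$stack <- array(runif(length(Ax$stack)), dim(Ax$stack))
  Atp <- back_project(p, g, geom, mode = "adjoint")
  lhs <- sum(Ax$stack * p$stack)
  rhs <- sum(vol$data * Atp$data)
  expect_equal(lhs, rhs, tolerance = 0.01 * abs(lhs))
})

test_that("short-scan FDK recovers a static phantom quantitatively", {
  vol <- sphere_volume(40, 0.02)
  geom <- scan_geometry()
  ang <- seq(1, 200, length.out = 200)
  d <- forward_project(vol, geom, ang)
  rec <- reconstruct_fdk(d, grid_spec(64, 2))
  ## mean attenuation deep inside the sphere within 15%
  inside <- roi_sphere(rec, c(0, 0, 0), 25)
  expect_equal(mean(rec$data[inside]), 0.02, tolerance = 0.15 * 0.02)
  ## center of mass within one voxel
  expect_lt(max(abs(com_near(rec, c(0, 0, 0), radius = 50))), 2)
  ## arc below the short-scan minimum is refused
  short <- subset_projections_pub(d, which(ang <= 150))
  expect_error(fdk_filter(short), "short-scan")
})

test_that("phase-resolved frames sum exactly to the full reconstruction", {
  ph <- make_phantom()
  g <- small_grid()
  vol <- phantom_volume(ph, 0.4, g)
  geom <- scan_geometry()
  ang <- seq(1, 200, length.out = 60)
  d <- forward_project(vol, geom, ang)
  d$meta$bin <- rep(1:10, 6)
  f4 <- reconstruct_4dfdk(d, 10, g)
  fdk <- reconstruct_fdk(d, g)
  s <- Reduce(`+`, lapply(f4$frames, `[[`, "data"))
  relerr <- sqrt(sum((s - fdk$data)^2) / sum(fdk$data^2))
  expect_lt(relerr, 1e-6)
  ## single-bin degenerate case equals plain FDK
  d1 <- d; d1$meta$bin <- rep(1L, 60)
  f1 <- reconstruct_4dfdk(d1, 1, g)
  expect_equal(f1$frames[[1]]$data, fdk$data, tolerance = 1e-12)
  ## an empty bin is reported by name
  d2 <- d; d2$meta$bin <- rep(c(1:5, 1:5), 6)
  expect_error(reconstruct_4dfdk(d2, 10, g), "bin 6")
})
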