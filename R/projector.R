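#' Cone-beam scan geometry
#'
#' Source-axis distance, source-detector distance and flat-panel layout.
#' Defaults are conventional linac CBCT values: SAD 1000 mm, SDD 1536 mm,
#' 96 x 96 detector at 4 mm pitch, 200 degree arc. The rotation axis is the
#' superior-inferior (z) axis through the isocenter.
#'
#' @param sad source-axis distance, mm.
#' @param sdd source-detector distance, mm.
#' @param det_rows,det_cols detector rows (axial, v) and columns
#'   (transaxial, u).
#' @param det_pitch pixel pitch mm (scalar or `c(u, v)`).
#' @param arc_deg gantry arc, degrees.
#' @return list of class `scan_geometry`.
#' @export
scan_geometry <- function(sad = 1000, sdd = 1536, det_rows = 96,
                          det_cols = 96, det_pitch = 4, arc_deg = 200) {
  if (!(sdd > sad && sad > 0)) stop("need SDD > SAD > 0")
  if (det_rows < 1 || det_cols < 1) stop("detector dims must be positive")
  det_pitch <- rep(det_pitch, length.out = 2)
  structure(list(sad = sad, sdd = sdd, det_rows = as.integer(det_rows),
                 det_cols = as.integer(det_cols), det_pitch = det_pitch,
                 arc_deg = arc_deg),
            class = "scan_geometry")
}

#' Cone-beam projection set
#'
#' A stack of 2D line-integral projections with per-projection metadata.
#'
#' @param stack numeric array `[det_cols, det_rows, n_proj]`.
#' @param angles_deg gantry angle per projection.
#' @param geometry a [scan_geometry].
#' @param times_s acquisition time per projection (s), NA if unbound.
#' @param bins respiratory bin per projection, NA if unassigned.
#' @return object of class `projection_set`.
#' @export
projection_set <- function(stack, angles_deg, geometry,
                           times_s = NA_real_, bins = NA_integer_) {
  stopifnot(inherits(geometry, "scan_geometry"))
  d <- dim(stack)
  if (length(d) != 3L) stop("stack must be [det_cols, det_rows, n_proj]")
  n <- d[3]
  if (length(angles_deg) != n)
    stop("angles_deg length must equal stack depth")
  meta <- data.frame(k = seq_len(n), angle_deg = angles_deg,
                     t_s = rep(times_s, length.out = n),
                     bin = as.integer(rep(bins, length.out = n)))
  structure(list(stack = stack, meta = meta, geometry = geometry),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf("<projection_set> %d projections of %dx%d, angles [%.1f, %.1f] deg\n",
              nrow(x$meta), dim(x$stack)[1], dim(x$stack)[2],
              min(x$meta$angle_deg), max(x$meta$angle_deg)))
  invisible(x)
}

subset_projections <- function(p, idx) {
  out <- p
  out$stack <- p$stack[, , idx, drop = FALSE]
  out$meta <- p$meta[idx, , drop = FALSE]
  out$meta$k <- seq_len(nrow(out$meta))
  rownames(out$meta) <- NULL
  out
}

#' Forward projection (cone-beam line integrals)
#'
#' Ray-driven interpolating projector: for each detector pixel, the
#' attenuation volume is integrated along the source-to-pixel ray with
#' mid-point sampling at half the smallest voxel size. Values are
#' dimensionless line integrals (mm^-1 times mm).
#'
#' @param volume a [volume3d].
#' @param geometry a [scan_geometry].
#' @param angles_deg gantry angles to project at.
#' @param step_mm ray sampling step; default `min(spacing)/2`.
#' @return a [projection_set].
#' @export
forward_project <- function(volume, geometry, angles_deg, step_mm = NULL) {
  stopifnot(inherits(volume, "volume3d"), inherits(geometry, "scan_geometry"))
  if (is.null(step_mm)) step_mm <- min(volume$spacing) / 2
  ## field-of-view check: grid corner radius vs detector fan
  fov_r <- geometry$det_cols * geometry$det_pitch[1] / 2 *
    geometry$sad / geometry$sdd
  ext <- (dim(volume$data) - 1) * volume$spacing
  r_xy <- sqrt(sum((pmax(abs(volume$origin[1:2]),
                         abs(volume$origin[1:2] + ext[1:2])))^2))
  if (r_xy > fov_r * 1.75)
    warning("volume extends far outside the detector field of view")
  stack <- forward_project_cpp(volume$data, dim(volume$data), volume$spacing,
                               volume$origin, geometry$sad, geometry$sdd,
                               geometry$det_cols, geometry$det_rows,
                               geometry$det_pitch[1], geometry$det_pitch[2],
                               angles_deg * pi / 180, step_mm)
  projection_set(stack, angles_deg, geometry)
}

## generalized Parker redundancy weight for arcs >= 180 deg + fan angle;
## gamma = fan angle of the detector column, b = angle from scan start (rad),
## arc in rad, delta = (arc - pi) / 2
parker_weight <- function(gamma, b, arc, delta) {
  eps <- 1e-9
  w <- rep(1, length(gamma))
  r1 <- b < 2 * (delta + gamma)
  w[r1] <- sin(pi / 4 * b / pmax(delta + gamma[r1], eps))^2
  r3 <- b > arc - 2 * (delta - gamma)
  w[r3] <- sin(pi / 4 * (arc - b) / pmax(delta - gamma[r3], eps))^2
  w
}

#' FDK projection filtering
#'
#' Per-projection cosine weighting, short-scan (Parker-type) redundancy
#' weighting generalized to the actual arc, and row-wise ramp filtering with
#' a Hann apodization, implemented in the frequency domain with
#' power-of-two zero padding and edge-taper extension. Linear in the input.
#'
#' @param projections a [projection_set] covering the scan arc.
#' @param apodization `"cosine"` (default; mild smoothing, close to
#'   clinical practice), `"hann"` (strong smoothing) or `"none"` (pure
#'   ramp).
#' @return a filtered [projection_set] (attribute `filtered = TRUE`).
#' @export
fdk_filter <- function(projections, apodization = c("cosine", "hann", "none")) {
  apodization <- match.arg(apodization)
  g <- projections$geometry
  stack <- projections$stack
  nu <- dim(stack)[1]; nv <- dim(stack)[2]; nk <- dim(stack)[3]
  if (nk < 1) stop("empty projection stack")
  du <- g$det_pitch[1] * g$sad / g$sdd   # pitch rescaled to isocenter plane
  dv <- g$det_pitch[2] * g$sad / g$sdd
  u <- (seq_len(nu) - (nu + 1) / 2) * du
  v <- (seq_len(nv) - (nv + 1) / 2) * dv
  gamma <- atan(u / g$sad)
  gamma_m <- max(abs(gamma))
  beta <- projections$meta$angle_deg * pi / 180
  b0 <- min(beta)
  dbeta <- if (nk > 1) diff(range(beta)) / (nk - 1) else 0
  arc <- diff(range(beta)) + dbeta
  if (arc < pi + 2 * gamma_m - 1e-9)
    stop(sprintf("arc %.1f deg below the short-scan minimum %.1f deg",
                 arc * 180 / pi, (pi + 2 * gamma_m) * 180 / pi))
  delta <- (arc - pi) / 2

  cosw <- g$sad / sqrt(g$sad^2 + outer(u^2, v^2, "+"))

  ## ramp convolver (Ram-Lak spatial kernel), circular, padded
  P <- 2^ceiling(log2(2 * nu))
  h <- numeric(P)
  h[1] <- 1 / (4 * du^2)
  n_odd <- seq(1, P / 2, by = 2)
  h[1 + n_odd] <- -1 / (pi * n_odd * du)^2
  h[P + 1 - n_odd] <- -1 / (pi * n_odd * du)^2
  H <- Re(fft(h))
  nu_f <- pmin(0:(P - 1), P - (0:(P - 1))) / P     # |freq| in cycles/sample
  if (apodization == "hann") {
    H <- H * 0.5 * (1 + cos(2 * pi * nu_f))
  } else if (apodization == "cosine") {
    H <- H * cos(pi * nu_f)
  }
  Tpad <- min(nu, (P - nu) %/% 2)
  taper <- 0.5 * (1 + cos(seq_len(Tpad) / (Tpad + 1) * pi))

  out <- array(0, dim(stack))
  for (k in seq_len(nk)) {
    pw <- stack[, , k] * cosw *
      parker_weight(gamma, beta[k] - b0, arc, delta)
    padded <- matrix(0, P, nv)
    padded[seq_len(nu), ] <- pw
    if (Tpad > 0) {
      padded[nu + seq_len(Tpad), ] <- outer(taper, pw[nu, ])
      padded[P + 1 - seq_len(Tpad), ] <- outer(taper, pw[1, ])
    }
    q <- Re(stats::mvfft(stats::mvfft(padded) * H, inverse = TRUE)) / P
    out[, , k] <- q[seq_len(nu), ] * du
  }
  res <- projections
  res$stack <- out
  attr(res, "filtered") <- TRUE
  res
}

#' FDK weighted backprojection
#'
#' Voxel-driven accumulation of filtered projections with the FDK distance
#' weight `SAD^2/U^2` and angular-step scaling `dbeta`. With
#' `mode = "adjoint"` it instead applies the exact adjoint of
#' [forward_project] (ray-driven splatting, no FDK weights), used for
#' operator checks.
#'
#' @param filtered a [projection_set] (normally the output of [fdk_filter]).
#' @param geometry a [scan_geometry] (defaults to the set's geometry).
#' @param grid a [grid_spec].
#' @param dbeta_rad angular step in radians; default inferred from the
#'   projection angles. Pass the global step of the full scan when
#'   backprojecting per-bin subsets.
#' @param mode `"fdk"` or `"adjoint"`.
#' @param step_mm ray step for adjoint mode.
#' @return a [volume3d].
#' @export
back_project <- function(filtered, grid, geometry = filtered$geometry,
                         dbeta_rad = NULL, mode = c("fdk", "adjoint"),
                         step_mm = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "grid_spec"))
  ang <- filtered$meta$angle_deg * pi / 180
  if (is.null(dbeta_rad))
    dbeta_rad <- if (length(ang) > 1) diff(range(ang)) / (length(ang) - 1) else 1
  if (mode == "adjoint") {
    if (is.null(step_mm)) step_mm <- min(grid$spacing) / 2
    vox <- forward_adjoint_cpp(filtered$stack, grid$shape, grid$spacing,
                               grid$origin, geometry$sad, geometry$sdd,
                               geometry$det_cols, geometry$det_rows,
                               geometry$det_pitch[1], geometry$det_pitch[2],
                               ang, step_mm)
  } else {
    vox <- back_project_cpp(filtered$stack, grid$shape, grid$spacing,
                            grid$origin, geometry$sad, geometry$sdd,
                            geometry$det_cols, geometry$det_rows,
                            geometry$det_pitch[1], geometry$det_pitch[2],
                            ang, dbeta_rad, TRUE)
  }
  volume3d(vox, grid$spacing, grid$origin)
}

#' FDK reconstruction
#'
#' Filtered backprojection adapted to cone-beam geometry:
#' filter the projections, then backproject with distance weighting.
#'
#' @param d a [projection_set] spanning the scan arc.
#' @param grid a [grid_spec] for the reconstruction.
#' @return a [volume3d] estimate of the attenuation map.
#' @export
reconstruct_fdk <- function(d, grid) {
  back_project(fdk_filter(d), grid)
}

#' Phase-resolved (4D) FDK reconstruction
#'
#' Reconstructs one volume per respiratory bin from only that bin's
#' projections. Projections are filtered once as a full set (so redundancy
#' weights are those of the complete scan) and each frame's backprojection is
#' scaled by the global angular step; consequently the frames sum exactly to
#' the motion-blurred full FDK reconstruction.
#'
#' @param d a [projection_set] whose metadata carries bin labels.
#' @param n_bins number of respiratory bins.
#' @param grid a [grid_spec].
#' @return an [image4d] with `n_bins` frames.
#' @export
reconstruct_4dfdk <- function(d, n_bins, grid) {
  bins <- d$meta$bin
  if (anyNA(bins)) stop("projection set has unassigned bins")
  counts <- tabulate(bins, n_bins)
  if (any(counts == 0))
    stop(sprintf("no projections in bin %s",
                 paste(which(counts == 0), collapse = ", ")))
  q <- fdk_filter(d)
  ang <- d$meta$angle_deg * pi / 180
  dbeta_global <- if (length(ang) > 1)
    diff(range(ang)) / (length(ang) - 1) else 1
  frames <- lapply(seq_len(n_bins), function(j) {
    back_project(subset_projections(q, which(bins == j)), grid,
                 dbeta_rad = dbeta_global)
  })
  image4d(frames, seq_len(n_bins))
}

#' Geometric field-of-view mask
#'
#' Voxels that are projected inside the detector at every gantry angle of the
#' arc (sampled every few degrees). Cone-beam data cannot support voxels
#' outside this region (most visibly the first/last axial slices), so
#' quantitative comparisons between reconstructions are made inside it; the
#' same masking is applied to clinical displays.
#'
#' @param grid a [grid_spec].
#' @param geometry a [scan_geometry].
#' @param margin_mm shrink the mask by this margin (default one detector
#'   pixel at the isocenter).
#' @return logical array on the grid.
#' @export
fov_mask <- function(grid, geometry, margin_mm = NULL) {
  if (is.null(margin_mm))
    margin_mm <- max(geometry$det_pitch) * geometry$sad / geometry$sdd
  gx <- grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1]
  gy <- grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2]
  gz <- grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3]
  half_u <- geometry$det_cols * geometry$det_pitch[1] / 2 - margin_mm *
    geometry$sdd / geometry$sad
  half_v <- geometry$det_rows * geometry$det_pitch[2] / 2 - margin_mm *
    geometry$sdd / geometry$sad
  mask <- array(TRUE, grid$shape)
  for (b in seq(0, geometry$arc_deg, by = 5) * pi / 180) {
    sb <- sin(b); cb <- cos(b)
    U <- geometry$sad - outer(gx * cb, gy * sb, "+")       # nx x ny
    mag <- geometry$sdd / pmax(U, 1e-6)
    ud <- outer(-gx * sb, gy * cb, "+") * mag
    ok_xy <- U > 1e-6 & abs(ud) <= half_u
    vlim <- half_v / mag                                   # allowed |z|
    m_b <- array(ok_xy, grid$shape) &
      (rep(abs(gz), each = length(ok_xy)) <=
         as.numeric(vlim))
    mask <- mask & m_b
  }
  mask
}
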