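#' Deformable registration configuration
#'
#' @param grid_spacing_mm B-spline control-point spacing on the finest level
#'   (default 16 mm, a deliberately coarse grid: CBCT frame quality does not
#'   support finer control, and a coarse grid keeps registration fast and
#'   regular).
#' @param metric `"mi"` (Mattes mutual information, default) or `"ssd"`.
#' @param levels multiresolution levels (default 3; control spacing and image
#'   resolution halve per level).
#' @param iterations gradient-ascent iterations per level.
#' @param n_samples voxel samples per metric evaluation.
#' @param n_bins histogram bins for mutual information.
#' @param step0_mm initial optimizer step (mm at the control points).
#' @param smooth membrane-regularization strength in `[0, 1)`: each
#'   iteration every control coefficient is relaxed toward the mean of its
#'   6-neighborhood by this fraction (uniform motion is unaffected).
#' @param reference_bin reference respiratory phase r (default 1 = peak
#'   inhale).
#' @param seed seed for the deterministic sample draw.
#' @return list of class `reg_config`.
#' @export
reg_config <- function(grid_spacing_mm = 16, metric = c("mi", "ssd"),
                       levels = 3, iterations = 600, n_samples = 80000,
                       n_bins = 32, step0_mm = 3.0, smooth = 0.03,
                       reference_bin = 1L, seed = 42L) {
  metric <- match.arg(metric)
  if (grid_spacing_mm <= 0) stop("grid_spacing_mm must be positive")
  structure(list(grid_spacing_mm = grid_spacing_mm, metric = metric,
                 levels = as.integer(levels),
                 iterations = as.integer(iterations),
                 n_samples = as.integer(n_samples),
                 n_bins = as.integer(n_bins), step0_mm = step0_mm,
                 smooth = smooth,
                 reference_bin = as.integer(reference_bin),
                 seed = as.integer(seed)),
            class = "reg_config")
}

#' B-spline deformable registration
#'
#' Estimates the dense displacement field V such that the moving image
#' resampled at `x + V(x)` matches the fixed image: a multiresolution
#' free-form cubic B-spline deformation optimized by gradient ascent on
#' Mattes mutual information (or descent on mean squared difference).
#' Deterministic for fixed inputs and configuration.
#'
#' @param moving,fixed [volume3d] images on the same grid.
#' @param cfg a [reg_config].
#' @return a [dvf] on the image grid (displacements in mm).
#' @export
register_deformable <- function(moving, fixed, cfg = reg_config()) {
  stopifnot(inherits(moving, "volume3d"), inherits(fixed, "volume3d"))
  if (!same_grid(moving, fixed)) stop("images must share one grid")
  if (cfg$grid_spacing_mm <= max(moving$spacing))
    stop("control-point spacing must exceed the voxel spacing")
  res <- bspline_register_cpp(fixed$data, moving$data, dim(fixed$data),
                              fixed$spacing, fixed$origin,
                              cfg$grid_spacing_mm, cfg$levels,
                              cfg$iterations, cfg$n_samples, cfg$n_bins,
                              cfg$metric, cfg$seed, cfg$step0_mm, cfg$smooth)
  if (!all(is.finite(res$disp)))
    stop("registration optimizer diverged (non-finite displacements); ",
         "metric trace: ", paste(signif(res$metric_trace, 4), collapse = ", "))
  out <- dvf(res$disp, fixed$spacing, fixed$origin)
  attr(out, "metric") <- res$metric
  attr(out, "metric_trace") <- res$metric_trace
  out
}

#' Invert a displacement field
#'
#' Fixed-point iteration `Vinv(x) <- -V(x + Vinv(x))`, iterated to a tolerance
#' of 0.1 voxel (at most `max_iter` sweeps). Inverting is much cheaper than
#' estimating the reverse deformation with another registration.
#'
#' @param V a [dvf].
#' @param tol_voxel convergence tolerance in voxels.
#' @param max_iter maximum fixed-point sweeps.
#' @return the inverse [dvf].
#' @export
invert_dvf <- function(V, tol_voxel = 0.1, max_iter = 50L) {
  stopifnot(inherits(V, "dvf"))
  res <- invert_dvf_cpp(V$disp, dim(V$disp)[1:3], V$spacing,
                        tol_voxel * min(V$spacing), as.integer(max_iter))
  if (!res$converged)
    stop(sprintf("DVF inversion did not converge: residual %.3g mm after %d iterations",
                 res$residual_mm, res$iterations))
  dvf(res$disp, V$spacing, V$origin,
      source_bin = V$target_bin, target_bin = V$source_bin)
}

#' Warp a volume by a displacement field
#'
#' Pull-back interpolation: `out(x) = x_in(x + V(x))`, with out-of-grid
#' samples clamped to the boundary value. Linear in the image intensities.
#' Interpolation is trilinear by default; `"cubic"` uses prefiltered cubic
#' B-spline interpolation, which preserves edges noticeably better when a
#' volume passes through more than one warp (as in the motion-compensated
#' frame synthesis).
#'
#' @param x a [volume3d].
#' @param V a [dvf] on the same grid.
#' @param interp `"linear"` or `"cubic"`.
#' @return the warped [volume3d].
#' @export
warp_volume <- function(x, V, interp = c("linear", "cubic")) {
  interp <- match.arg(interp)
  stopifnot(inherits(x, "volume3d"), inherits(V, "dvf"))
  if (!identical(dim(x$data), dim(V$disp)[1:3]))
    stop("volume and DVF must share one grid")
  volume3d(warp_volume_cpp(x$data, V$disp, dim(x$data), x$spacing,
                           if (interp == "cubic") 3L else 1L),
           x$spacing, x$origin)
}

#' Sample a volume at world coordinates
#'
#' Clamped trilinear interpolation at arbitrary points (mm).
#'
#' @param x a [volume3d].
#' @param pts n-by-3 matrix of world mm coordinates.
#' @return numeric vector of sampled values.
#' @export
sample_volume <- function(x, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  sample_volume_cpp(x$data, dim(x$data), x$spacing, x$origin, pts)
}
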