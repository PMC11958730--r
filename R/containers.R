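#' Regular voxel grid specification
#'
#' Defines the sampling lattice on which volumes are rendered and
#' reconstructed. The grid is isocenter-centered by default: the world
#' coordinate of the center of voxel `[1, 1, 1]` is chosen so that the grid
#' midpoint coincides with the origin (the rotation isocenter). World frame is
#' right-handed with z = superior (the rotation axis).
#'
#' @param shape integer length-3, number of voxels along x, y, z.
#' @param spacing numeric length-3 (or scalar), voxel size in mm.
#' @param origin world coordinate (mm) of the center of voxel `[1,1,1]`;
#'   default centers the grid on the isocenter.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(shape, spacing, origin = NULL) {
  shape <- as.integer(rep(shape, length.out = 3))
  spacing <- as.numeric(rep(spacing, length.out = 3))
  if (any(shape < 1)) stop("grid shape must be positive")
  if (any(spacing <= 0)) stop("grid spacing must be positive")
  if (is.null(origin)) origin <- -(shape - 1) / 2 * spacing
  origin <- as.numeric(rep(origin, length.out = 3))
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_spec")
}

#' 3D attenuation volume
#'
#' A dense 3D array of linear attenuation values (mm^-1) on a regular grid.
#'
#' @param data 3D numeric array.
#' @param spacing voxel size mm (length 3 or scalar).
#' @param origin world mm of the center of voxel `[1,1,1]`.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing, origin = NULL) {
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  g <- grid_spec(dim(data), spacing, origin)
  if (!all(is.finite(data))) stop("volume values must be finite")
  structure(list(data = data, spacing = g$spacing, origin = g$origin),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s voxels, spacing %s mm, range [%.4g, %.4g] mm^-1\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

vol_grid <- function(vol) grid_spec(dim(vol$data), vol$spacing, vol$origin)

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Phase-resolved 4D image
#'
#' A list of [volume3d] frames on a common grid, one per respiratory bin.
#'
#' @param frames list of `volume3d` objects sharing one grid.
#' @param bins integer bin labels, defaults to `1:length(frames)`.
#' @return An object of class `image4d`.
#' @export
image4d <- function(frames, bins = seq_along(frames)) {
  if (length(frames) < 1L) stop("image4d needs at least one frame")
  if (!all(vapply(frames, inherits, TRUE, "volume3d")))
    stop("all frames must be volume3d")
  for (f in frames[-1]) {
    if (!same_grid(frames[[1]], f)) stop("all frames must share one grid")
  }
  if (length(bins) != length(frames)) stop("bins must match frame count")
  structure(list(frames = frames, bins = as.integer(bins)),
            class = "image4d")
}

#' @export
print.image4d <- function(x, ...) {
  cat(sprintf("<image4d> %d frames of %s voxels (bins %s)\n",
              length(x$frames), paste(dim(x$frames[[1]]$data), collapse = "x"),
              paste(x$bins, collapse = ",")))
  invisible(x)
}

#' Dense deformation vector field
#'
#' Per-voxel 3D displacement in mm on the reconstruction grid, mapping the
#' coordinate frame of the target (fixed, reference-bin) image into the source
#' (moving) image: warping pulls intensities back from position `x + V(x)`.
#'
#' @param disp 4D numeric array `[nx, ny, nz, 3]` of displacements in mm.
#' @param spacing,origin grid geometry as in [volume3d].
#' @param source_bin,target_bin bin bookkeeping labels.
#' @return An object of class `dvf`.
#' @export
dvf <- function(disp, spacing, origin = NULL, source_bin = NA_integer_,
                target_bin = NA_integer_) {
  d <- dim(disp)
  if (length(d) != 4L || d[4] != 3L) stop("dvf needs a [nx,ny,nz,3] array")
  if (!all(is.finite(disp))) stop("dvf displacements must be finite")
  g <- grid_spec(d[1:3], spacing, origin)
  structure(list(disp = disp, spacing = g$spacing, origin = g$origin,
                 source_bin = as.integer(source_bin),
                 target_bin = as.integer(target_bin)),
            class = "dvf")
}

zero_dvf <- function(grid, source_bin = NA_integer_, target_bin = NA_integer_) {
  dvf(array(0, c(grid$shape, 3L)), grid$spacing, grid$origin,
      source_bin, target_bin)
}
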