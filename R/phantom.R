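#' Construct a breathing thorax phantom
#'
#' Builds a simple digital thorax: an ellipsoidal body, two low-attenuation
#' lung ellipsoids, a spherical tumor inside one lung, and a spherical-cap
#' diaphragm dome intruding into the lung base. The tumor and diaphragm move
#' with the normalized breathing displacement `u` in `[0, 1]` (`u = 0` is peak
#' inhale, both structures at their most inferior; `u = 1` is peak exhale).
#' Default motion is superior-inferior only, 15 mm for the tumor and 25 mm for
#' the diaphragm apex. Attenuations are linear attenuation coefficients in
#' mm^-1 (roughly water = 0.02 at CBCT energies); no HU conversion is applied.
#'
#' @param config optional named list overriding any of `body`, `lungs`,
#'   `tumor`, `diaphragm` sub-lists (see Details in the package vignette).
#' @return A validated object of class `phantom_model`.
#' @export
make_phantom <- function(config = list()) {
  def <- list(
    body = list(center = c(0, 0, 0), semi_axes = c(125, 95, 150), mu = 0.020),
    lungs = list(
      list(center = c(-60, 0, 20), semi_axes = c(50, 65, 85), mu = 0.004),
      list(center = c(60, 0, 20), semi_axes = c(50, 65, 85), mu = 0.004)
    ),
    tumor = list(center = c(60, 0, 10), radius = 10, mu = 0.024,
                 amplitude = c(0, 0, 15)),
    diaphragm = list(center = c(60, 0, -150), radius = 90, mu = 0.024,
                     amplitude = c(0, 0, 25))
  )
  m <- modifyList(def, config)
  if (length(m$tumor$amplitude) == 1)
    m$tumor$amplitude <- c(0, 0, m$tumor$amplitude)
  if (length(m$diaphragm$amplitude) == 1)
    m$diaphragm$amplitude <- c(0, 0, m$diaphragm$amplitude)

  mus <- c(m$body$mu, m$tumor$mu, m$diaphragm$mu, vapply(m$lungs, `[[`, 0, "mu"))
  if (any(mus < 0)) stop("attenuations must be nonnegative")
  lung_mu <- max(vapply(m$lungs, `[[`, 0, "mu"))
  if (!(lung_mu < m$body$mu && m$body$mu < m$tumor$mu &&
        m$body$mu < m$diaphragm$mu))
    stop("attenuation ordering violated: need lung < body < tumor/diaphragm")

  ## tumor must stay inside some lung over the whole displacement range
  if (m$tumor$radius > 0) {
    inside_some_lung <- vapply(seq(0, 1, length.out = 11), function(u) {
      ctr <- m$tumor$center + u * m$tumor$amplitude
      any(vapply(m$lungs, function(L) {
        margin <- L$semi_axes - m$tumor$radius
        if (any(margin <= 0)) return(FALSE)
        sum(((ctr - L$center) / margin)^2) <= 1
      }, TRUE))
    }, TRUE)
    if (!all(inside_some_lung))
      stop("tumor leaves the lung over the displacement range [0,1]")
  }
  structure(m, class = "phantom_model")
}

#' @export
print.phantom_model <- function(x, ...) {
  cat(sprintf(
    "<phantom_model> body %s mm, tumor r=%g mm (%.0f mm motion), diaphragm %.0f mm motion\n",
    paste(round(2 * x$body$semi_axes), collapse = "x"), x$tumor$radius,
    sqrt(sum(x$tumor$amplitude^2)), sqrt(sum(x$diaphragm$amplitude^2))))
  invisible(x)
}

## smooth occupancy of an ellipsoid on precomputed world coordinate vectors;
## edge softened over ~1 voxel using an approximate signed distance
ellipsoid_alpha <- function(gx, gy, gz, center, semi, edge_mm) {
  rho2 <- outer(outer((gx - center[1])^2 / semi[1]^2,
                      (gy - center[2])^2 / semi[2]^2, "+"),
                (gz - center[3])^2 / semi[3]^2, "+")
  dist <- (1 - sqrt(rho2)) * min(semi)
  pmin(pmax(dist / edge_mm + 0.5, 0), 1)
}

sphere_alpha <- function(gx, gy, gz, center, radius, edge_mm) {
  r <- sqrt(outer(outer((gx - center[1])^2, (gy - center[2])^2, "+"),
                  (gz - center[3])^2, "+"))
  pmin(pmax((radius - r) / edge_mm + 0.5, 0), 1)
}

#' Render the phantom at a breathing displacement
#'
#' Voxelizes the phantom attenuation map at normalized displacement `u`,
#' with structure edges anti-aliased over one voxel so line integrals vary
#' smoothly with `u`. Deterministic.
#'
#' @param model a [make_phantom] result.
#' @param u normalized breathing displacement in `[0, 1]`.
#' @param grid a [grid_spec].
#' @param edge_mm width of the anti-aliased structure boundary (default one
#'   voxel). Wider edges give a band-limited phantom, useful when verifying
#'   operator identities that hold in the continuum but are obscured by
#'   discretization at sharp boundaries.
#' @return A [volume3d] of attenuation (mm^-1).
#' @export
phantom_volume <- function(model, u, grid, edge_mm = NULL) {
  stopifnot(inherits(model, "phantom_model"), inherits(grid, "grid_spec"))
  if (u < 0 || u > 1) stop("displacement u must lie in [0, 1]")
  gx <- grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1]
  gy <- grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2]
  gz <- grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3]
  b <- model$body
  lo <- b$center - b$semi_axes; hi <- b$center + b$semi_axes
  ## a body longer than the grid along z (superior-inferior) is the normal
  ## patient situation; warn only for transaxial truncation
  if (min(gx) > lo[1] || max(gx) < hi[1] || min(gy) > lo[2] ||
      max(gy) < hi[2])
    warning("grid does not cover the phantom body; truncated render")
  edge <- if (is.null(edge_mm)) min(grid$spacing) else edge_mm

  body_a <- ellipsoid_alpha(gx, gy, gz, b$center, b$semi_axes, edge)
  vol <- b$mu * body_a
  for (L in model$lungs) {
    a <- ellipsoid_alpha(gx, gy, gz, L$center, L$semi_axes, edge)
    vol <- vol * (1 - a) + L$mu * a
  }
  ## diaphragm dome: spherical cap confined to the body, overriding lung
  ## tissue where it intrudes into the lung base
  d <- model$diaphragm
  a <- sphere_alpha(gx, gy, gz, d$center + u * d$amplitude, d$radius, edge) *
    body_a
  vol <- vol * (1 - a) + d$mu * a
  tm <- model$tumor
  if (tm$radius > 0) {
    a <- sphere_alpha(gx, gy, gz, tm$center + u * tm$amplitude, tm$radius, edge)
    vol <- vol * (1 - a) + tm$mu * a
  }
  volume3d(vol, grid$spacing, grid$origin)
}

#' Ground-truth tumor center at displacement u
#'
#' @param model a [make_phantom] result.
#' @param u normalized displacement in `[0,1]` (vectorized).
#' @return matrix with one row per `u`, columns x/y/z in mm.
#' @export
tumor_center <- function(model, u) {
  t(vapply(u, function(ui) model$tumor$center + ui * model$tumor$amplitude,
           numeric(3)))
}
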