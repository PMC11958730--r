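#' Mean absolute angular error of a realized schedule
#'
#' `MAE = mean(|S_ideal,k - S_acquired,k|)` over projection index, degrees.
#'
#' @param acquired,ideal `acquisition_schedule` objects of equal length,
#'   matched by projection index.
#' @return MAE in degrees.
#' @export
schedule_mae <- function(acquired, ideal) {
  if (nrow(acquired) != nrow(ideal))
    stop(sprintf("schedule lengths differ (%d vs %d)",
                 nrow(acquired), nrow(ideal)))
  mean(abs(acquired$angle_deg - ideal$angle_deg))
}

#' Contrast-to-noise ratio between lung and diaphragm regions
#'
#' `CNR = (mu_lung - mu_diaphragm) / sigma` with `sigma` the pooled standard
#' deviation of the two regions (deviations taken about each region's own
#' mean). Sign is preserved.
#'
#' @param volume a [volume3d].
#' @param roi_lung,roi_diaphragm disjoint logical masks on the volume grid.
#' @return the CNR (signed).
#' @export
cnr <- function(volume, roi_lung, roi_diaphragm) {
  stopifnot(inherits(volume, "volume3d"))
  if (!any(roi_lung) || !any(roi_diaphragm)) stop("empty ROI")
  if (any(roi_lung & roi_diaphragm)) stop("ROIs must be disjoint")
  a <- volume$data[roi_lung]; b <- volume$data[roi_diaphragm]
  n1 <- length(a); n2 <- length(b)
  sigma <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
                  (n1 + n2 - 2))
  (mean(a) - mean(b)) / sigma
}

#' Spherical region-of-interest mask
#'
#' @param grid a [grid_spec] (or [volume3d]).
#' @param center world mm.
#' @param radius mm.
#' @return logical array on the grid.
#' @export
roi_sphere <- function(grid, center, radius) {
  if (inherits(grid, "volume3d")) grid <- vol_grid(grid)
  gx <- grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1]
  gy <- grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2]
  gz <- grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3]
  outer(outer((gx - center[1])^2, (gy - center[2])^2, "+"),
        (gz - center[3])^2, "+") <= radius^2
}

#' Tissue interface width
#'
#' Quantifies edge definition at a tissue interface: a block of parallel
#' voxel runs is extracted across the interface, a 4-parameter logistic
#' sigmoid `lo + (hi-lo)/(1+exp(-(x-x0)/s))` is fitted to each run, and the
#' width over which the fitted sigmoid moves from 10% to 90% of its asymptote
#' range (`= 2*ln(9)*|s|`) is averaged over the runs that fit. Runs are
#' rejected when the fit fails, explains less than half the variance, or
#' yields a width wider than the probe; if more than half the runs fail the
#' interface is declared incoherent.
#'
#' @param volume a [volume3d].
#' @param probe list with `center` (world mm, on the interface), `direction`
#'   (length-3, need not be normalized), `n_along` run length in samples
#'   (default 60), `n_across` runs per side dimension (default 5: 25 runs),
#'   `step_mm` sampling step along the run (default: voxel spacing along the
#'   dominant axis).
#' @return TIW in mm, with attributes `n_failed` and `widths_mm`.
#' @export
tiw <- function(volume, probe) {
  stopifnot(inherits(volume, "volume3d"))
  dirv <- probe$direction / sqrt(sum(probe$direction^2))
  n_along <- probe$n_along %||% 60L
  n_across <- probe$n_across %||% 5L
  step <- probe$step_mm %||% volume$spacing[which.max(abs(dirv))]
  ## two unit vectors orthogonal to the run direction
  aux <- if (abs(dirv[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- pracma::cross(dirv, aux); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- pracma::cross(dirv, e1)
  off <- seq_len(n_across) - (n_across + 1) / 2
  s_along <- (seq_len(n_along) - (n_along + 1) / 2) * step
  cross_step <- probe$cross_step_mm %||% min(volume$spacing)
  widths <- c(); n_failed <- 0L
  for (i in off) for (j in off) {
    base <- probe$center + (i * e1 + j * e2) * cross_step
    pts <- t(vapply(s_along, function(s) base + s * dirv, numeric(3)))
    vals <- sample_volume(volume, pts)
    w <- fit_sigmoid_width(s_along, vals)
    if (is.na(w) || w > diff(range(s_along))) n_failed <- n_failed + 1L
    else widths <- c(widths, w)
  }
  n_runs <- n_across^2
  if (n_failed > n_runs %/% 2)
    stop(sprintf("no coherent interface: %d of %d runs failed to fit",
                 n_failed, n_runs))
  structure(mean(widths), n_failed = n_failed, widths_mm = widths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## 10-90% width of a fitted 4-parameter logistic; NA on failure
fit_sigmoid_width <- function(x, y) {
  rng <- range(y)
  if (diff(rng) <= 0) return(NA_real_)
  ## fit with a rising sigmoid; flip falling runs so the scale s stays
  ## positive and can be bounded away from the singular s -> 0 limit
  if (stats::cor(x, y) < 0) y <- -y
  rng <- range(y)
  start_mid <- x[which.min(abs(y - mean(rng)))]
  s0 <- max(diff(range(x)) / 20, 0.05)
  dx <- stats::median(diff(x))
  ## sub-resolution edges (complete within ~2 samples) make the logistic
  ## scale collapse to its bound with a singular fit; report the empirical
  ## 10-90% width instead
  lev10 <- rng[1] + 0.1 * diff(rng)
  lev90 <- rng[1] + 0.9 * diff(rng)
  x10 <- tryCatch(min(x[y >= lev10]), warning = function(w) NA)
  x90 <- tryCatch(min(x[y >= lev90]), warning = function(w) NA)
  if (is.finite(x10) && is.finite(x90) && all(diff(y >= lev10) >= 0) &&
      all(diff(y >= lev90) >= 0) && (x90 - x10) <= 2 * dx)
    return(x90 - x10)
  fit <- NULL
  for (mid in c(start_mid, start_mid + dx, start_mid - dx)) {
    ## plogis is overflow-safe where the raw exp() form produces NaN
    ## gradients for very sharp edges; a couple of shifted starts work
    ## around occasional exact-fit convergence failures
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ lo + (hi - lo) * stats::plogis((x - xc) / s),
                        start = list(lo = rng[1], hi = rng[2],
                                     xc = mid, s = s0),
                        lower = c(-Inf, -Inf, min(x), 0.01),
                        upper = c(Inf, Inf, max(x), diff(range(x))),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) return(NA_real_)
  cf <- coef(fit)
  r2 <- 1 - sum(stats::residuals(fit)^2) / max(sum((y - mean(y))^2), 1e-30)
  if (!is.finite(r2) || r2 < 0.3) return(NA_real_)
  if (abs(cf["hi"] - cf["lo"]) < 0.05 * diff(rng)) return(NA_real_)
  2 * log(9) * abs(cf["s"])
}

#' Dose-reduction bookkeeping
#'
#' Percentage reduction in acquired projections relative to a reference scan,
#' the leading-order approximation of the scan-radiation reduction at fixed
#' per-projection exposure.
#'
#' @param n_proj,n_proj_ref projection counts of the scan and the reference.
#' @return percent in `[0, 100]` (negative if more projections were used).
#' @export
dose_reduction <- function(n_proj, n_proj_ref) {
  if (n_proj_ref <= 0) stop("reference projection count must be positive")
  100 * (1 - n_proj / n_proj_ref)
}

#' Motion-model robustness between reconstructions
#'
#' Deformably registers a motion-compensated image to a non-compensated
#' reference and summarizes the displacement field over the tumor mask:
#' per-axis mean and standard deviation plus mean/SD of the total
#' displacement magnitude. Small values indicate the motion model did not
#' displace the tumor relative to the reference anatomy.
#'
#' @param mc_image motion-compensated [volume3d].
#' @param reference_image non-compensated [volume3d] on the same grid.
#' @param tumor_mask logical array on the same grid.
#' @param cfg a [reg_config].
#' @return list with `mean_mm`, `sd_mm` (length-3 each), `total_mean_mm`,
#'   `total_sd_mm`, `n_voxels`.
#' @export
motion_robustness <- function(mc_image, reference_image, tumor_mask,
                              cfg = reg_config()) {
  if (!any(tumor_mask)) stop("empty tumor mask")
  V <- register_deformable(moving = mc_image, fixed = reference_image, cfg)
  comp <- lapply(1:3, function(a) V$disp[, , , a][tumor_mask])
  tot <- sqrt(comp[[1]]^2 + comp[[2]]^2 + comp[[3]]^2)
  list(mean_mm = vapply(comp, mean, 0), sd_mm = vapply(comp, sd, 0),
       total_mean_mm = mean(tot), total_sd_mm = sd(tot),
       n_voxels = sum(tumor_mask))
}
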