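#' Direct least-squares ellipse fit
#'
#' Fits an ellipse to 2D points with the ellipse-constrained direct
#' least-squares conic fit (Fitzgibbon's constraint, solved with the
#' numerically stable block decomposition of Halir & Flusser). Points are
#' centered and isotropically scaled before fitting. Used on the lag plot of
#' the surrogate signal, `(y(t), y(t - omega))`, whose center tracks the
#' baseline drift.
#'
#' @param points two-column matrix (or data.frame) of `(x, y)` coordinates.
#' @return An object of class `ellipse_model` with fields `center`,
#'   `semi_axes` (major >= minor), `orientation` (radians of the major axis in
#'   `[0, pi)`) and `fit_residual` (RMS radial distance, same units as input).
#' @export
fit_ellipse <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L || nrow(pts) < 6L)
    stop("need at least 6 (x, y) points")
  if (!all(is.finite(pts))) stop("points must be finite")
  ctr <- colMeans(pts)
  pc <- sweep(pts, 2, ctr)
  sv <- svd(pc, nu = 0, nv = 0)$d
  if (sv[1] == 0 || sv[2] / sv[1] < 1e-7)
    stop("degenerate (collinear) points: no breathing detected")
  scale <- mean(apply(pc, 2, sd))
  pn <- pc / scale
  x <- pn[, 1]; y <- pn[, 2]

  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("degenerate point configuration: no breathing detected"))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0) stop("no ellipse solution: no breathing detected")
  a1 <- vecs[, ok[1]]
  conic <- c(a1, as.numeric(Tm %*% a1))  # A B C D E F in normalized frame

  A <- conic[1]; B <- conic[2]; C <- conic[3]
  D <- conic[4]; E <- conic[5]; Fc <- conic[6]
  cen_n <- solve(matrix(c(2 * A, B, B, 2 * C), 2), -c(D, E))
  F0 <- A * cen_n[1]^2 + B * cen_n[1] * cen_n[2] + C * cen_n[2]^2 +
    D * cen_n[1] + E * cen_n[2] + Fc
  Q <- matrix(c(A, B / 2, B / 2, C), 2)
  eg <- eigen(Q, symmetric = TRUE)
  ax2 <- -F0 / eg$values
  if (any(ax2 <= 0)) stop("degenerate conic: no breathing detected")
  axes_n <- sqrt(ax2)
  major_i <- which.max(axes_n)
  vmaj <- eg$vectors[, major_i]
  theta <- atan2(vmaj[2], vmaj[1]) %% pi

  center <- cen_n * scale + ctr
  semi <- sort(axes_n * scale, decreasing = TRUE)

  ## RMS radial residual: |point radius - ellipse radius at same angle|
  rel <- sweep(pts, 2, center)
  ca <- cos(theta); sa <- sin(theta)
  u <- rel[, 1] * ca + rel[, 2] * sa
  v <- -rel[, 1] * sa + rel[, 2] * ca
  ang <- atan2(v / semi[2], u / semi[1])
  r_ell <- sqrt((semi[1] * cos(ang))^2 + (semi[2] * sin(ang))^2)
  resid <- sqrt(mean((sqrt(u^2 + v^2) - r_ell)^2))

  structure(list(center = center, semi_axes = semi, orientation = theta,
                 fit_residual = resid),
            class = "ellipse_model")
}

#' @export
print.ellipse_model <- function(x, ...) {
  cat(sprintf("<ellipse_model> center (%.3g, %.3g), axes (%.3g, %.3g), angle %.1f deg, RMS resid %.3g\n",
              x$center[1], x$center[2], x$semi_axes[1], x$semi_axes[2],
              x$orientation * 180 / pi, x$fit_residual))
  invisible(x)
}

## elliptical angle of a point about the model center, measured from the
## positive major axis in the traversal direction, in [0, 2*pi)
ellipse_angle <- function(model, point, direction = 1) {
  rel <- as.numeric(point) - model$center
  ca <- cos(model$orientation); sa <- sin(model$orientation)
  u <- rel[1] * ca + rel[2] * sa
  v <- -rel[1] * sa + rel[2] * ca
  ang <- atan2(v / model$semi_axes[2], u / model$semi_axes[1])
  if (direction < 0) ang <- -ang
  ang %% (2 * pi)
}

#' Respiratory bin of a lag-plot point
#'
#' Divides the fitted ellipse into `n_bins` equal angular sectors starting at
#' the positive major axis and returns the sector ("phase") of the given
#' point. The angle is the elliptical angle in the frame of the ellipse axes,
#' measured in the traversal direction, so points off the ellipse are
#' projected by angle. For a surrogate lag plot the positive major axis
#' corresponds to peak inhale, so bin 1 begins at peak inhale.
#'
#' @param model an [fit_ellipse] result.
#' @param point numeric length-2, `(y(t), y(t - omega))`.
#' @param direction traversal sign (+1 counterclockwise, -1 clockwise).
#' @param n_bins number of respiratory bins.
#' @return integer bin in `1..n_bins`.
#' @export
phase_from_point <- function(model, point, direction = 1, n_bins = 10) {
  ang <- ellipse_angle(model, point, direction)
  as.integer(pmin(floor(ang / (2 * pi) * n_bins) + 1L, n_bins))
}
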