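# Astigmatic elliptical-Gaussian PSF model and analytic derivatives.
#
# The unit-peak model at pixel (i, j) for an emitter at (x, y, z):
#   u = (i - x) cos(phi) + (j - y) sin(phi)
#   v = -(i - x) sin(phi) + (j - y) cos(phi)
#   PSF = exp(-u^2 / (2 sigma_x(z)^2) - v^2 / (2 sigma_y(z)^2))
# sigma_x and sigma_y are the calibrated B-spline curves over z.

checkZRange <- function(calib, z) {
  if (any(z < calib@zRange[1L] - 1e-9) || any(z > calib@zRange[2L] + 1e-9))
    stop(sprintf("z = %g nm outside the calibrated range [%g, %g] nm",
                 z[which(z < calib@zRange[1L] | z > calib@zRange[2L])][1L],
                 calib@zRange[1L], calib@zRange[2L]), call. = FALSE)
  invisible(TRUE)
}

#' PSF widths at an axial position
#'
#' Evaluates the calibrated \eqn{\sigma_x(z)}, \eqn{\sigma_y(z)} cubic
#' B-spline curves (and optionally their first derivatives).
#'
#' @param calib an [AstigmaticCalibration-class].
#' @param z axial position(s), nm; must lie within `zRange(calib)`.
#' @param deriv 0 for the widths, 1 for d sigma / d z (pixels/nm).
#' @return list with numeric vectors `sx` and `sy` (pixels).
#' @export
sigmaOfZ <- function(calib, z, deriv = 0L) {
  checkZRange(calib, z)
  list(sx = evalBSpline(calib@sxSpline, z, deriv),
       sy = evalBSpline(calib@sySpline, z, deriv))
}

#' Evaluate the astigmatic Gaussian PSF
#'
#' Unit-peak elliptical Gaussian centered on the emitter; returns the
#' intensity fraction at pixel centers `(i, j)`.
#'
#' @param calib an [AstigmaticCalibration-class].
#' @param x,y emitter position, pixels.
#' @param z emitter axial position, nm (within the calibrated range).
#' @param i,j pixel center coordinates (x-like and y-like), same length or
#'   scalar; recycled against each other.
#' @return numeric vector of intensity fractions in `(0, 1]`.
#' @export
psfValue <- function(calib, x, y, z, i, j) {
  s <- sigmaOfZ(calib, z)
  di <- i - x
  dj <- j - y
  cp <- cos(calib@phi); sp <- sin(calib@phi)
  u <- di * cp + dj * sp
  v <- -di * sp + dj * cp
  exp(-u^2 / (2 * s$sx^2) - v^2 / (2 * s$sy^2))
}

#' Analytic PSF gradient with respect to the emitter position
#'
#' Partial derivatives of [psfValue()] with respect to x, y (per pixel)
#' and z (per nm, through the spline derivatives d sigma/dz).
#'
#' @inheritParams psfValue
#' @return list of numeric vectors `dx`, `dy`, `dz`.
#' @export
psfGradient <- function(calib, x, y, z, i, j) {
  s <- sigmaOfZ(calib, z)
  ds <- sigmaOfZ(calib, z, deriv = 1L)
  di <- i - x
  dj <- j - y
  cp <- cos(calib@phi); sp <- sin(calib@phi)
  u <- di * cp + dj * sp
  v <- -di * sp + dj * cp
  p <- exp(-u^2 / (2 * s$sx^2) - v^2 / (2 * s$sy^2))
  # d/dx: du/dx = -cos, dv/dx = +sin; d/dy: du/dy = -sin, dv/dy = -cos
  dx <- p * (u * cp / s$sx^2 - v * sp / s$sy^2)
  dy <- p * (u * sp / s$sx^2 + v * cp / s$sy^2)
  dz <- p * (u^2 / s$sx^3 * ds$sx + v^2 / s$sy^3 * ds$sy)
  list(dx = dx, dy = dy, dz = dz)
}

#' Pixel-integrated astigmatic Gaussian PSF
#'
#' Integral of the Gaussian over the unit pixel area centered at `(i, j)`,
#' accounting for camera pixelation. With `rescaled = TRUE` (the default)
#' the integral is multiplied by \eqn{2\pi\sigma_x(z)\sigma_y(z)} so that
#' integrated intensities convert to peak intensities and the central
#' pixel value approaches 1 as sigma grows; with `rescaled = FALSE` the
#' raw integrals sum to a total flux of 1 over a large window.
#'
#' Only the axis-aligned case is integrable in the separable erf form;
#' for `phi != 0` the point-sampled model is returned with a warning.
#'
#' @inheritParams psfValue
#' @param rescaled logical; see Details.
#' @return numeric vector of per-pixel intensities.
#' @export
psfValueIntegrated <- function(calib, x, y, z, i, j, rescaled = TRUE) {
  if (abs(calib@phi) > 1e-12) {
    warning("integrated PSF model requires phi = 0; falling back to the sampled model")
    return(psfValue(calib, x, y, z, i, j))
  }
  s <- sigmaOfZ(calib, z)
  ex <- stats::pnorm((i - x + 0.5) / s$sx) - stats::pnorm((i - x - 0.5) / s$sx)
  ey <- stats::pnorm((j - y + 0.5) / s$sy) - stats::pnorm((j - y - 0.5) / s$sy)
  val <- ex * ey
  if (rescaled) val <- 2 * pi * s$sx * s$sy * val
  val
}

#' Gradient of the pixel-integrated PSF (rescaled form)
#'
#' Analytic partials of [psfValueIntegrated()] (with `rescaled = TRUE`)
#' with respect to the emitter position; the z derivative includes both
#' the \eqn{2\pi\sigma_x\sigma_y} prefactor and the erf-argument terms
#' through d sigma/dz. Requires `phi = 0`.
#'
#' @inheritParams psfValue
#' @return list of numeric vectors `dx`, `dy`, `dz`.
#' @export
psfGradientIntegrated <- function(calib, x, y, z, i, j) {
  if (abs(calib@phi) > 1e-12)
    stop("integrated PSF gradient requires phi = 0")
  s <- sigmaOfZ(calib, z)
  ds <- sigmaOfZ(calib, z, deriv = 1L)
  ax1 <- (i - x + 0.5) / s$sx; ax0 <- (i - x - 0.5) / s$sx
  ay1 <- (j - y + 0.5) / s$sy; ay0 <- (j - y - 0.5) / s$sy
  ex <- stats::pnorm(ax1) - stats::pnorm(ax0)
  ey <- stats::pnorm(ay1) - stats::pnorm(ay0)
  dx1 <- stats::dnorm(ax1); dx0 <- stats::dnorm(ax0)
  dy1 <- stats::dnorm(ay1); dy0 <- stats::dnorm(ay0)
  pre <- 2 * pi * s$sx * s$sy
  # d ex / dx = (dnorm(ax0) - dnorm(ax1)) / sx
  dExDx <- (dx0 - dx1) / s$sx
  dEyDy <- (dy0 - dy1) / s$sy
  # d ex / d sx = (dnorm(ax0) * ax0 - dnorm(ax1) * ax1) / sx
  dExDsx <- (dx0 * ax0 - dx1 * ax1) / s$sx
  dEyDsy <- (dy0 * ay0 - dy1 * ay1) / s$sy
  dx <- pre * dExDx * ey
  dy <- pre * ex * dEyDy
  dz <- ds$sx * (2 * pi * s$sy * ex * ey + pre * dExDsx * ey) +
        ds$sy * (2 * pi * s$sx * ex * ey + pre * ex * dEyDsy)
  list(dx = dx, dy = dy, dz = dz)
}
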