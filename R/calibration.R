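# Axial calibration: sigma_x(z), sigma_y(z) from bead z-stacks.

#' Build a calibration from sampled width curves
#'
#' Fits least-squares clamped cubic B-splines (knots at every other
#' sampled plane) through `(z, sigmaX)` and `(z, sigmaY)` and derives the
#' focal plane as the argmin of \eqn{\sigma_x(z)\sigma_y(z)} on a fine
#' grid.
#'
#' @param z strictly increasing axial positions, nm.
#' @param sigmaX,sigmaY PSF widths at `z`, pixels.
#' @param phi rotation of the elliptical Gaussian, radians.
#' @param pixelSize nm per pixel.
#' @param knotEvery take every `knotEvery`-th interior plane as a knot.
#' @return an [AstigmaticCalibration-class].
#' @export
calibrationFromCurves <- function(z, sigmaX, sigmaY, phi = 0,
                                  pixelSize = 100, knotEvery = 2L) {
  if (is.unsorted(z, strictly = TRUE))
    stop("z must be strictly increasing")
  sx <- fitBSpline(z, sigmaX, knotEvery)
  sy <- fitBSpline(z, sigmaY, knotEvery)
  zz <- seq(min(z), max(z), length.out = 2001L)
  prod <- evalBSpline(sx, zz) * evalBSpline(sy, zz)
  # among (numerically) tied minima pick the z closest to the range
  # center, so degenerate flat curves get a sensible focal plane
  near <- which(prod <= min(prod) + 1e-9 * max(prod))
  zFocus <- zz[near[which.min(abs(zz[near] - mean(range(z))))]]
  new("AstigmaticCalibration",
      sxSpline = sx, sySpline = sy, phi = phi,
      zRange = range(z), zFocus = zFocus,
      pixelSize = pixelSize)
}

#' Default synthetic astigmatic calibration
#'
#' The calibration used by the synthetic study conditions: classic
#' cylindrical-lens astigmatism with defocus curves
#' \eqn{\sigma_{x,y}(z) = \sigma_0\sqrt{1 + ((z \mp \delta)/z_R)^2}},
#' an in-focus width \eqn{\sigma_0 = 1.3} px, focal-plane separation
#' \eqn{2\delta = 500} nm and depth scale \eqn{z_R = 350} nm, sampled
#' every 25 nm over \eqn{\pm 600} nm and refit as B-splines exactly as a
#' measured bead calibration would be. The focal plane sits at z = 0.
#'
#' @param pixelSize nm per pixel.
#' @param sigma0 in-focus width, pixels.
#' @param delta half focal-plane separation, nm.
#' @param depth axial depth scale, nm.
#' @param zMax half range of the calibration, nm.
#' @return an [AstigmaticCalibration-class].
#' @export
defaultStarCalibration <- function(pixelSize = 100, sigma0 = 1.3,
                                   delta = 250, depth = 350, zMax = 600) {
  z <- seq(-zMax, zMax, by = 25)
  sx <- sigma0 * sqrt(1 + ((z - delta) / depth)^2)
  sy <- sigma0 * sqrt(1 + ((z + delta) / depth)^2)
  calibrationFromCurves(z, sx, sy, phi = 0, pixelSize = pixelSize)
}

# Unconstrained elliptical-Gaussian fit of one spot window.
# Parameters: bg, p, x, y (pixels, window coordinates), sx, sy (pixels).
# Returns the parameter vector or NULL when the optimizer fails.
#' @keywords internal
#' @noRd
fitEllipticalSpot <- function(win, phi = 0) {
  w <- nrow(win)
  ctr <- (w - 1) / 2
  ij <- expand.grid(i = 0:(w - 1), j = 0:(w - 1))
  obs <- as.numeric(win[cbind(ij$j + 1L, ij$i + 1L)])
  bg0 <- stats::median(win)
  p0 <- max(win) - bg0
  start <- c(bg = bg0, p = max(p0, 1e-6), x = ctr, y = ctr, sx = 1.5, sy = 1.5)
  cp <- cos(phi); sp <- sin(phi)
  fn <- function(th) {
    di <- ij$i - th[3L]; dj <- ij$j - th[4L]
    u <- di * cp + dj * sp
    v <- -di * sp + dj * cp
    obs - (th[1L] + th[2L] * exp(-u^2 / (2 * th[5L]^2) - v^2 / (2 * th[6L]^2)))
  }
  res <- try(minpack.lm::nls.lm(
    par = start, fn = fn,
    lower = c(-Inf, 0, 0, 0, 0.3, 0.3),
    upper = c(Inf, Inf, w - 1, w - 1, w, w),
    control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
  if (inherits(res, "try-error") || !res$info %in% 1:4) return(NULL)
  res$par
}

#' Calibrate the axial shape map from a bead z-stack
#'
#' For every plane of a bead z-stack, fits each bead with an
#' unconstrained elliptical Gaussian and averages the recovered
#' \eqn{\sigma_x}, \eqn{\sigma_y} over beads; then fits cubic B-splines
#' through the per-plane widths and sets the focal plane to the argmin of
#' \eqn{\sigma_x(z)\sigma_y(z)}.
#'
#' Beads are located in the sharpest plane (largest peak) by the same
#' modified non-maximum suppression used for emitter detection and then
#' followed through the remaining planes at fixed lateral positions.
#'
#' @param stack list of 2D count matrices (one per z plane) or a 3D array
#'   with the plane as the third dimension.
#' @param zPositions strictly monotone stage z positions, nm.
#' @param threshold detection threshold (counts above local background)
#'   used to find beads in the reference plane.
#' @param beadWindow odd fit-window side, pixels; generous enough to hold
#'   the defocused bead image.
#' @param phi rotation passed through to the calibration.
#' @param pixelSize nm per pixel.
#' @param knotEvery spline knot spacing in planes.
#' @return an [AstigmaticCalibration-class].
#' @export
calibrateFromBeads <- function(stack, zPositions, threshold = 100,
                               beadWindow = 15L, phi = 0, pixelSize = 100,
                               knotEvery = 2L) {
  if (is.array(stack) && length(dim(stack)) == 3L)
    stack <- lapply(seq_len(dim(stack)[3L]), function(k) stack[, , k])
  if (length(stack) != length(zPositions))
    stop("one z position per plane required")
  if (is.unsorted(zPositions, strictly = TRUE) &&
      is.unsorted(rev(zPositions), strictly = TRUE))
    stop("zPositions must be strictly monotone")
  half <- beadWindow %/% 2L
  # reference plane: largest peak value (sharpest bead images)
  ref <- which.max(vapply(stack, max, numeric(1)))
  cand <- findCandidates(stack[[ref]], threshold = threshold,
                         suppressionRadius = beadWindow,
                         bgWindow = beadWindow + 2L,
                         fitWindow = beadWindow)
  if (nrow(cand) == 0L)
    stop(sprintf("no detectable bead in reference plane %d", ref))
  nPlane <- length(stack)
  sxMat <- matrix(NA_real_, nPlane, nrow(cand))
  syMat <- matrix(NA_real_, nPlane, nrow(cand))
  for (pl in seq_len(nPlane)) {
    frame <- stack[[pl]]
    ok <- FALSE
    for (b in seq_len(nrow(cand))) {
      r0 <- cand$py[b] + 1L; c0 <- cand$px[b] + 1L
      if (r0 - half < 1L || r0 + half > nrow(frame) ||
          c0 - half < 1L || c0 + half > ncol(frame)) next
      win <- frame[(r0 - half):(r0 + half), (c0 - half):(c0 + half)]
      fit <- fitEllipticalSpot(win, phi)
      if (is.null(fit) || fit[["p"]] <= threshold / 2) next
      sxMat[pl, b] <- fit[["sx"]]
      syMat[pl, b] <- fit[["sy"]]
      ok <- TRUE
    }
    if (!ok)
      stop(sprintf("no detectable bead in plane %d (z = %g nm)",
                   pl, zPositions[pl]))
  }
  sx <- rowMeans(sxMat, na.rm = TRUE)
  sy <- rowMeans(syMat, na.rm = TRUE)
  ord <- order(zPositions)
  calibrationFromCurves(zPositions[ord], sx[ord], sy[ord], phi = phi,
                        pixelSize = pixelSize, knotEvery = knotEvery)
}

#' Serialize / restore a calibration
#'
#' The calibration is stored as a single JSON file holding the spline
#' knots and coefficients, `phi`, the z range, the focal plane and the
#' pixel size, so it round-trips losslessly.
#'
#' @param calib an [AstigmaticCalibration-class].
#' @param path file path.
#' @return `readCalibration` returns the restored object;
#'   `writeCalibration` returns `path` invisibly.
#' @export
writeCalibration <- function(calib, path) {
  obj <- list(
    sxSpline = calib@sxSpline, sySpline = calib@sySpline,
    phi = calib@phi, zRange = calib@zRange, zFocus = calib@zFocus,
    pixelSize = calib@pixelSize)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix <- function(sp) list(knots = as.numeric(sp$knots),
                           coefs = as.numeric(sp$coefs),
                           ord = as.integer(sp$ord))
  new("AstigmaticCalibration",
      sxSpline = fix(obj$sxSpline), sySpline = fix(obj$sySpline),
      phi = as.numeric(obj$phi), zRange = as.numeric(obj$zRange),
      zFocus = as.numeric(obj$zFocus), pixelSize = as.numeric(obj$pixelSize))
}
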