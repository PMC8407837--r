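# Shared numeric helpers.
#
# Coordinate convention used throughout the package (stated once here and in
# the vignette): pixel centers sit at integer coordinates, x runs along
# columns and y along rows, both 0-based and in pixel units; z is in nm in
# the calibration's axial coordinate (the focal plane of a simulated
# calibration is at z = 0).

#' Round half away from zero
#'
#' Deterministic grid rounding used when snapping fit parameters onto the
#' lookup-table grid: ties (exact half steps) round away from the grid
#' center rather than to even, so the mapping is symmetric about 0.
#'
#' @param v numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
roundHalfAway <- function(v) {
  sign(v) * floor(abs(v) + 0.5)
}

#' @keywords internal
#' @noRd
isOdd <- function(n) n %% 2 == 1

#' @keywords internal
#' @noRd
stopIfNotScalarNumeric <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}

# Least-squares cubic B-spline with clamped (4-fold) boundary knots.
# Stored as a plain list so it serializes to JSON without loss.
#' @keywords internal
#' @noRd
fitBSpline <- function(x, y, knotEvery = 2L) {
  ord <- 4L
  n <- length(x)
  if (n < 5L) stop("need at least 5 points to fit a cubic B-spline")
  if (is.unsorted(x, strictly = TRUE))
    stop("spline abscissae must be strictly increasing")
  interior <- x[seq(3L, n - 2L, by = knotEvery)]
  knots <- c(rep(x[1L], ord), interior, rep(x[n], ord))
  B <- splines::splineDesign(knots, x, ord = ord)
  coefs <- qr.coef(qr(B), y)
  list(knots = as.numeric(knots), coefs = as.numeric(coefs), ord = ord)
}

#' @keywords internal
#' @noRd
evalBSpline <- function(sp, x, deriv = 0L) {
  B <- splines::splineDesign(sp$knots, x, ord = sp$ord,
                             derivs = rep(deriv, length(x)))
  as.numeric(B %*% sp$coefs)
}
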