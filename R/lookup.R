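# Lookup table: pre-computed PSF templates and derivatives on the
# discrete (x, y, z) grid, with O(1) index arithmetic.

#' Create a lookup-table specification
#'
#' Grid convention: lateral offsets cover `[-rxy/2, +rxy/2]` inclusive in
#' steps of `dxy` (`nxy = rxy/dxy + 1` positions per axis), the axial grid
#' covers `[zFocus - rz/2, zFocus + rz/2]` in steps of `dz`
#' (`nz = rz/dz + 1`). `rxy/2` and `rz/2` must therefore be integer
#' multiples of the corresponding step so the grid is symmetric around
#' the center.
#'
#' @param window odd template side length, pixels.
#' @param dxy lateral step, pixels.
#' @param rxy total lateral span, pixels.
#' @param dz axial step, nm.
#' @param rz total axial span, nm.
#' @param precision `"double"` (default) or `"single"`; storage intent
#'   reported by [memoryFootprint()].
#' @return a [LookupTableSpec-class].
#' @export
lookupTableSpec <- function(window = 9L, dxy = 0.1, rxy = 4, dz = 25,
                            rz = 1000, precision = "double") {
  new("LookupTableSpec", window = as.integer(window), dxy = dxy, rxy = rxy,
      dz = dz, rz = rz, precision = precision)
}

#' @keywords internal
#' @noRd
gridSizes <- function(spec) {
  c(nxy = as.integer(round(spec@rxy / spec@dxy)) + 1L,
    nz = as.integer(round(spec@rz / spec@dz)) + 1L)
}

#' Number of templates in a table or spec
#'
#' @param x a [LookupTableSpec-class] or [LookupTable-class].
#' @return integer count `nxy^2 * nz`.
#' @export
setGeneric("nTemplates", function(x) standardGeneric("nTemplates"))

#' @rdname nTemplates
#' @export
setMethod("nTemplates", "LookupTableSpec", function(x) {
  g <- gridSizes(x)
  as.integer(as.numeric(g[["nxy"]])^2 * g[["nz"]])
})

#' @rdname nTemplates
#' @export
setMethod("nTemplates", "LookupTable", function(x) dim(x@templates)[4L])

#' Memory footprint of a (prospective) lookup table in bytes
#'
#' `nTemplates * window^2 * 4 channels * bytes per value` (8 for double,
#' 4 for single precision).
#'
#' @param x a [LookupTableSpec-class] or [LookupTable-class].
#' @return numeric, bytes.
#' @export
setGeneric("memoryFootprint", function(x) standardGeneric("memoryFootprint"))

#' @rdname memoryFootprint
#' @export
setMethod("memoryFootprint", "LookupTableSpec", function(x) {
  bytes <- if (x@precision == "double") 8 else 4
  as.numeric(nTemplates(x)) * x@window^2 * 4 * bytes
})

#' @rdname memoryFootprint
#' @export
setMethod("memoryFootprint", "LookupTable", function(x) memoryFootprint(x@spec))

#' Build the lookup table
#'
#' Evaluates the PSF model and its three positional derivatives on a
#' `window x window` pixel grid at every discrete `(x, y, z)` grid point.
#' Templates are stored in one contiguous array with the 0-based index
#' `k = ((ix * nxy) + iy) * nz + iz` (z fastest; exposed 1-based in R) so
#' lookup is pure arithmetic. Building is deterministic: two builds from
#' the same inputs are bitwise identical.
#'
#' Template images are oriented like extracted frame windows: rows are y
#' (j), columns are x (i); the emitter sits at the window center plus the
#' grid offset.
#'
#' @param spec a [LookupTableSpec-class].
#' @param calib an [AstigmaticCalibration-class] whose `zRange` covers
#'   `[zFocus - rz/2, zFocus + rz/2]`.
#' @param model `"sampled"` point-sampled Gaussian (default) or
#'   `"integrated"` pixel-integrated Gaussian (requires `phi = 0`).
#' @param verbose print the template count and memory footprint.
#' @return a [LookupTable-class].
#' @export
buildTable <- function(spec, calib, model = c("sampled", "integrated"),
                       verbose = FALSE) {
  model <- match.arg(model)
  g <- gridSizes(spec)
  nxy <- g[["nxy"]]; nz <- g[["nz"]]
  w <- spec@window
  half <- spec@rxy / 2
  xOff <- seq(-half, half, length.out = nxy)
  yOff <- xOff
  zVal <- seq(calib@zFocus - spec@rz / 2, calib@zFocus + spec@rz / 2,
              length.out = nz)
  if (zVal[1L] < calib@zRange[1L] - 1e-9 || zVal[nz] > calib@zRange[2L] + 1e-9)
    stop(sprintf(
      "calibration range [%g, %g] nm does not cover the axial grid [%g, %g] nm",
      calib@zRange[1L], calib@zRange[2L], zVal[1L], zVal[nz]), call. = FALSE)
  if (model == "integrated" && abs(calib@phi) > 1e-12)
    stop("integrated model requires phi = 0")
  n <- nxy^2 * nz
  arr <- array(0, dim = c(w, w, 4L, n))
  ctr <- (w - 1) / 2
  pix <- 0:(w - 1)
  s <- sigmaOfZ(calib, zVal)
  ds <- sigmaOfZ(calib, zVal, deriv = 1L)
  fastPath <- abs(calib@phi) <= 1e-12
  for (izi in seq_len(nz)) {
    sx <- s$sx[izi]; sy <- s$sy[izi]
    dsx <- ds$sx[izi]; dsy <- ds$sy[izi]
    kIdx <- izi + nz * (0:(nxy^2 - 1L))
    if (fastPath) {
      U <- outer(pix, ctr + xOff, "-")        # w x nxy, i - x
      V <- outer(pix, ctr + yOff, "-")        # w x nxy, j - y
      if (model == "sampled") {
        ex <- exp(-U^2 / (2 * sx^2))
        ey <- exp(-V^2 / (2 * sy^2))
        dex <- ex * U / sx^2
        dey <- ey * V / sy^2
        exz <- ex * U^2 / sx^3 * dsx
        eyz <- ey * V^2 / sy^3 * dsy
      } else {
        cx <- sqrt(2 * pi) * sx
        cy <- sqrt(2 * pi) * sy
        ax1 <- (U + 0.5) / sx; ax0 <- (U - 0.5) / sx
        ay1 <- (V + 0.5) / sy; ay0 <- (V - 0.5) / sy
        Ex <- stats::pnorm(ax1) - stats::pnorm(ax0)
        Ey <- stats::pnorm(ay1) - stats::pnorm(ay0)
        ex <- cx * Ex
        ey <- cy * Ey
        dex <- cx * (stats::dnorm(ax0) - stats::dnorm(ax1)) / sx
        dey <- cy * (stats::dnorm(ay0) - stats::dnorm(ay1)) / sy
        # d(cx * Ex)/d sx * dsx/dz
        exz <- dsx * (sqrt(2 * pi) * Ex +
                      cx * (stats::dnorm(ax0) * ax0 - stats::dnorm(ax1) * ax1) / sx)
        eyz <- dsy * (sqrt(2 * pi) * Ey +
                      cy * (stats::dnorm(ay0) * ay0 - stats::dnorm(ay1) * ay1) / sy)
      }
      # outer(A[j, iy], B[i, ix]) -> [j, iy, i, ix]; reorder to [j, i, iy, ix]
      shape <- function(A) {
        dim(A) <- c(w, w, nxy^2)
        A
      }
      arr[, , 1L, kIdx] <- shape(aperm(outer(ey, ex), c(1L, 3L, 2L, 4L)))
      arr[, , 2L, kIdx] <- shape(aperm(outer(ey, dex), c(1L, 3L, 2L, 4L)))
      arr[, , 3L, kIdx] <- shape(aperm(outer(dey, ex), c(1L, 3L, 2L, 4L)))
      arr[, , 4L, kIdx] <- shape(aperm(outer(eyz, ex) + outer(ey, exz),
                                       c(1L, 3L, 2L, 4L)))
    } else {
      grid <- expand.grid(j = pix, i = pix)  # j fastest: matrix rows are y
      for (ixi in seq_len(nxy)) for (iyi in seq_len(nxy)) {
        k <- (( (ixi - 1L) * nxy) + (iyi - 1L)) * nz + izi
        x0 <- ctr + xOff[ixi]; y0 <- ctr + yOff[iyi]
        v <- psfValue(calib, x0, y0, zVal[izi], grid$i, grid$j)
        gr <- psfGradient(calib, x0, y0, zVal[izi], grid$i, grid$j)
        arr[, , 1L, k] <- matrix(v, w, w)          # [j, i] since j fastest
        arr[, , 2L, k] <- matrix(gr$dx, w, w)
        arr[, , 3L, k] <- matrix(gr$dy, w, w)
        arr[, , 4L, k] <- matrix(gr$dz, w, w)
      }
    }
  }
  tab <- new("LookupTable", spec = spec, calib = calib, templates = arr,
             xOffsets = xOff, yOffsets = yOff, zValues = zVal, model = model)
  if (verbose)
    message(sprintf("lookup table: %d templates, %.1f MB (%s precision)",
                    n, memoryFootprint(tab) / 2^20, spec@precision))
  tab
}

# Index arithmetic shared by indexOf and the fitter. Returns the 1-based
# template index plus out-of-range flags (the fitter turns these into
# termination codes rather than errors).
#' @keywords internal
#' @noRd
indexParts <- function(spec, x, y, z, zFocus) {
  g <- gridSizes(spec)
  nxy <- g[["nxy"]]; nz <- g[["nz"]]
  hx <- (nxy - 1L) %/% 2L
  hz <- (nz - 1L) %/% 2L
  ix <- roundHalfAway(x / spec@dxy)
  iy <- roundHalfAway(y / spec@dxy)
  iz <- roundHalfAway((z - zFocus) / spec@dz)
  oobLat <- abs(ix) > hx | abs(iy) > hx
  oobAx <- abs(iz) > hz
  k <- ((ix + hx) * nxy + (iy + hx)) * nz + (iz + hz) + 1
  k[oobLat | oobAx] <- NA_integer_
  list(k = as.integer(k), oobLateral = oobLat, oobAxial = oobAx)
}

#' Template index of a (rounded) position
#'
#' Maps continuous parameters to the index of the nearest grid point
#' (rounding half away from the grid center). Out-of-range positions
#' yield `NA` -- inside the fitter this is a termination condition, not
#' an error.
#'
#' @param x a [LookupTable-class] or [LookupTableSpec-class].
#' @param thetaX,thetaY lateral offsets from the window center, pixels.
#' @param thetaZ axial position, nm.
#' @param zFocus grid center in z, nm (taken from the calibration when a
#'   full table is supplied).
#' @return integer vector of 1-based template indices (`NA` out of range).
#' @export
setGeneric("indexOf", function(x, thetaX, thetaY, thetaZ, ...)
  standardGeneric("indexOf"))

#' @rdname indexOf
#' @export
setMethod("indexOf", "LookupTableSpec",
  function(x, thetaX, thetaY, thetaZ, zFocus = 0) {
    indexParts(x, thetaX, thetaY, thetaZ, zFocus)$k
  })

#' @rdname indexOf
#' @export
setMethod("indexOf", "LookupTable",
  function(x, thetaX, thetaY, thetaZ) {
    indexParts(x@spec, thetaX, thetaY, thetaZ, x@calib@zFocus)$k
  })

#' Extract one template
#'
#' @param table a [LookupTable-class].
#' @param k 1-based template index.
#' @return list of four `window x window` matrices `psf`, `dx`, `dy`,
#'   `dz` (rows are y, columns are x).
#' @export
templateAt <- function(table, k) {
  n <- nTemplates(table)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k > n)
    stop(sprintf("template index must be in [1, %d]", n), call. = FALSE)
  list(psf = table@templates[, , 1L, k],
       dx = table@templates[, , 2L, k],
       dy = table@templates[, , 3L, k],
       dz = table@templates[, , 4L, k])
}

#' Grid coordinates of a template index
#'
#' Inverse of [indexOf()] on grid points.
#'
#' @param table a [LookupTable-class].
#' @param k 1-based template index (vectorized).
#' @return data.frame with columns `x`, `y` (pixel offsets) and `z` (nm).
#' @export
gridPointOf <- function(table, k) {
  g <- gridSizes(table@spec)
  nxy <- g[["nxy"]]; nz <- g[["nz"]]
  k0 <- as.integer(k) - 1L
  iz <- k0 %% nz
  lat <- k0 %/% nz
  iy <- lat %% nxy
  ix <- lat %/% nxy
  data.frame(x = table@xOffsets[ix + 1L],
             y = table@yOffsets[iy + 1L],
             z = table@zValues[iz + 1L])
}

setMethod("show", "LookupTableSpec", function(object) {
  g <- gridSizes(object)
  cat(sprintf(
    "LookupTableSpec: window %d px, dxy %g px over +/-%g px (%d steps/axis),\n  dz %g nm over +/-%g nm (%d steps); %d templates, %.1f MB (%s)\n",
    object@window, object@dxy, object@rxy / 2, g[["nxy"]],
    object@dz, object@rz / 2, g[["nz"]], nTemplates(object),
    memoryFootprint(object) / 2^20, object@precision))
})

setMethod("show", "LookupTable", function(object) {
  cat(sprintf("LookupTable (%s model) built from calibration with zFocus %.1f nm\n",
              object@model, object@calib@zFocus))
  show(object@spec)
})

setMethod("show", "AstigmaticCalibration", function(object) {
  s <- sigmaOfZ(object, object@zFocus)
  cat(sprintf(
    "AstigmaticCalibration: z in [%g, %g] nm, focus at %.1f nm (sigma %.2f x %.2f px),\n  phi %.3f rad, pixel %g nm\n",
    object@zRange[1L], object@zRange[2L], object@zFocus, s$sx, s$sy,
    object@phi, object@pixelSize))
})
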