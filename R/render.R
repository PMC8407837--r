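# Real-time histogram rendering: max-z super-resolution binning plus a
# rainbow color render with a Gaussian gradient around occupied bins.

#' Render localizations into a max-z histogram image
#'
#' Bins localizations into a super-resolution grid `scale` times finer
#' than the camera frame; each bin keeps the highest axial position that
#' fell into it. A localization at `(x, y)` pixels lands in the 0-based
#' bin `(floor(x * scale), floor(y * scale))`.
#'
#' @param localizations data.frame with `x_px`, `y_px` (pixels) and
#'   `z_nm`.
#' @param frameShape camera frame shape `c(rows, cols)`.
#' @param scale super-resolution factor (default 10).
#' @param sigmaPx Gaussian gradient sigma for the color render, in
#'   rendered pixels.
#' @param zRange z interval mapped onto the color table (defaults to the
#'   data range).
#' @param color also produce the rainbow-coded RGB image (slower).
#' @return list with `zMap` (matrix, max z per bin, 0 where empty; rows
#'   are y) and `rgb` (`rows x cols x 3` array in `[0, 1]`, or NULL).
#' @export
renderHistogram <- function(localizations, frameShape, scale = 10L,
                            sigmaPx = 1, zRange = NULL, color = TRUE) {
  nr <- frameShape[1L] * scale
  nc <- frameShape[2L] * scale
  zMap <- matrix(0, nr, nc)
  occ <- matrix(FALSE, nr, nc)
  st <- updateZMap(list(zMap = zMap, occ = occ, scale = scale), localizations)
  rgb <- if (color) renderColorMap(st$zMap, st$occ, sigmaPx, zRange) else NULL
  list(zMap = st$zMap, rgb = rgb)
}

#' @keywords internal
#' @noRd
updateZMap <- function(state, localizations) {
  if (!nrow(localizations)) return(state)
  bx <- floor(localizations$x_px * state$scale) + 1L
  by <- floor(localizations$y_px * state$scale) + 1L
  ok <- bx >= 1L & bx <= ncol(state$zMap) & by >= 1L & by <= nrow(state$zMap)
  bx <- bx[ok]; by <- by[ok]
  z <- localizations$z_nm[ok]
  for (idx in seq_along(bx)) {
    if (!state$occ[by[idx], bx[idx]] || z[idx] > state$zMap[by[idx], bx[idx]]) {
      state$zMap[by[idx], bx[idx]] <- z[idx]
      state$occ[by[idx], bx[idx]] <- TRUE
    }
  }
  state
}

# Rainbow color render: occupied bins are drawn at full intensity in the
# color of their z; empty bins bordering (8-neighborhood) an occupied bin
# inherit the color of the highest-z neighbor, attenuated by a Gaussian
# in the center distance.
#' @keywords internal
#' @noRd
renderColorMap <- function(zMap, occ, sigmaPx = 1, zRange = NULL) {
  nr <- nrow(zMap); nc <- ncol(zMap)
  if (is.null(zRange)) {
    zr <- if (any(occ)) range(zMap[occ]) else c(0, 1)
  } else zr <- zRange
  if (diff(zr) <= 0) zr <- zr + c(-1, 1)
  pal <- grDevices::rainbow(256L, end = 0.7)
  colIdx <- function(z) pmin(pmax(1L + floor(255 * (z - zr[1L]) / diff(zr)),
                                  1L), 256L)
  rgbPal <- grDevices::col2rgb(pal) / 255
  out <- array(0, dim = c(nr, nc, 3L))
  # best (max z) neighbor value and its weight per empty pixel
  bestZ <- matrix(-Inf, nr, nc)
  bestW <- matrix(0, nr, nc)
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  for (s in seq_len(nrow(shifts))) {
    dr <- shifts$dr[s]; dc <- shifts$dc[s]
    w <- exp(-(dr^2 + dc^2) / (2 * sigmaPx^2))
    rT <- max(1L, 1L + dr):min(nr, nr + dr)
    rS <- rT - dr
    cT <- max(1L, 1L + dc):min(nc, nc + dc)
    cS <- cT - dc
    neighOcc <- occ[rS, cS, drop = FALSE]
    neighZ <- zMap[rS, cS, drop = FALSE]
    better <- neighOcc & (neighZ > bestZ[rT, cT, drop = FALSE])
    bz <- bestZ[rT, cT, drop = FALSE]; bw <- bestW[rT, cT, drop = FALSE]
    bz[better] <- neighZ[better]
    bw[better] <- w
    bestZ[rT, cT] <- bz
    bestW[rT, cT] <- bw
  }
  fillIdx <- which(!occ & is.finite(bestZ))
  occIdx <- which(occ)
  for (ch in 1:3) {
    plane <- matrix(0, nr, nc)
    if (length(occIdx))
      plane[occIdx] <- rgbPal[ch, colIdx(zMap[occIdx])]
    if (length(fillIdx))
      plane[fillIdx] <- rgbPal[ch, colIdx(bestZ[fillIdx])] * bestW[fillIdx]
    out[, , ch] <- plane
  }
  out
}

#' Initialize / advance the incremental renderer
#'
#' Streaming version of [renderHistogram()]: call [renderIncremental()]
#' once per frame with that frame's new localizations. The max-z map is
#' updated every call (order-independent, so the streamed result equals
#' the batch result exactly); the expensive color render is refreshed
#' only every `everyNFrames` frames.
#'
#' @param frameShape camera frame shape `c(rows, cols)`.
#' @param scale super-resolution factor.
#' @param everyNFrames color-render cadence in frames.
#' @param sigmaPx,zRange see [renderHistogram()].
#' @return a renderer state list; pass it to [renderIncremental()].
#' @export
renderState <- function(frameShape, scale = 10L, everyNFrames = 10L,
                        sigmaPx = 1, zRange = NULL) {
  nr <- frameShape[1L] * scale
  nc <- frameShape[2L] * scale
  list(zMap = matrix(0, nr, nc), occ = matrix(FALSE, nr, nc),
       scale = scale, everyNFrames = everyNFrames, sigmaPx = sigmaPx,
       zRange = zRange, frameCount = 0L, nRenders = 0L, rgb = NULL)
}

#' @rdname renderState
#' @param state state from [renderState()] / a previous call.
#' @param newLocalizations localizations of the newly analyzed frame.
#' @export
renderIncremental <- function(state, newLocalizations) {
  state <- updateZMap(state, newLocalizations)
  state$frameCount <- state$frameCount + 1L
  if (state$frameCount %% state$everyNFrames == 0L) {
    state$rgb <- renderColorMap(state$zMap, state$occ, state$sigmaPx,
                                state$zRange)
    state$nRenders <- state$nRenders + 1L
  }
  state
}

#' Render localizations as a Gaussian-blob image (for FRC)
#'
#' Draws every localization as a symmetric 2D Gaussian of fixed sigma on
#' a fine grid -- the standard rendering for Fourier-ring-correlation
#' resolution estimates (sigma 25 nm on 16.67 nm pixels by default).
#'
#' @param localizations data.frame with `x_nm`, `y_nm`.
#' @param extentNm image extent `c(width, height)` in nm.
#' @param pixelSize rendered pixel size, nm.
#' @param sigmaNm blob sigma, nm.
#' @return numeric matrix (rows are y).
#' @export
renderGaussianImage <- function(localizations, extentNm,
                                pixelSize = 100 / 6, sigmaNm = 25) {
  nc <- ceiling(extentNm[1L] / pixelSize)
  nr <- ceiling(extentNm[2L] / pixelSize)
  img <- matrix(0, nr, nc)
  if (!nrow(localizations)) return(img)
  sPx <- sigmaNm / pixelSize
  rad <- ceiling(3 * sPx)
  for (idx in seq_len(nrow(localizations))) {
    cxp <- localizations$x_nm[idx] / pixelSize
    cyp <- localizations$y_nm[idx] / pixelSize
    i0 <- max(0L, floor(cxp) - rad); i1 <- min(nc - 1L, ceiling(cxp) + rad)
    j0 <- max(0L, floor(cyp) - rad); j1 <- min(nr - 1L, ceiling(cyp) + rad)
    if (i1 < i0 || j1 < j0) next
    gx <- exp(-((i0:i1) - cxp)^2 / (2 * sPx^2))
    gy <- exp(-((j0:j1) - cyp)^2 / (2 * sPx^2))
    img[(j0:j1) + 1L, (i0:i1) + 1L] <- img[(j0:j1) + 1L, (i0:i1) + 1L] +
      outer(gy, gx)
  }
  img
}
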