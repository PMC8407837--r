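# Synthetic data generators: EMCCD noise chain, 3D Siemens-star movies,
# bead calibration stacks and blinking (photoswitching) movies.

#' EMCCD noise model constructor
#'
#' Defaults are the study conditions of the synthetic benchmark: baseline
#' 100 counts, EM gain 300, quantum efficiency 0.9, readout noise 74.4
#' counts rms, spurious charge 2e-4 events/pixel/frame.
#'
#' @param baseline counts.
#' @param emGain counts per photoelectron.
#' @param quantumEfficiency fraction in `[0, 1]`.
#' @param readoutNoise counts rms.
#' @param spuriousCharge events/pixel/frame.
#' @return an [EMCCDNoiseModel-class].
#' @export
emccdNoiseModel <- function(baseline = 100, emGain = 300,
                            quantumEfficiency = 0.9, readoutNoise = 74.4,
                            spuriousCharge = 2e-4) {
  new("EMCCDNoiseModel", baseline = baseline, emGain = emGain,
      quantumEfficiency = quantumEfficiency, readoutNoise = readoutNoise,
      spuriousCharge = spuriousCharge)
}

setMethod("show", "EMCCDNoiseModel", function(object) {
  cat(sprintf(
    "EMCCDNoiseModel: baseline %g, gain %g, QE %g, readout %g rms, spurious %g\n",
    object@baseline, object@emGain, object@quantumEfficiency,
    object@readoutNoise, object@spuriousCharge))
})

#' Apply the EMCCD counting chain to an expected-photon image
#'
#' Per pixel: photoelectrons ~ Poisson(QE * photons + spurious), electron
#' multiplication ~ Gamma(shape = electrons, scale = gain) (the standard
#' EMCCD approximation with excess-noise factor 2), Gaussian readout
#' noise, camera baseline, integer rounding.
#'
#' @param clean non-negative matrix of expected photons/pixel.
#' @param noise an [EMCCDNoiseModel-class].
#' @param seed optional integer; when given, the RNG state is set (and
#'   restored afterwards) so the draw is reproducible.
#' @return integer-valued matrix of counts (same shape as `clean`).
#' @export
applyEMCCDNoise <- function(clean, noise, seed = NULL) {
  if (any(clean < 0)) stop("expected photon image must be non-negative")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  lam <- noise@quantumEfficiency * as.numeric(clean) + noise@spuriousCharge
  n <- stats::rpois(length(lam), lam)
  out <- numeric(length(n))
  pos <- n > 0L
  if (any(pos))
    out[pos] <- stats::rgamma(sum(pos), shape = n[pos], scale = noise@emGain)
  out <- out + stats::rnorm(length(out), 0, noise@readoutNoise) + noise@baseline
  matrix(round(out), nrow(clean), ncol(clean))
}

# Render expected images. Emitters: data.frame with x, y (px, 0-based),
# z (nm), peak (expected peak counts above baseline). In count units the
# emitter contribution is peak * PSF; in photon units it is divided by
# gain * QE (the mean count per photon). Stamps span +-4 sigma.
#' @keywords internal
#' @noRd
renderExpectedFrame <- function(calib, emitters, nrowF, ncolF,
                                units = c("counts", "photons"), noise = NULL) {
  units <- match.arg(units)
  img <- matrix(0, nrowF, ncolF)
  if (!nrow(emitters)) return(img)
  conv <- if (units == "photons")
    1 / (noise@emGain * noise@quantumEfficiency) else 1
  s <- sigmaOfZ(calib, emitters$z)
  for (e in seq_len(nrow(emitters))) {
    rad <- ceiling(4 * max(s$sx[e], s$sy[e]))
    i0 <- max(0L, floor(emitters$x[e]) - rad)
    i1 <- min(ncolF - 1L, ceiling(emitters$x[e]) + rad)
    j0 <- max(0L, floor(emitters$y[e]) - rad)
    j1 <- min(nrowF - 1L, ceiling(emitters$y[e]) + rad)
    if (i1 < i0 || j1 < j0) next
    ii <- i0:i1; jj <- j0:j1
    grid <- expand.grid(j = jj, i = ii)
    v <- psfValue(calib, emitters$x[e], emitters$y[e], emitters$z[e],
                  grid$i, grid$j)
    img[jj + 1L, ii + 1L] <- img[jj + 1L, ii + 1L] +
      emitters$peak[e] * conv * matrix(v, length(jj), length(ii))
  }
  img
}

#' @keywords internal
#' @noRd
focusPeakScale <- function(calib, z, peakAtFocus) {
  sF <- sigmaOfZ(calib, calib@zFocus)
  s <- sigmaOfZ(calib, z)
  peakAtFocus * (sF$sx * sF$sy) / (s$sx * s$sy)
}

#' Simulate a 3D Siemens-star SMLM movie
#'
#' Ground-truth geometry: a radial star of `nSectors` filled circle
#' sectors (alternating with equally wide blank sectors) whose axial
#' position increases sector by sector in `zStep` steps starting at
#' `zMin`; each emitter's z is its sector step plus Normal(0, `zJitter`)
#' noise. Emitters are distributed uniformly over the filled sectors of
#' an annulus, with per-frame rejection sampling enforcing the minimum
#' pairwise lateral distance. Emitters carry a constant integrated flux:
#' the expected peak equals `peak` counts (above baseline) in focus and
#' decreases as \eqn{1/(\sigma_x(z)\sigma_y(z))} with defocus, which is
#' what makes strongly defocused spokes hard to detect. Frames are
#' rendered with the astigmatic Gaussian PSF and passed through the EMCCD
#' noise chain.
#'
#' @param nEmitters total ground-truth emitters (spread evenly over
#'   frames).
#' @param nFrames number of frames.
#' @param calib an [AstigmaticCalibration-class]; must cover the axial
#'   pattern range.
#' @param noise an [EMCCDNoiseModel-class] (`NULL` renders noiseless
#'   expected-count frames).
#' @param seed integer seed; the movie is bit-for-bit reproducible.
#' @param frameSize frame side, pixels.
#' @param peak expected in-focus peak, counts above baseline.
#' @param minDistance minimum pairwise lateral distance per frame, px.
#' @param nSectors number of filled sectors (40 spokes = 20 filled + 20
#'   blank).
#' @param zMin,zStep axial staircase start and step, nm.
#' @param zJitter per-emitter axial sigma, nm.
#' @param outerRadius,innerRadius annulus radii, px (defaults: 40% of the
#'   frame side, and 12 px to keep the min-distance constraint satisfiable
#'   near the center).
#' @param maxAttempts rejection-sampling cap per emitter.
#' @return a [SyntheticMovie-class]; its ground truth additionally
#'   records the sector's axial step in column `z0`.
#' @export
simulateSiemensStar <- function(nEmitters, nFrames,
                                calib = defaultStarCalibration(),
                                noise = emccdNoiseModel(), seed = 1L,
                                frameSize = 256L, peak = 2000,
                                minDistance = 7.5, nSectors = 20L,
                                zMin = -450, zStep = 45, zJitter = 25,
                                outerRadius = 0.4 * frameSize,
                                innerRadius = 12, maxAttempts = 10000L) {
  stopifnot(nEmitters > 0, nFrames > 0)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  zLevels <- zMin + zStep * (0:(nSectors - 1L))
  if (min(zLevels) - 4 * zJitter < calib@zRange[1L] ||
      max(zLevels) + 4 * zJitter > calib@zRange[2L])
    stop("calibration does not cover the axial pattern range")
  sectorWidth <- 2 * pi / (2 * nSectors)
  cx <- (frameSize - 1) / 2
  perFrame <- rep(nEmitters %/% nFrames, nFrames)
  extra <- nEmitters %% nFrames
  if (extra > 0L) perFrame[seq_len(extra)] <- perFrame[seq_len(extra)] + 1L
  gt <- vector("list", nFrames)
  frames <- vector("list", nFrames)
  for (f in seq_len(nFrames)) {
    n <- perFrame[f]
    xs <- numeric(n); ys <- numeric(n); zs <- numeric(n); z0 <- numeric(n)
    placed <- 0L
    while (placed < n) {
      ok <- FALSE
      for (att in seq_len(maxAttempts)) {
        sec <- sample.int(nSectors, 1L) - 1L
        ang <- (2 * sec) * sectorWidth + stats::runif(1L) * sectorWidth
        rad <- sqrt(stats::runif(1L, innerRadius^2, outerRadius^2))
        x <- cx + rad * cos(ang)
        y <- cx + rad * sin(ang)
        if (placed > 0L &&
            min((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2) <
              minDistance^2) next
        placed <- placed + 1L
        xs[placed] <- x; ys[placed] <- y
        z0[placed] <- zLevels[sec + 1L]
        zs[placed] <- z0[placed] + stats::rnorm(1L, 0, zJitter)
        ok <- TRUE
        break
      }
      if (!ok)
        stop("could not satisfy the minimum-distance constraint; lower the density")
    }
    em <- data.frame(frame = f, x = xs, y = ys, z = zs, z0 = z0,
                     peak = focusPeakScale(calib, zs, peak))
    gt[[f]] <- em
    if (is.null(noise)) {
      frames[[f]] <- renderExpectedFrame(calib, em, frameSize, frameSize)
    } else {
      photons <- renderExpectedFrame(calib, em, frameSize, frameSize,
                                     units = "photons", noise = noise)
      frames[[f]] <- applyEMCCDNoise(photons, noise)
    }
  }
  new("SyntheticMovie", frames = frames, groundTruth = do.call(rbind, gt),
      pixelSize = calib@pixelSize,
      noise = if (is.null(noise))
        emccdNoiseModel(0, 1, 1, 0, 0) else noise,
      seed = as.integer(seed))
}

#' Simulate a bead calibration z-stack
#'
#' One frame per stage z position; each bead is rendered with the widths
#' \eqn{\sigma_x(z)}, \eqn{\sigma_y(z)} of the supplied ground-truth
#' calibration, at constant integrated flux (`peak` counts in focus).
#' Beads are laid out on a grid with spacing at least `2 * window` so
#' their fit neighborhoods stay disjoint.
#'
#' @param calib ground-truth [AstigmaticCalibration-class].
#' @param zPositions stage z values, nm (one frame each).
#' @param nBeads number of beads.
#' @param peak in-focus expected peak, counts above baseline.
#' @param noise `NULL` for noiseless frames, `"poisson"` for plain
#'   Poisson counts, or an [EMCCDNoiseModel-class].
#' @param window bead fit window the spacing is derived from, px.
#' @param seed integer seed.
#' @return list with `stack` (list of frames), `positions` (data.frame
#'   `x`, `y` in 0-based pixels) and `zPositions`.
#' @export
simulateBeadStack <- function(calib, zPositions, nBeads = 4L, peak = 2000,
                              noise = NULL, window = 15L, seed = 1L) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  spacing <- 2L * window
  perSide <- ceiling(sqrt(nBeads))
  frameSize <- as.integer(spacing * (perSide + 1L))
  idx <- 0:(nBeads - 1L)
  pos <- data.frame(x = spacing * (idx %% perSide + 1L),
                    y = spacing * (idx %/% perSide + 1L))
  stack <- lapply(zPositions, function(z) {
    em <- data.frame(frame = 1L, x = pos$x, y = pos$y, z = z,
                     peak = focusPeakScale(calib, z, peak))
    clean <- renderExpectedFrame(calib, em, frameSize, frameSize)
    if (is.null(noise)) {
      clean
    } else if (identical(noise, "poisson")) {
      matrix(stats::rpois(length(clean), clean), frameSize, frameSize)
    } else {
      applyEMCCDNoise(clean / (noise@emGain * noise@quantumEfficiency), noise)
    }
  })
  list(stack = stack, positions = pos, zPositions = zPositions)
}

#' Blinking photophysics model
#'
#' Three-state per-fluorophore Markov chain (dark, on, bleached) advanced
#' once per frame: dark fluorophores activate with probability
#' `1 - exp(-(kOnBase + kOnPerMw * power))`, active ones bleach with
#' probability `1 - exp(-kBleach)` or else switch off with probability
#' `1 - exp(-kOff)`. The activation rate grows with the UV laser power,
#' which is what the feedback controller exploits.
#'
#' @param nFluorophores pool size.
#' @param kOnBase,kOnPerMw activation rate per frame at 0 mW and its
#'   increase per mW.
#' @param kOff,kBleach switching-off and bleaching rates per frame.
#' @return a list of class `blinkingModel`.
#' @export
blinkingModel <- function(nFluorophores = 2000L, kOnBase = 0.02,
                          kOnPerMw = 0.004, kOff = 0.8, kBleach = 0.01) {
  stopifnot(nFluorophores > 0, kOnBase >= 0, kOnPerMw >= 0,
            kOff >= 0, kBleach >= 0)
  structure(list(nFluorophores = as.integer(nFluorophores),
                 kOnBase = kOnBase, kOnPerMw = kOnPerMw,
                 kOff = kOff, kBleach = kBleach),
            class = "blinkingModel")
}

# Advance all fluorophore states by one frame. states: 0 dark, 1 on,
# 2 bleached.
#' @keywords internal
#' @noRd
stepBlinking <- function(states, model, powerMw) {
  pOn <- 1 - exp(-(model$kOnBase + model$kOnPerMw * powerMw))
  pOff <- 1 - exp(-model$kOff)
  pBleach <- 1 - exp(-model$kBleach)
  u <- stats::runif(length(states))
  dark <- states == 0L
  on <- states == 1L
  states[dark & u < pOn] <- 1L
  bleach <- on & u < pBleach
  states[bleach] <- 2L
  states[on & !bleach & u >= pBleach & u < pBleach + (1 - pBleach) * pOff] <- 0L
  states
}

#' Simulate a blinking movie (active-emitter time series)
#'
#' Runs the [blinkingModel()] chain for `nFrames` frames under a fixed or
#' per-frame UV power schedule and reports the per-frame active-emitter
#' count; optionally renders frames (active emitters at fixed random
#' positions, EMCCD noise) so the full detection pipeline can be driven.
#'
#' @param model a [blinkingModel()].
#' @param nFrames frames to simulate.
#' @param uvPower scalar or length-`nFrames` power schedule, mW.
#' @param seed integer seed.
#' @param initialOnFraction fraction of the pool starting in the on
#'   state (default: the no-bleach stationary fraction at the initial
#'   power).
#' @param render also render frames (slower).
#' @param calib,noise,frameSize,peak rendering parameters (used when
#'   `render = TRUE`).
#' @return list with `counts` (integer per frame), `states` (final
#'   states) and `movie` (a [SyntheticMovie-class] or NULL).
#' @export
simulateBlinkingMovie <- function(model, nFrames, uvPower = 0, seed = 1L,
                                  initialOnFraction = NULL, render = FALSE,
                                  calib = defaultStarCalibration(),
                                  noise = emccdNoiseModel(),
                                  frameSize = 64L, peak = 2000) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  power <- rep_len(uvPower, nFrames)
  N <- model$nFluorophores
  if (is.null(initialOnFraction)) {
    pOn <- 1 - exp(-(model$kOnBase + model$kOnPerMw * power[1L]))
    pOff <- 1 - exp(-model$kOff)
    initialOnFraction <- if (pOn + pOff > 0) pOn / (pOn + pOff) else 0
  }
  states <- integer(N)
  nOn0 <- round(initialOnFraction * N)
  if (nOn0 > 0) states[sample.int(N, nOn0)] <- 1L
  posX <- stats::runif(N, 4, frameSize - 5)
  posY <- stats::runif(N, 4, frameSize - 5)
  counts <- integer(nFrames)
  frames <- if (render) vector("list", nFrames) else list()
  gt <- if (render) vector("list", nFrames) else list()
  for (f in seq_len(nFrames)) {
    states <- stepBlinking(states, model, power[f])
    on <- states == 1L
    counts[f] <- sum(on)
    if (render) {
      em <- data.frame(frame = f, x = posX[on], y = posY[on],
                       z = 0, peak = peak)
      gt[[f]] <- em
      photons <- renderExpectedFrame(calib, em, frameSize, frameSize,
                                     units = "photons", noise = noise)
      frames[[f]] <- applyEMCCDNoise(photons, noise)
    }
  }
  movie <- NULL
  if (render)
    movie <- new("SyntheticMovie", frames = frames,
                 groundTruth = do.call(rbind, gt), pixelSize = calib@pixelSize,
                 noise = noise, seed = as.integer(seed))
  list(counts = counts, states = states, movie = movie)
}

#' Accessors for synthetic movies
#'
#' @param x a [SyntheticMovie-class].
#' @return `frames()`: the list of count matrices; `groundTruth()`: the
#'   per-emitter truth table.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname frames
#' @export
setMethod("frames", "SyntheticMovie", function(x) x@frames)

#' @rdname frames
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname frames
#' @export
setMethod("groundTruth", "SyntheticMovie", function(x) x@groundTruth)

setMethod("show", "SyntheticMovie", function(object) {
  cat(sprintf(
    "SyntheticMovie: %d frames (%s px), %d ground-truth emitters, pixel %g nm, seed %d\n",
    length(object@frames),
    if (length(object@frames))
      paste(dim(object@frames[[1L]]), collapse = " x ") else "-",
    nrow(object@groundTruth), object@pixelSize, object@seed))
})
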