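#' @import methods
NULL

#' Astigmatic calibration: the z -> PSF-shape map
#'
#' Holds the cubic B-spline curves \eqn{\sigma_x(z)} and \eqn{\sigma_y(z)}
#' (in pixels, over z in nm), the in-plane rotation \eqn{\varphi} of the
#' elliptical Gaussian, the calibrated axial range, the focal plane (the z
#' of best overall focus, used to initialize the axial fit parameter) and
#' the camera pixel size.
#'
#' Evaluating the curves outside `zRange` is an error, never a silent
#' extrapolation.
#'
#' @slot sxSpline,sySpline lists with elements `knots`, `coefs`, `ord`
#'   describing clamped cubic B-splines mapping z (nm) to sigma (pixels).
#' @slot phi clockwise rotation of the elliptical Gaussian, radians.
#' @slot zRange numeric(2), calibrated z interval in nm.
#' @slot zFocus nm; plane of maximum focus (argmin of
#'   \eqn{\sigma_x(z)\sigma_y(z)}).
#' @slot pixelSize nm per camera pixel.
#' @export
setClass("AstigmaticCalibration",
  representation(
    sxSpline = "list",
    sySpline = "list",
    phi = "numeric",
    zRange = "numeric",
    zFocus = "numeric",
    pixelSize = "numeric"
  )
)

setValidity("AstigmaticCalibration", function(object) {
  msg <- character()
  if (length(object@zRange) != 2L || diff(object@zRange) <= 0)
    msg <- c(msg, "zRange must be an increasing interval")
  if (length(object@zFocus) != 1L ||
      object@zFocus < object@zRange[1L] || object@zFocus > object@zRange[2L])
    msg <- c(msg, "zFocus must lie within zRange")
  if (length(object@phi) != 1L || !is.finite(object@phi))
    msg <- c(msg, "phi must be a finite scalar")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be positive")
  if (length(msg) == 0L) {
    zz <- seq(object@zRange[1L], object@zRange[2L], length.out = 201L)
    sx <- evalBSpline(object@sxSpline, zz)
    sy <- evalBSpline(object@sySpline, zz)
    if (any(sx <= 0) || any(sy <= 0))
      msg <- c(msg, "sigma_x(z) and sigma_y(z) must be strictly positive over zRange")
  }
  if (length(msg)) msg else TRUE
})

#' Lookup-table discretization parameters
#'
#' @slot window odd template side length in pixels.
#' @slot dxy lateral grid step in pixels.
#' @slot rxy total lateral span in pixels; offsets cover
#'   \code{[-rxy/2, +rxy/2]} inclusive.
#' @slot dz axial step in nm.
#' @slot rz total axial span in nm; the grid covers
#'   \code{[zFocus - rz/2, zFocus + rz/2]}.
#' @slot precision `"double"` or `"single"` (storage intent; R arrays are
#'   double either way, the slot drives the reported memory footprint).
#' @export
setClass("LookupTableSpec",
  representation(
    window = "integer",
    dxy = "numeric",
    rxy = "numeric",
    dz = "numeric",
    rz = "numeric",
    precision = "character"
  )
)

setValidity("LookupTableSpec", function(object) {
  msg <- character()
  if (length(object@window) != 1L || object@window < 5L || !isOdd(object@window))
    msg <- c(msg, "window must be odd and >= 5")
  for (nm in c("dxy", "rxy", "dz", "rz")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be a positive scalar", nm))
  }
  if (length(msg) == 0L) {
    hx <- object@rxy / object@dxy / 2
    hz <- object@rz / object@dz / 2
    if (abs(hx - round(hx)) > 1e-9)
      msg <- c(msg, "rxy/2 must be an integer multiple of dxy")
    if (abs(hz - round(hz)) > 1e-9)
      msg <- c(msg, "rz/2 must be an integer multiple of dz")
  }
  if (!object@precision %in% c("double", "single"))
    msg <- c(msg, "precision must be 'double' or 'single'")
  if (length(msg)) msg else TRUE
})

#' Lookup table of PSF templates and derivatives
#'
#' A 4-channel stack of template images: channel 1 is the PSF, channels
#' 2-4 its partial derivatives with respect to the emitter x (pixels),
#' y (pixels) and z (nm) position, pre-computed at every discrete grid
#' point so that fitting needs only O(1) index arithmetic.
#'
#' Template layout: 0-based index \code{k = ((ix * nxy) + iy) * nz + iz}
#' (z fastest), exposed 1-based in R. `xOffsets`/`yOffsets` are offsets in
#' pixels from the window center; `zValues` are absolute z in nm.
#'
#' @slot spec a [LookupTableSpec-class].
#' @slot calib the [AstigmaticCalibration-class] the table was built from.
#' @slot templates numeric array `(window, window, 4, nTemplates)`.
#' @slot xOffsets,yOffsets,zValues grid axis vectors.
#' @slot model `"sampled"` (point-sampled Gaussian) or `"integrated"`
#'   (pixel-integrated Gaussian).
#' @export
setClass("LookupTable",
  representation(
    spec = "LookupTableSpec",
    calib = "AstigmaticCalibration",
    templates = "array",
    xOffsets = "numeric",
    yOffsets = "numeric",
    zValues = "numeric",
    model = "character"
  )
)

setValidity("LookupTable", function(object) {
  d <- dim(object@templates)
  n <- length(object@xOffsets) * length(object@yOffsets) * length(object@zValues)
  if (length(d) != 4L || d[3L] != 4L)
    return("templates must be a (window, window, 4, n) array")
  if (d[4L] != n)
    return("template count must equal nxy^2 * nz")
  TRUE
})

#' EMCCD camera noise model
#'
#' Parameters of the electron-multiplying CCD counting chain: expected
#' photons are converted to photoelectrons (quantum efficiency), joined by
#' clock-induced spurious charge, amplified by the stochastic EM register
#' (Gamma-distributed with mean `emGain`, excess-noise factor 2), read out
#' with Gaussian noise and offset by the camera baseline.
#'
#' @slot baseline camera offset, counts.
#' @slot emGain electron-multiplying gain (counts per photoelectron).
#' @slot quantumEfficiency photoelectrons per photon, in `[0, 1]`.
#' @slot readoutNoise rms readout noise, counts.
#' @slot spuriousCharge clock-induced charge, events/pixel/frame.
#' @export
setClass("EMCCDNoiseModel",
  representation(
    baseline = "numeric",
    emGain = "numeric",
    quantumEfficiency = "numeric",
    readoutNoise = "numeric",
    spuriousCharge = "numeric"
  )
)

setValidity("EMCCDNoiseModel", function(object) {
  vals <- c(object@baseline, object@emGain, object@quantumEfficiency,
            object@readoutNoise, object@spuriousCharge)
  if (any(!is.finite(vals)) || any(vals < 0))
    return("all noise parameters must be finite and non-negative")
  if (object@quantumEfficiency > 1)
    return("quantumEfficiency must be <= 1")
  TRUE
})

#' Synthetic SMLM movie with ground truth
#'
#' @slot frames list of 2D count matrices.
#' @slot groundTruth data.frame with columns `frame`, `x`, `y` (pixels,
#'   0-based), `z` (nm), `peak` (expected peak counts above baseline).
#' @slot pixelSize nm per pixel.
#' @slot noise the [EMCCDNoiseModel-class] applied (or NULL-model with
#'   zero noise for noiseless renders).
#' @slot seed integer seed the movie is bit-for-bit reproducible from.
#' @export
setClass("SyntheticMovie",
  representation(
    frames = "list",
    groundTruth = "data.frame",
    pixelSize = "numeric",
    noise = "EMCCDNoiseModel",
    seed = "integer"
  )
)

setValidity("SyntheticMovie", function(object) {
  need <- c("frame", "x", "y", "z", "peak")
  if (!all(need %in% names(object@groundTruth)))
    return(sprintf("groundTruth must have columns %s",
                   paste(need, collapse = ", ")))
  if (length(object@frames) &&
      any(object@groundTruth$frame > length(object@frames)))
    return("groundTruth refers to frames beyond the movie length")
  TRUE
})

#' UV-activation feedback controller state
#'
#' State machine that watches the per-frame localization count and drives
#' the activation laser: when the count stays strictly below
#' `countThreshold` for `streakLength` consecutive frames, the first
#' trigger turns the laser on and every later trigger raises the power by
#' `powerStep` (clamped at `powerMax`). The streak re-arms after every
#' trigger and resets whenever a frame reaches the threshold.
#'
#' @slot laserOn logical.
#' @slot powerMw current laser power, mW.
#' @slot streak number of consecutive below-threshold frames seen.
#' @slot countThreshold localizations/frame.
#' @slot streakLength frames.
#' @slot powerStep,powerMax mW.
#' @export
setClass("ControllerState",
  representation(
    laserOn = "logical",
    powerMw = "numeric",
    streak = "integer",
    countThreshold = "numeric",
    streakLength = "integer",
    powerStep = "numeric",
    powerMax = "numeric"
  )
)

setValidity("ControllerState", function(object) {
  if (object@powerMw < 0) return("powerMw must be >= 0")
  if (object@streak < 0) return("streak must be >= 0")
  if (object@streakLength < 1L) return("streakLength must be >= 1")
  if (object@powerStep <= 0) return("powerStep must be > 0")
  if (object@powerMax < object@powerStep) return("powerMax must be >= powerStep")
  TRUE
})

#' Result of matching localizations against ground truth
#'
#' @slot pairs two-column integer matrix of (ground-truth row, fit row)
#'   indices for the matched pairs.
#' @slot nTP,nFP,nFN true positive / false positive / false negative counts.
#' @slot lateralErrors,axialErrors per-pair errors in nm (lateral is the 2D
#'   Euclidean distance).
#' @export
setClass("MatchResult",
  representation(
    pairs = "matrix",
    nTP = "integer",
    nFP = "integer",
    nFN = "integer",
    lateralErrors = "numeric",
    axialErrors = "numeric"
  )
)

setValidity("MatchResult", function(object) {
  if (object@nTP != nrow(object@pairs))
    return("nTP must equal the number of matched pairs")
  if (length(object@lateralErrors) != object@nTP ||
      length(object@axialErrors) != object@nTP)
    return("one error per matched pair required")
  if (object@nTP > 0 &&
      (anyDuplicated(object@pairs[, 1L]) || anyDuplicated(object@pairs[, 2L])))
    return("pairing must be one-to-one")
  TRUE
})
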