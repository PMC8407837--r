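# UV-activation feedback: keep the per-frame emitter count constant by
# driving the activation laser from the live localization counts.

#' Create a feedback controller
#'
#' Defaults follow the published operating point: trigger when fewer
#' than 25 localizations are seen for 5 consecutive frames, raise the
#' power in 5 mW steps. "Below" is strict (a frame with exactly
#' `countThreshold` localizations resets the streak). The laser is
#' turned on at one `powerStep` on the first trigger; every later
#' trigger adds a step, clamped at `powerMax`.
#'
#' @param countThreshold localizations/frame.
#' @param streakLength consecutive below-threshold frames required.
#' @param powerStep mW per trigger.
#' @param powerMax safety clamp, mW.
#' @return a [ControllerState-class].
#' @export
controllerState <- function(countThreshold = 25, streakLength = 5L,
                            powerStep = 5, powerMax = 50) {
  new("ControllerState", laserOn = FALSE, powerMw = 0, streak = 0L,
      countThreshold = countThreshold, streakLength = as.integer(streakLength),
      powerStep = powerStep, powerMax = powerMax)
}

setMethod("show", "ControllerState", function(object) {
  cat(sprintf(
    "ControllerState: laser %s at %g mW, streak %d/%d (threshold %g, step %g mW, max %g mW)\n",
    if (object@laserOn) "on" else "off", object@powerMw, object@streak,
    object@streakLength, object@countThreshold, object@powerStep,
    object@powerMax))
})

#' Advance the controller by one frame
#'
#' The streak of below-threshold frames increments when
#' `frameCount < countThreshold` and resets to zero otherwise. When the
#' streak reaches `streakLength` a command fires and the streak re-arms:
#' `"laser_on"` on the first trigger of the run, `"power_up"` afterwards.
#' Power never decreases.
#'
#' @param state a [ControllerState-class].
#' @param frameCount localizations in the newly analyzed frame.
#' @return list with `state` (updated) and `command` (`"none"`,
#'   `"laser_on"` or `"power_up"`).
#' @export
controllerUpdate <- function(state, frameCount) {
  stopifnot(frameCount >= 0)
  command <- "none"
  if (frameCount < state@countThreshold) {
    state@streak <- state@streak + 1L
    if (state@streak >= state@streakLength) {
      if (!state@laserOn) {
        state@laserOn <- TRUE
        state@powerMw <- min(state@powerStep, state@powerMax)
        command <- "laser_on"
      } else {
        state@powerMw <- min(state@powerMw + state@powerStep, state@powerMax)
        command <- "power_up"
      }
      state@streak <- 0L
    }
  } else {
    state@streak <- 0L
  }
  list(state = state, command = command)
}

#' Run the closed activation loop against the blinking simulator
#'
#' Couples a [blinkingModel()] to the controller: each frame the chain is
#' advanced at the current laser power, the frame's emitter count is
#' measured (by default the true active count; optionally a user
#' `analyzer` function receives a rendered frame and returns a count) and
#' fed to [controllerUpdate()], whose power commands take effect from the
#' next frame on.
#'
#' @param model a [blinkingModel()].
#' @param controller a [ControllerState-class] (or NULL to run open-loop
#'   at 0 mW).
#' @param nFrames frames to run.
#' @param seed integer seed for the photophysics.
#' @param initialOnFraction see [simulateBlinkingMovie()].
#' @param analyzer optional `function(frame) -> count`; when supplied,
#'   frames are rendered and analyzed instead of using the true count.
#' @param calib,noise,frameSize,peak rendering parameters for `analyzer`.
#' @return data.frame with one row per frame: `frame`, `count`,
#'   `power_mw` (power during the frame), `command`.
#' @export
runClosedLoop <- function(model, controller, nFrames, seed = 1L,
                          initialOnFraction = NULL, analyzer = NULL,
                          calib = defaultStarCalibration(),
                          noise = emccdNoiseModel(), frameSize = 64L,
                          peak = 2000) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  N <- model$nFluorophores
  if (is.null(initialOnFraction)) {
    pOn <- 1 - exp(-model$kOnBase)
    pOff <- 1 - exp(-model$kOff)
    initialOnFraction <- if (pOn + pOff > 0) pOn / (pOn + pOff) else 0
  }
  states <- integer(N)
  nOn0 <- round(initialOnFraction * N)
  if (nOn0 > 0) states[sample.int(N, nOn0)] <- 1L
  posX <- stats::runif(N, 4, frameSize - 5)
  posY <- stats::runif(N, 4, frameSize - 5)
  power <- 0
  out <- data.frame(frame = seq_len(nFrames), count = NA_integer_,
                    power_mw = NA_real_, command = "none",
                    stringsAsFactors = FALSE)
  for (f in seq_len(nFrames)) {
    states <- stepBlinking(states, model, power)
    on <- states == 1L
    count <- if (is.null(analyzer)) {
      sum(on)
    } else {
      em <- data.frame(frame = f, x = posX[on], y = posY[on], z = 0,
                       peak = peak)
      photons <- renderExpectedFrame(calib, em, frameSize, frameSize,
                                     units = "photons", noise = noise)
      analyzer(applyEMCCDNoise(photons, noise))
    }
    out$count[f] <- count
    out$power_mw[f] <- power
    if (!is.null(controller)) {
      upd <- controllerUpdate(controller, count)
      controller <- upd$state
      out$command[f] <- upd$command
      power <- controller@powerMw
    }
  }
  out
}
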