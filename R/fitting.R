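# Grid-constrained Gauss-Newton least-squares fitting against lookup-table
# templates, per-fit Cramer-Rao lower bounds, and the continuous
# elliptical-Gaussian reference fitter.
#
# The parameter vector is theta = (bg, p, x, y, z): mean background and
# peak intensity in counts (unconstrained), lateral offsets from the
# window center in pixels and the axial position in nm (constrained to
# lookup-table grid points after every iteration).

TERMINATIONS <- c("converged", "max_iterations", "left_lateral_range",
                  "left_axial_range", "degenerate")

#' @keywords internal
#' @noRd
snapToGrid <- function(spec, x, y, z, zFocus) {
  c(x = roundHalfAway(x / spec@dxy) * spec@dxy,
    y = roundHalfAway(y / spec@dxy) * spec@dxy,
    z = zFocus + roundHalfAway((z - zFocus) / spec@dz) * spec@dz)
}

#' One Gauss-Newton iteration against the lookup table
#'
#' Builds the per-pixel Jacobian `(1, T, p dT/dx, p dT/dy, p dT/dz)` from
#' the template at the current (on-grid) position, forms the residual
#' `r = I - (bg + p T)`, solves the symmetric 5x5 normal equations
#' `(J'J) delta = J'r`, and returns the updated parameters with the
#' positional components rounded back onto the grid.
#'
#' @param window `window x window` count matrix (rows y, columns x).
#' @param table a [LookupTable-class].
#' @param theta named numeric `c(bg, p, x, y, z)` with the positional
#'   part on a grid point.
#' @return list with elements `theta` (updated, positions re-gridded),
#'   `residualNorm` (Euclidean norm of the entry residual) and `singular`
#'   (TRUE when the normal matrix is not numerically positive definite;
#'   treated as the "degenerate" termination by [fitEmitter()]).
#' @export
gaussNewtonStep <- function(window, table, theta) {
  spec <- table@spec
  if (!identical(dim(window), c(spec@window, spec@window)))
    stop("window must match the lookup-table template size")
  k <- indexOf(table, theta[["x"]], theta[["y"]], theta[["z"]])
  if (is.na(k)) stop("theta is outside the lookup-table grid")
  tm <- table@templates[, , , k]
  n <- spec@window^2
  Tv <- tm[seq_len(n)]
  J <- cbind(1, Tv, theta[["p"]] * tm[n + seq_len(n)],
             theta[["p"]] * tm[2L * n + seq_len(n)],
             theta[["p"]] * tm[3L * n + seq_len(n)])
  r <- as.numeric(window) - (theta[["bg"]] + theta[["p"]] * Tv)
  A <- crossprod(J)
  b <- crossprod(J, r)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) < sqrt(.Machine$double.eps) * max(diag(ch))))
    return(list(theta = theta, residualNorm = sqrt(sum(r^2)), singular = TRUE))
  delta <- backsolve(ch, forwardsolve(t(ch), b))
  new <- theta + as.numeric(delta)
  pos <- snapToGrid(spec, new[["x"]], new[["y"]], new[["z"]], table@calib@zFocus)
  new[c("x", "y", "z")] <- pos
  list(theta = new, residualNorm = sqrt(sum(r^2)), singular = FALSE)
}

#' Fit one candidate window against the lookup table
#'
#' Iterates [gaussNewtonStep()] from the standard initialization (lateral
#' position at the window center, z at the calibration's focal plane, bg
#' and peak from the candidate search) until one of the four termination
#' rules fires: convergence (the rounded position is unchanged and the
#' relative background/peak updates fall below `tol`), the iteration
#' budget is exhausted, or the position leaves the lateral or axial grid
#' range. A numerically singular normal matrix terminates the fit as
#' "degenerate".
#'
#' @param window `window x window` count matrix.
#' @param table a [LookupTable-class].
#' @param candidate list or one-row data.frame with `peak` and `bg`.
#' @param maxIterations iteration budget; the discretized model is
#'   designed to settle within about five iterations.
#' @param tol relative convergence tolerance on bg and p.
#' @param noise optional [EMCCDNoiseModel-class] for the CRLB variance
#'   model (default: pure Poisson in expected counts).
#' @param computeCrlb attach per-parameter CRLBs to converged fits.
#' @return list with `params` (named `c(bg, p, x, y, z)`; x/y are pixel
#'   offsets from the window center, z is nm), `nIterations`,
#'   `termination` (`"converged"`, `"max_iterations"`,
#'   `"left_lateral_range"`, `"left_axial_range"` or `"degenerate"`),
#'   `residualNorm`
#'   and `crlb` (named vector, or NULL).
#' @export
fitEmitter <- function(window, table, candidate, maxIterations = 5L,
                       tol = 1e-3, noise = NULL, computeCrlb = TRUE) {
  spec <- table@spec
  zF <- table@calib@zFocus
  theta <- c(bg = as.numeric(candidate$bg),
             p = max(as.numeric(candidate$peak) - as.numeric(candidate$bg),
                     .Machine$double.eps),
             x = 0, y = 0, z = zF)
  termination <- "max_iterations"
  resNorm <- NA_real_
  iter <- 0L
  kPrev <- indexOf(table, 0, 0, zF)
  while (iter < maxIterations) {
    iter <- iter + 1L
    st <- gaussNewtonStep(window, table, theta)
    resNorm <- st$residualNorm
    if (st$singular) {
      termination <- "degenerate"
      break
    }
    parts <- indexParts(spec, st$theta[["x"]], st$theta[["y"]],
                        st$theta[["z"]], zF)
    if (parts$oobLateral) {
      theta <- st$theta
      termination <- "left_lateral_range"
      break
    }
    if (parts$oobAxial) {
      theta <- st$theta
      termination <- "left_axial_range"
      break
    }
    converged <- parts$k == kPrev &&
      abs(st$theta[["bg"]] - theta[["bg"]]) <= tol * max(abs(theta[["bg"]]), 1) &&
      abs(st$theta[["p"]] - theta[["p"]]) <= tol * max(abs(theta[["p"]]), 1)
    theta <- st$theta
    kPrev <- parts$k
    if (converged) {
      termination <- "converged"
      break
    }
  }
  cr <- NULL
  if (computeCrlb && termination %in% c("converged", "max_iterations"))
    cr <- crlb(table, theta, noise = noise)
  list(params = theta, nIterations = iter, termination = termination,
       residualNorm = resNorm, crlb = cr)
}

#' Cramer-Rao lower bounds for a lookup-table fit
#'
#' Inverts the 5x5 Fisher information of the template model
#' `mu = bg + p T(x, y, z)` under per-pixel noise. The default noise
#' model is Poisson in the expected counts (`var = mu`); supplying an
#' [EMCCDNoiseModel-class] switches to the Gaussian-approximation EMCCD
#' variance `var = 2 gain (mu - baseline) + readout^2`, which carries the
#' electron-multiplying excess-noise factor of 2.
#'
#' @param table a [LookupTable-class].
#' @param theta named `c(bg, p, x, y, z)` on a grid point.
#' @param noise NULL (Poisson) or an [EMCCDNoiseModel-class].
#' @return named numeric `c(bg, p, x, y, z)` of lower-bound standard
#'   deviations (bg, p counts; x, y pixels; z nm). When the information
#'   matrix is not invertible all entries are `NA` and the attribute
#'   `undefined` is set.
#' @export
crlb <- function(table, theta, noise = NULL) {
  k <- indexOf(table, theta[["x"]], theta[["y"]], theta[["z"]])
  if (is.na(k)) stop("theta is outside the lookup-table grid")
  tm <- table@templates[, , , k]
  n <- table@spec@window^2
  Tv <- tm[seq_len(n)]
  D <- cbind(1, Tv, theta[["p"]] * tm[n + seq_len(n)],
             theta[["p"]] * tm[2L * n + seq_len(n)],
             theta[["p"]] * tm[3L * n + seq_len(n)])
  mu <- theta[["bg"]] + theta[["p"]] * Tv
  v <- if (is.null(noise)) {
    pmax(mu, .Machine$double.eps)
  } else {
    pmax(2 * noise@emGain * pmax(mu - noise@baseline, 0) +
           noise@readoutNoise^2, .Machine$double.eps)
  }
  info <- crossprod(D, D / v)
  C <- tryCatch(solve(info), error = function(e) NULL)
  out <- rep(NA_real_, 5L)
  names(out) <- c("bg", "p", "x", "y", "z")
  if (is.null(C)) {
    attr(out, "undefined") <- TRUE
    return(out)
  }
  out[] <- sqrt(pmax(diag(C), 0))
  out
}

#' @keywords internal
#' @noRd
extractWindow <- function(frame, px, py, w) {
  half <- w %/% 2L
  frame[(py - half):(py + half) + 1L, (px - half):(px + half) + 1L]
}

#' Detect and fit all emitters in one frame
#'
#' Runs [findCandidates()] and fits every candidate with [fitEmitter()].
#' With the default `accept = "in_range"` rule a fit is accepted when the
#' iteration stayed inside the grid with positive peak intensity --
#' exhausting the (deliberately small) iteration budget still yields the
#' best discrete fit, which is how the method is meant to operate;
#' `accept = "converged"` additionally demands the convergence test
#' fired. Rejected fits are tallied in the `diagnostics` attribute
#' (`nCandidates`, `nAccepted`, and a termination table of the
#' rejections). Detection and fitting are fully deterministic.
#'
#' @param frame 2D count matrix.
#' @param table a [LookupTable-class].
#' @param threshold detection threshold, counts above local background.
#' @param suppressionRadius,bgWindow see [findCandidates()]; the
#'   suppression radius defaults to the fit window size.
#' @param maxIterations,tol,noise see [fitEmitter()].
#' @param frameIndex frame number recorded in the output.
#' @param computeCrlb attach CRLBs (modest extra cost per fit).
#' @return data.frame, one row per accepted fit: `frame`, `x_px`, `y_px`
#'   (absolute pixel coordinates), `x_nm`, `y_nm`, `z_nm`, `intensity`,
#'   `background`, `crlb_x`, `crlb_y`, `crlb_z` (nm), `iterations`,
#'   `termination`.
#' @export
fitFrame <- function(frame, table, threshold, suppressionRadius = NULL,
                     bgWindow = 11L, maxIterations = 5L, tol = 1e-3,
                     noise = NULL, frameIndex = 1L, computeCrlb = TRUE,
                     accept = c("in_range", "converged")) {
  accept <- match.arg(accept)
  spec <- table@spec
  if (is.null(suppressionRadius)) suppressionRadius <- spec@window %/% 2L
  cand <- findCandidates(frame, threshold, suppressionRadius, bgWindow,
                         fitWindow = spec@window, frameIndex = frameIndex)
  zF <- table@calib@zFocus
  px <- table@calib@pixelSize
  halfLat <- spec@rxy / 2
  halfAx <- spec@rz / 2
  rows <- vector("list", nrow(cand))
  reject <- character(0)
  for (ci in seq_len(nrow(cand))) {
    win <- extractWindow(frame, cand$px[ci], cand$py[ci], spec@window)
    # theta_p is initialized from the NMS suppression score (the 3x3
    # mean): a single raw pixel is far too noisy at high EM gain.
    fit <- fitEmitter(win, table, list(peak = cand$score[ci], bg = cand$bg[ci]),
                      maxIterations, tol, noise, computeCrlb)
    th <- fit$params
    okTerm <- if (accept == "in_range")
      fit$termination %in% c("converged", "max_iterations")
    else fit$termination == "converged"
    ok <- okTerm && th[["p"]] > 0 &&
      abs(th[["x"]]) < halfLat && abs(th[["y"]]) < halfLat &&
      abs(th[["z"]] - zF) < halfAx
    if (!ok) {
      reject <- c(reject, if (okTerm) "filtered" else fit$termination)
      next
    }
    cr <- if (is.null(fit$crlb))
      c(bg = NA_real_, p = NA_real_, x = NA_real_, y = NA_real_,
        z = NA_real_) else fit$crlb
    rows[[ci]] <- data.frame(
      frame = frameIndex,
      x_px = cand$px[ci] + th[["x"]],
      y_px = cand$py[ci] + th[["y"]],
      x_nm = (cand$px[ci] + th[["x"]]) * px,
      y_nm = (cand$py[ci] + th[["y"]]) * px,
      z_nm = th[["z"]],
      intensity = th[["p"]],
      background = th[["bg"]],
      crlb_x = cr[["x"]] * px,
      crlb_y = cr[["y"]] * px,
      crlb_z = cr[["z"]],
      iterations = fit$nIterations,
      termination = fit$termination)
  }
  out <- do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                          list(emptyLocalizations())))
  attr(out, "diagnostics") <- list(
    nCandidates = nrow(cand),
    nAccepted = nrow(out),
    rejected = table(factor(reject,
                            levels = c(TERMINATIONS[-1L], "filtered"))))
  out
}

#' @keywords internal
#' @noRd
emptyLocalizations <- function() {
  data.frame(frame = integer(0), x_px = numeric(0), y_px = numeric(0),
             x_nm = numeric(0), y_nm = numeric(0), z_nm = numeric(0),
             intensity = numeric(0), background = numeric(0),
             crlb_x = numeric(0), crlb_y = numeric(0), crlb_z = numeric(0),
             iterations = integer(0), termination = character(0))
}

#' Fit a whole stack of frames
#'
#' Applies [fitFrame()] to every frame and concatenates the accepted
#' localizations; per-frame diagnostics are summed into the
#' `diagnostics` attribute.
#'
#' @param frames list of 2D count matrices (e.g. `frames(movie)` or
#'   [readStack()] output).
#' @inheritParams fitFrame
#' @param progress print a note every `progress` frames (0 = silent).
#' @return data.frame as in [fitFrame()].
#' @export
fitStack <- function(frames, table, threshold, suppressionRadius = NULL,
                     bgWindow = 11L, maxIterations = 5L, tol = 1e-3,
                     noise = NULL, computeCrlb = TRUE, progress = 0L,
                     accept = c("in_range", "converged")) {
  accept <- match.arg(accept)
  res <- vector("list", length(frames))
  nCand <- 0L
  rej <- NULL
  for (f in seq_along(frames)) {
    r <- fitFrame(frames[[f]], table, threshold, suppressionRadius, bgWindow,
                  maxIterations, tol, noise, frameIndex = f, computeCrlb,
                  accept = accept)
    d <- attr(r, "diagnostics")
    nCand <- nCand + d$nCandidates
    rej <- if (is.null(rej)) d$rejected else rej + d$rejected
    res[[f]] <- r
    if (progress > 0L && f %% progress == 0L)
      message(sprintf("frame %d/%d: %d localizations so far",
                      f, length(frames), sum(vapply(res, nrow, integer(1)),
                                             na.rm = TRUE)))
  }
  out <- do.call(rbind, res)
  attr(out, "diagnostics") <- list(nCandidates = nCand,
                                   nAccepted = nrow(out), rejected = rej)
  out
}

#' Continuous elliptical-Gaussian reference fitter
#'
#' Unconstrained (off-grid) least-squares fit of `(bg, p, x, y, z)` with
#' the same calibrated astigmatic PSF, via Levenberg-Marquardt with the
#' analytic Jacobian. This is the reference against which the discrete
#' lookup-table fitter is compared: positions are continuous, z is bounded
#' only by `zBounds`.
#'
#' @param window `window x window` count matrix.
#' @param calib an [AstigmaticCalibration-class].
#' @param candidate list with `peak` and `bg` initial estimates.
#' @param zBounds numeric(2), allowed z interval in nm (defaults to the
#'   calibrated range).
#' @param zInit starting z, nm (defaults to the focal plane).
#' @param maxIterations Levenberg-Marquardt iteration cap.
#' @return list with `params` (named `c(bg, p, x, y, z)`; x/y are pixel
#'   offsets from the window center), `converged` (logical) and
#'   `nIterations`.
#' @export
fitEmitterContinuous <- function(window, calib, candidate,
                                 zBounds = calib@zRange, zInit = calib@zFocus,
                                 maxIterations = 50L) {
  w <- nrow(window)
  ctr <- (w - 1) / 2
  ij <- expand.grid(j = 0:(w - 1), i = 0:(w - 1))
  obs <- as.numeric(window)
  start <- c(bg = as.numeric(candidate$bg),
             p = max(as.numeric(candidate$peak) - as.numeric(candidate$bg), 1e-6),
             x = ctr, y = ctr, z = zInit)
  fn <- function(th) {
    obs - (th[1L] + th[2L] *
             psfValue(calib, th[3L], th[4L], th[5L], ij$i, ij$j))
  }
  jac <- function(th) {
    v <- psfValue(calib, th[3L], th[4L], th[5L], ij$i, ij$j)
    g <- psfGradient(calib, th[3L], th[4L], th[5L], ij$i, ij$j)
    -cbind(1, v, th[2L] * g$dx, th[2L] * g$dy, th[2L] * g$dz)
  }
  res <- try(minpack.lm::nls.lm(
    par = start, fn = fn, jac = jac,
    lower = c(-Inf, 0, 0, 0, zBounds[1L]),
    upper = c(Inf, Inf, w - 1, w - 1, zBounds[2L]),
    control = minpack.lm::nls.lm.control(maxiter = maxIterations)),
    silent = TRUE)
  if (inherits(res, "try-error"))
    return(list(params = start, converged = FALSE, nIterations = 0L))
  th <- res$par
  th[["x"]] <- th[["x"]] - ctr
  th[["y"]] <- th[["y"]] - ctr
  list(params = th, converged = res$info %in% 1:3, nIterations = res$niter)
}

#' Detect and continuously fit all emitters in one frame
#'
#' The continuous counterpart of [fitFrame()]: identical candidate
#' detection, but each window is fit with [fitEmitterContinuous()]. A fit
#' is accepted when the optimizer converged with positive peak and a
#' position strictly inside the same lateral/axial acceptance region the
#' discrete fitter uses, so acceptance fractions are directly comparable.
#'
#' @inheritParams fitFrame
#' @param calib an [AstigmaticCalibration-class].
#' @param window fit window side, pixels.
#' @param rxy,rz lateral/axial acceptance spans matching the discrete
#'   grid (pixels / nm).
#' @return data.frame with the same columns as [fitFrame()] (CRLB columns
#'   are `NA`).
#' @export
fitFrameContinuous <- function(frame, calib, threshold, window = 9L,
                               rxy = 4, rz = 1000, suppressionRadius = NULL,
                               bgWindow = 11L, frameIndex = 1L) {
  if (is.null(suppressionRadius)) suppressionRadius <- window %/% 2L
  cand <- findCandidates(frame, threshold, suppressionRadius, bgWindow,
                         fitWindow = window, frameIndex = frameIndex)
  zF <- calib@zFocus
  pxs <- calib@pixelSize
  zB <- c(max(calib@zRange[1L], zF - rz / 2), min(calib@zRange[2L], zF + rz / 2))
  rows <- vector("list", nrow(cand))
  for (ci in seq_len(nrow(cand))) {
    win <- extractWindow(frame, cand$px[ci], cand$py[ci], window)
    fit <- fitEmitterContinuous(win, calib,
                                list(peak = cand$score[ci], bg = cand$bg[ci]),
                                zBounds = zB)
    th <- fit$params
    ok <- fit$converged && th[["p"]] > 0 &&
      abs(th[["x"]]) < rxy / 2 && abs(th[["y"]]) < rxy / 2 &&
      th[["z"]] > zB[1L] && th[["z"]] < zB[2L]
    if (!ok) next
    rows[[ci]] <- data.frame(
      frame = frameIndex,
      x_px = cand$px[ci] + th[["x"]],
      y_px = cand$py[ci] + th[["y"]],
      x_nm = (cand$px[ci] + th[["x"]]) * pxs,
      y_nm = (cand$py[ci] + th[["y"]]) * pxs,
      z_nm = th[["z"]],
      intensity = th[["p"]],
      background = th[["bg"]],
      crlb_x = NA_real_, crlb_y = NA_real_, crlb_z = NA_real_,
      iterations = fit$nIterations,
      termination = "converged")
  }
  out <- do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                          list(emptyLocalizations())))
  attr(out, "diagnostics") <- list(nCandidates = nrow(cand),
                                   nAccepted = nrow(out))
  out
}

#' @rdname fitFrameContinuous
#' @param frames list of frames.
#' @export
fitStackContinuous <- function(frames, calib, threshold, window = 9L,
                               rxy = 4, rz = 1000, suppressionRadius = NULL,
                               bgWindow = 11L) {
  res <- vector("list", length(frames))
  nCand <- 0L
  for (f in seq_along(frames)) {
    r <- fitFrameContinuous(frames[[f]], calib, threshold, window, rxy, rz,
                            suppressionRadius, bgWindow, frameIndex = f)
    nCand <- nCand + attr(r, "diagnostics")$nCandidates
    res[[f]] <- r
  }
  out <- do.call(rbind, res)
  attr(out, "diagnostics") <- list(nCandidates = nCand, nAccepted = nrow(out))
  out
}
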