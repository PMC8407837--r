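# Ground-truth matching and the challenge metrics: Jaccard index,
# lateral/axial RMSE, efficiency, and Fourier ring correlation.

BIGCOST <- 1e9

# Minimum-cost square assignment (Jonker-Volgenant style shortest
# augmenting paths with dual potentials). cost must be finite; gated
# (disallowed) pairs carry BIGCOST so maximizing the number of true
# matches dominates. Returns the column assigned to each row.
#' @keywords internal
#' @noRd
lapSolve <- function(cost) {
  n <- nrow(cost)
  if (n == 0L) return(integer(0))
  u <- numeric(n); v <- numeric(n)
  p <- integer(n + 1L)    # p[j + 1]: row assigned to column j (0 = virtual)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- logical(n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])
      cur <- cost[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd] + 1L] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedReal <- which(used[-1L])
      rowsUsed <- p[c(1L, usedReal + 1L)]
      u[rowsUsed] <- u[rowsUsed] + delta
      v[usedReal] <- v[usedReal] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  assign[p[-1L]] <- seq_len(n)
  assign
}

#' Ground truth of a movie as a localization table
#'
#' Converts the per-emitter truth of a [SyntheticMovie-class] (pixels) to
#' the nm-based column layout of the localization tables so the two can
#' be matched directly.
#'
#' @param movie a [SyntheticMovie-class].
#' @return data.frame with `frame`, `x_nm`, `y_nm`, `z_nm`, `peak`.
#' @export
groundTruthTable <- function(movie) {
  gt <- movie@groundTruth
  data.frame(frame = gt$frame, x_nm = gt$x * movie@pixelSize,
             y_nm = gt$y * movie@pixelSize, z_nm = gt$z, peak = gt$peak)
}

#' Match localizations against ground truth
#'
#' Per frame, finds the globally optimal one-to-one assignment (minimum
#' total 3D distance) among ground-truth/fit pairs that fall within both
#' the lateral and the axial tolerance gate; everything else counts as
#' false positive (unmatched fit) or false negative (unmatched truth).
#' The default gates are the 2016 localization-challenge values of
#' 250 nm lateral and 500 nm axial.
#'
#' @param fits,truth data.frames with columns `frame`, `x_nm`, `y_nm`,
#'   `z_nm` in the same coordinate system.
#' @param lateralTol,axialTol matching gates, nm.
#' @return a [MatchResult-class]; `pairs` holds (truth row, fit row)
#'   indices into the input tables.
#' @export
matchLocalizations <- function(fits, truth, lateralTol = 250, axialTol = 500) {
  need <- c("frame", "x_nm", "y_nm", "z_nm")
  stopifnot(all(need %in% names(fits)), all(need %in% names(truth)))
  pairs <- matrix(integer(0), 0L, 2L)
  latErr <- numeric(0)
  axErr <- numeric(0)
  frames <- union(unique(truth$frame), unique(fits$frame))
  for (f in frames) {
    gi <- which(truth$frame == f)
    fi <- which(fits$frame == f)
    if (!length(gi) || !length(fi)) next
    dx <- outer(truth$x_nm[gi], fits$x_nm[fi], "-")
    dy <- outer(truth$y_nm[gi], fits$y_nm[fi], "-")
    dz <- outer(truth$z_nm[gi], fits$z_nm[fi], "-")
    lat <- sqrt(dx^2 + dy^2)
    allowed <- lat <= lateralTol & abs(dz) <= axialTol
    if (!any(allowed)) next
    cost <- sqrt(lat^2 + dz^2)
    cost[!allowed] <- BIGCOST
    n <- max(length(gi), length(fi))
    sq <- matrix(BIGCOST, n, n)
    sq[seq_along(gi), seq_along(fi)] <- cost
    assign <- lapSolve(sq)
    for (a in seq_along(gi)) {
      b <- assign[a]
      if (b <= length(fi) && cost[a, b] < BIGCOST) {
        pairs <- rbind(pairs, c(gi[a], fi[b]))
        latErr <- c(latErr, lat[a, b])
        axErr <- c(axErr, abs(dz[a, b]))
      }
    }
  }
  nTP <- nrow(pairs)
  new("MatchResult", pairs = pairs, nTP = as.integer(nTP),
      nFP = as.integer(nrow(fits) - nTP), nFN = as.integer(nrow(truth) - nTP),
      lateralErrors = latErr, axialErrors = axErr)
}

setMethod("show", "MatchResult", function(object) {
  cat(sprintf(
    "MatchResult: TP %d, FP %d, FN %d; Jaccard %.3f; RMSE %.1f nm lateral / %.1f nm axial\n",
    object@nTP, object@nFP, object@nFN, jaccardIndex(object),
    rmseErrors(object)[["lateral"]], rmseErrors(object)[["axial"]]))
})

#' Jaccard index of a match
#'
#' `TP / (TP + FP + FN)`: the overlap between the detected and the true
#' emitter sets.
#'
#' @param match a [MatchResult-class].
#' @return fraction in `[0, 1]`.
#' @export
jaccardIndex <- function(match) {
  denom <- match@nTP + match@nFP + match@nFN
  if (denom == 0L) return(1)
  match@nTP / denom
}

#' Root-mean-square localization errors of a match
#'
#' Lateral error is the 2D Euclidean distance per matched pair; axial is
#' `|dz|`.
#'
#' @param match a [MatchResult-class].
#' @return named numeric `c(lateral, axial)` in nm (`NaN` with no pairs).
#' @export
rmseErrors <- function(match) {
  c(lateral = sqrt(mean(match@lateralErrors^2)),
    axial = sqrt(mean(match@axialErrors^2)))
}

#' Localization-challenge efficiency score
#'
#' `E = 100 - sqrt((100 (1 - JI))^2 + (alpha RMSE)^2)` with
#' `alpha = 1 /nm` laterally and `0.5 /nm` axially; the overall score is
#' the mean of the two components. A perfect match with zero error scores
#' 100 in every component.
#'
#' @param jaccard Jaccard index, fraction.
#' @param lateralRmse,axialRmse nm.
#' @param alphaLateral,alphaAxial error weights, 1/nm.
#' @return named numeric `c(lateral, axial, overall)` in percent.
#' @export
efficiency <- function(jaccard, lateralRmse, axialRmse,
                       alphaLateral = 1, alphaAxial = 0.5) {
  eLat <- 100 - sqrt((100 * (1 - jaccard))^2 + (alphaLateral * lateralRmse)^2)
  eAx <- 100 - sqrt((100 * (1 - jaccard))^2 + (alphaAxial * axialRmse)^2)
  c(lateral = eLat, axial = eAx, overall = (eLat + eAx) / 2)
}

#' Fourier ring correlation between two half-dataset images
#'
#' Ring-wise normalized cross-correlation of the 2D Fourier transforms;
#' the image resolution is read off where the (3-ring moving-average
#' smoothed) curve first drops below the threshold, by default the
#' "1 over 7" (14.29%) criterion. All threshold crossings are reported as
#' well, since curves of discretely fitted data can dip more than once.
#'
#' @param imageA,imageB same-shape square numeric matrices (typically
#'   renders of the even and odd frames).
#' @param pixelSize nm per rendered pixel.
#' @param threshold correlation threshold, default 1/7.
#' @param smooth moving-average window in rings (odd; 1 = no smoothing).
#' @return list of class `FRCResult`: `spatialFrequencies` (cycles/px per
#'   ring), `correlation`, `smoothed`, `resolution` (nm, `NA` when the
#'   curve never crosses), `crossings` (nm for every downward crossing),
#'   `threshold`.
#' @export
frc <- function(imageA, imageB, pixelSize, threshold = 1 / 7, smooth = 3L) {
  stopifnot(identical(dim(imageA), dim(imageB)),
            nrow(imageA) == ncol(imageA))
  n <- nrow(imageA)
  fa <- stats::fft(imageA)
  fb <- stats::fft(imageB)
  ax <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))  # frequency index per dim
  ring <- round(sqrt(outer(ax^2, ax^2, "+")))
  maxR <- n %/% 2
  sel <- ring <= maxR
  rf <- factor(ring[sel], levels = 0:maxR)
  num <- tapply(Re(fa[sel] * Conj(fb[sel])), rf, sum)
  da <- tapply(abs(fa[sel])^2, rf, sum)
  db <- tapply(abs(fb[sel])^2, rf, sum)
  corr <- as.numeric(num / sqrt(da * db))
  corr[!is.finite(corr)] <- 0
  sm <- corr
  if (smooth > 1L) {
    f <- stats::filter(corr, rep(1 / smooth, smooth), sides = 2L)
    sm[!is.na(f)] <- f[!is.na(f)]
  }
  rings <- 0:maxR
  freqPx <- rings / n
  below <- sm < threshold
  crossIdx <- which(below & !c(FALSE, below[-length(below)]) & rings > 0)
  toNm <- function(r) n * pixelSize / r
  res <- if (length(crossIdx)) toNm(rings[crossIdx[1L]]) else NA_real_
  structure(list(spatialFrequencies = freqPx, correlation = corr,
                 smoothed = sm, resolution = res,
                 crossings = toNm(rings[crossIdx]), threshold = threshold),
            class = "FRCResult")
}

#' @export
print.FRCResult <- function(x, ...) {
  cat(sprintf("FRC: resolution %s at threshold %.4f (%d rings)\n",
              if (is.na(x$resolution)) "undefined (no crossing)"
              else sprintf("%.1f nm", x$resolution),
              x$threshold, length(x$correlation)))
  invisible(x)
}
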