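# Candidate detection: modified non-maximum suppression on the 3x3-mean
# score image, boundary-line local background, intensity threshold.

# 3x3 box mean with -Inf outside the valid 1-px-inset region, so border
# pixels can never become candidates.
#' @keywords internal
#' @noRd
boxMean3 <- function(frame) {
  nr <- nrow(frame); nc <- ncol(frame)
  s <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    s[2:(nr - 1), 2:(nc - 1)] <- s[2:(nr - 1), 2:(nc - 1)] +
      frame[(2 + dr):(nr - 1 + dr), (2 + dc):(nc - 1 + dc)]
  }
  s <- s / 9
  s[c(1L, nr), ] <- -Inf
  s[, c(1L, nc)] <- -Inf
  s
}

# Running maximum filter over a (2r+1) square (separable, via pmax shifts).
#' @keywords internal
#' @noRd
maxFilterSquare <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  rows <- m
  for (d in seq_len(r)) {
    up <- rbind(m[-seq_len(d), , drop = FALSE],
                matrix(-Inf, d, nc))
    dn <- rbind(matrix(-Inf, d, nc),
                m[seq_len(nr - d), , drop = FALSE])
    rows <- pmax(rows, up, dn)
  }
  out <- rows
  for (d in seq_len(r)) {
    lf <- cbind(rows[, -seq_len(d), drop = FALSE], matrix(-Inf, nr, d))
    rt <- cbind(matrix(-Inf, nr, d), rows[, seq_len(nc - d), drop = FALSE])
    out <- pmax(out, lf, rt)
  }
  out
}

#' Local background along a square boundary line
#'
#' Arithmetic mean of the pixels on the perimeter of a `bgWindow`-sided
#' square centered on `(cx, cy)`. For even window sides the square spans
#' offsets `-floor(w/2) .. w/2 - 1`. Perimeter pixels falling outside the
#' frame are clipped (excluded from the mean).
#'
#' @param frame 2D count matrix.
#' @param cx,cy center pixel, 0-based (x = column, y = row).
#' @param bgWindow square side length in pixels, > 2.
#' @return mean of the in-frame perimeter pixels, counts.
#' @export
localBackground <- function(frame, cx, cy, bgWindow = 11L) {
  w <- as.integer(bgWindow)
  if (w <= 2L) stop("bgWindow must be > 2 pixels")
  lo <- -(w %/% 2L)
  hi <- lo + w - 1L
  edge <- lo:hi
  offs <- rbind(
    cbind(dx = edge, dy = lo),
    cbind(dx = edge, dy = hi),
    cbind(dx = lo, dy = edge[-c(1L, w)]),
    cbind(dx = hi, dy = edge[-c(1L, w)]))
  xs <- cx + offs[, "dx"]
  ys <- cy + offs[, "dy"]
  keep <- xs >= 0L & xs < ncol(frame) & ys >= 0L & ys < nrow(frame)
  if (!any(keep)) stop("background window lies entirely outside the frame")
  mean(frame[cbind(ys[keep] + 1L, xs[keep] + 1L)])
}

#' Find single-emitter candidates by modified non-maximum suppression
#'
#' Maxima are identified on the raw image (pixels not smaller than any
#' of their 8 neighbors); each maximum is scored by the mean of the 3x3
#' block around it, and that smoothed score -- not the single noisy
#' pixel -- drives the suppression: maxima are visited in decreasing
#' score order (ties lexicographically by `(row, col)`) and kept only if
#' no already-kept maximum lies within `suppressionRadius` (Chebyshev
#' distance). Each survivor gets a local background estimate from the
#' square boundary line ([localBackground()]); candidates whose peak
#' statistic does not exceed `background + threshold` are dropped, as
#' are candidates whose `fitWindow` would cross the frame border.
#'
#' @param frame 2D count matrix.
#' @param threshold intensity threshold, counts above local background
#'   (strict inequality).
#' @param suppressionRadius Chebyshev radius in pixels, >= 1; defaults to
#'   `floor(fitWindow/2)`, i.e. the suppression neighborhood is the fit
#'   window itself (the method requires one emitter per fit window).
#' @param bgWindow side of the background boundary square, pixels.
#' @param fitWindow fit window side, pixels; candidates closer than
#'   `floor(fitWindow/2)` to any border are discarded, not clipped.
#' @param frameIndex value copied into the `frame` column.
#' @param peakStatistic which statistic is compared against
#'   `background + threshold`: the `"score"` (3x3 mean, default -- the
#'   same smoothed value the suppression ranks by, far less sensitive to
#'   the electron-multiplying noise of a single pixel) or the `"raw"`
#'   center pixel value.
#' @return data.frame sorted by decreasing `peak`, with columns `frame`,
#'   `px`, `py` (0-based integer pixel, x = column), `peak` (raw center
#'   pixel), `score` (3x3 mean) and `bg` (counts). Zero rows on blank
#'   frames.
#' @export
findCandidates <- function(frame, threshold, suppressionRadius = NULL,
                           bgWindow = 11L, fitWindow = 9L, frameIndex = 1L,
                           peakStatistic = c("score", "raw")) {
  peakStatistic <- match.arg(peakStatistic)
  if (!is.matrix(frame) || !length(frame)) stop("frame must be a non-empty matrix")
  if (is.null(suppressionRadius)) suppressionRadius <- fitWindow %/% 2L
  r <- as.integer(suppressionRadius)
  if (r < 1L) stop("suppressionRadius must be >= 1")
  s <- boxMean3(frame)
  # raw local maxima (8-neighborhood); the border inset comes from the
  # -Inf frame of the score image
  mxRaw <- maxFilterSquare(frame, 1L)
  hit <- which(is.finite(s) & frame >= mxRaw, arr.ind = TRUE)
  if (nrow(hit) == 0L)
    return(emptyCandidates())
  sc <- s[hit]
  # greedy suppression by smoothed score with an occupancy grid
  ord2 <- order(-sc, hit[, 1L], hit[, 2L])
  hit <- hit[ord2, , drop = FALSE]
  nr <- nrow(frame); nc <- ncol(frame)
  blocked <- matrix(FALSE, nr, nc)
  keep <- logical(nrow(hit))
  for (a in seq_len(nrow(hit))) {
    ra <- hit[a, 1L]; ca <- hit[a, 2L]
    if (blocked[ra, ca]) next
    keep[a] <- TRUE
    blocked[max(1L, ra - r):min(nr, ra + r),
            max(1L, ca - r):min(nc, ca + r)] <- TRUE
  }
  hit <- hit[keep, , drop = FALSE]
  half <- as.integer(fitWindow) %/% 2L
  py <- hit[, 1L] - 1L
  px <- hit[, 2L] - 1L
  inb <- px >= half & px < ncol(frame) - half & py >= half & py < nrow(frame) - half
  px <- px[inb]; py <- py[inb]
  if (!length(px)) return(emptyCandidates())
  bg <- vapply(seq_along(px), function(idx)
    localBackground(frame, px[idx], py[idx], bgWindow), numeric(1))
  peak <- frame[cbind(py + 1L, px + 1L)]
  score <- s[cbind(py + 1L, px + 1L)]
  stat <- if (peakStatistic == "score") score else peak
  pass <- which((stat - bg) > threshold)
  out <- data.frame(frame = rep(as.integer(frameIndex), length(pass)),
                    px = as.integer(px[pass]), py = as.integer(py[pass]),
                    peak = peak[pass], score = score[pass], bg = bg[pass])
  out[order(-out$peak, out$py, out$px), , drop = FALSE]
}

#' @keywords internal
#' @noRd
emptyCandidates <- function() {
  data.frame(frame = integer(0), px = integer(0), py = integer(0),
             peak = numeric(0), score = numeric(0), bg = numeric(0))
}
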