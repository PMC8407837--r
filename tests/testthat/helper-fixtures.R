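# Shared fixtures and independent oracles. Everything is generated in
# code; expensive objects are built lazily and cached for the whole run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# Constant-width calibration (sigma_x = sigma_y = sigma everywhere):
# a constant is exactly representable by the spline basis.
flatCalibration <- function(sigma = 1, zMax = 600, phi = 0) {
  z <- seq(-zMax, zMax, by = 50)
  calibrationFromCurves(z, rep(sigma, length(z)), rep(sigma, length(z)),
                        phi = phi)
}

# Quadratic width curves (exactly representable by cubic B-splines):
# sigma(z) = 1.3 + 0.5 (z / 400)^2, mirrored for sigma_y.
quadCalibration <- function(zMax = 600, phi = 0, shift = 150) {
  z <- seq(-zMax, zMax, by = 50)
  sx <- 1.3 + 0.5 * ((z - shift) / 400)^2
  sy <- 1.3 + 0.5 * ((z + shift) / 400)^2
  calibrationFromCurves(z, sx, sy, phi = phi)
}

starCalib <- function() cached("starCalib", defaultStarCalibration())

defaultTable <- function()
  cached("defaultTable", buildTable(lookupTableSpec(), starCalib()))

# small table for index/step tests: 9 x 9, dxy 0.5 over +-2, dz 100 over +-500
smallTable <- function()
  cached("smallTable",
         buildTable(lookupTableSpec(window = 9L, dxy = 0.5, rxy = 4,
                                    dz = 100, rz = 1000), starCalib()))

# Render an isolated emitter and return the noisy frame (counts).
emitterFrame <- function(calib, x, y, z, peak = 2000, size = 41L,
                         noise = NULL, baseline = 100) {
  em <- data.frame(frame = 1L, x = x, y = y, z = z, peak = peak)
  if (is.null(noise)) {
    lutSMLM:::renderExpectedFrame(calib, em, size, size) + baseline
  } else {
    ph <- lutSMLM:::renderExpectedFrame(calib, em, size, size,
                                        units = "photons", noise = noise)
    applyEMCCDNoise(ph, noise)
  }
}

# ---------------------------------------------------------------------------
# Independent oracles

# Per-pixel brute-force modified NMS + boundary-line background +
# threshold, implementing the documented contract with explicit loops.
oracleCandidates <- function(frame, threshold, r, bgWindow, fitWindow,
                             peakStatistic = "score") {
  nr <- nrow(frame); nc <- ncol(frame)
  score <- matrix(-Inf, nr, nc)
  for (row in 2:(nr - 1)) for (col in 2:(nc - 1))
    score[row, col] <- mean(frame[(row - 1):(row + 1), (col - 1):(col + 1)])
  # identified maxima: raw pixels not smaller than any 8-neighbor
  surv <- list()
  for (row in 2:(nr - 1)) for (col in 2:(nc - 1)) {
    if (frame[row, col] >= max(frame[(row - 1):(row + 1), (col - 1):(col + 1)]))
      surv[[length(surv) + 1L]] <- c(row, col)
  }
  if (!length(surv)) return(data.frame(px = integer(0), py = integer(0)))
  sm <- do.call(rbind, surv)
  sc <- score[sm]
  # greedy in (score desc, row, col) order with min-distance blocking
  ord <- order(-sc, sm[, 1L], sm[, 2L])
  sm <- sm[ord, , drop = FALSE]; sc <- sc[ord]
  kept <- matrix(numeric(0), 0L, 2L)
  for (a in seq_len(nrow(sm))) {
    blocked <- FALSE
    for (b in seq_len(nrow(kept)))
      if (max(abs(sm[a, ] - kept[b, ])) <= r) { blocked <- TRUE; break }
    if (!blocked) kept <- rbind(kept, sm[a, ])
  }
  half <- fitWindow %/% 2L
  out <- data.frame(px = integer(0), py = integer(0), peak = numeric(0),
                    score = numeric(0), bg = numeric(0))
  for (a in seq_len(nrow(kept))) {
    row <- kept[a, 1L]; col <- kept[a, 2L]
    px <- col - 1L; py <- row - 1L
    if (px < half || px >= nc - half || py < half || py >= nr - half) next
    bg <- oraclePerimeterMean(frame, px, py, bgWindow)
    stat <- if (peakStatistic == "score") score[row, col] else frame[row, col]
    if (stat - bg > threshold)
      out <- rbind(out, data.frame(px = px, py = py, peak = frame[row, col],
                                   score = score[row, col], bg = bg))
  }
  out[order(-out$peak, out$py, out$px), , drop = FALSE]
}

# boundary-line mean by explicit coordinate enumeration
oraclePerimeterMean <- function(frame, cx, cy, w) {
  lo <- -(w %/% 2L); hi <- lo + w - 1L
  vals <- numeric(0)
  for (dx in lo:hi) for (dy in lo:hi) {
    if (dx != lo && dx != hi && dy != lo && dy != hi) next
    x <- cx + dx; y <- cy + dy
    if (x < 0 || x >= ncol(frame) || y < 0 || y >= nrow(frame)) next
    vals <- c(vals, frame[y + 1L, x + 1L])
  }
  mean(vals)
}

# Moore-Penrose pseudo-inverse via SVD (least-squares step oracle).
pinv <- function(A, tol = 1e-12) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Exhaustive optimal gated assignment for small matching instances:
# maximize the number of in-gate pairs, among those minimize the total
# 3D distance. Returns list(nTP, cost).
oracleAssignment <- function(cost, allowed) {
  nG <- nrow(cost); nF <- ncol(cost)
  best <- list(nTP = -1L, cost = Inf)
  recurse <- function(g, used, n, tot) {
    if (g > nG) {
      if (n > best$nTP || (n == best$nTP && tot < best$cost))
        best <<- list(nTP = n, cost = tot)
      return()
    }
    recurse(g + 1L, used, n, tot)          # leave g unmatched
    for (f in seq_len(nF)) {
      if (!used[f] && allowed[g, f]) {
        used[f] <- TRUE
        recurse(g + 1L, used, n + 1L, tot + cost[g, f])
        used[f] <- FALSE
      }
    }
  }
  recurse(1L, logical(nF), 0L, 0)
  best
}

# Ring-by-ring FRC with explicit loops (independent of the package path).
oracleFRC <- function(a, b) {
  n <- nrow(a)
  fa <- stats::fft(a); fb <- stats::fft(b)
  maxR <- n %/% 2
  num <- den1 <- den2 <- numeric(maxR + 1L)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    qi <- min(i - 1L, n - (i - 1L))
    qj <- min(j - 1L, n - (j - 1L))
    r <- round(sqrt(qi^2 + qj^2))
    if (r > maxR) next
    num[r + 1L] <- num[r + 1L] + Re(fa[i, j] * Conj(fb[i, j]))
    den1[r + 1L] <- den1[r + 1L] + abs(fa[i, j])^2
    den2[r + 1L] <- den2[r + 1L] + abs(fb[i, j])^2
  }
  out <- num / sqrt(den1 * den2)
  out[!is.finite(out)] <- 0
  out
}

# Simpson quadrature of the sampled PSF over one pixel (for the
# integrated-model oracle).
oraclePixelIntegral <- function(calib, x, y, z, i, j, n = 61L) {
  gx <- seq(i - 0.5, i + 0.5, length.out = n)
  gy <- seq(j - 0.5, j + 0.5, length.out = n)
  wts <- c(1, rep(c(4, 2), (n - 3) / 2), 4, 1) / 3 * (1 / (n - 1))
  vals <- outer(gy, gx, function(jj, ii)
    psfValue(calib, x, y, z, ii, jj))
  as.numeric(t(wts) %*% vals %*% wts)
}
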