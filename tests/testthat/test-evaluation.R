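# Ground-truth matching, challenge metrics, Fourier ring correlation.

fakeLocs <- function(frame, x, y, z) {
  data.frame(frame = frame, x_nm = x, y_nm = y, z_nm = z)
}

test_that("matching trivia: perfect match, partial match, symmetry", {
  gt <- fakeLocs(1L, c(100, 900), c(100, 900), c(0, 200))
  m <- matchLocalizations(gt, gt)
  expect_identical(c(m@nTP, m@nFP, m@nFN), c(2L, 0L, 0L))
  expect_identical(m@lateralErrors, c(0, 0))
  expect_equal(jaccardIndex(m), 1)
  # 2 truths, 1 fit near truth #1
  fits <- fakeLocs(1L, 110, 95, 10)
  m2 <- matchLocalizations(fits, gt)
  expect_identical(c(m2@nTP, m2@nFP, m2@nFN), c(1L, 0L, 1L))
  expect_equal(m2@lateralErrors, sqrt(10^2 + 5^2))
  expect_equal(m2@axialErrors, 10)
  # swapping fits and truth swaps FP and FN
  m3 <- matchLocalizations(gt, fits)
  expect_identical(c(m3@nTP, m3@nFP, m3@nFN), c(1L, 1L, 0L))
  # localizations only match within their own frame
  off <- fakeLocs(2L, 110, 95, 10)
  m4 <- matchLocalizations(off, gt)
  expect_identical(m4@nTP, 0L)
})

test_that("small random instances match the exhaustive assignment oracle", {
  set.seed(51)
  for (r in 1:25) {
    nG <- sample(1:6, 1); nF <- sample(1:6, 1)
    gt <- fakeLocs(1L, runif(nG, 0, 600), runif(nG, 0, 600),
                   runif(nG, -300, 300))
    fits <- fakeLocs(1L, runif(nF, 0, 600), runif(nF, 0, 600),
                     runif(nF, -300, 300))
    m <- matchLocalizations(fits, gt, lateralTol = 250, axialTol = 500)
    dx <- outer(gt$x_nm, fits$x_nm, "-"); dy <- outer(gt$y_nm, fits$y_nm, "-")
    dz <- outer(gt$z_nm, fits$z_nm, "-")
    lat <- sqrt(dx^2 + dy^2)
    allowed <- lat <= 250 & abs(dz) <= 500
    oracle <- oracleAssignment(sqrt(lat^2 + dz^2), allowed)
    expect_identical(m@nTP, oracle$nTP)
    expect_equal(sum(sqrt(m@lateralErrors^2 + m@axialErrors^2)), oracle$cost,
                 tolerance = 1e-9)
  }
})

test_that("Jaccard index equals the set-theoretic overlap", {
  m <- new("MatchResult", pairs = matrix(1L, 1L, 2L), nTP = 1L, nFP = 1L,
           nFN = 1L, lateralErrors = 0, axialErrors = 0)
  expect_equal(jaccardIndex(m), 1 / 3)
  set.seed(52)
  for (r in 1:10) {
    tp <- sample(0:30, 1); fp <- sample(0:10, 1); fn <- sample(0:10, 1)
    if (tp + fp + fn == 0) next
    m <- new("MatchResult",
             pairs = cbind(seq_len(tp), seq_len(tp)),
             nTP = tp, nFP = fp, nFN = fn,
             lateralErrors = numeric(tp), axialErrors = numeric(tp))
    truthIds <- seq_len(tp + fn)
    fitIds <- c(seq_len(tp), tp + fn + seq_len(fp))
    expect_equal(jaccardIndex(m),
                 length(intersect(truthIds, fitIds)) /
                   length(union(truthIds, fitIds)))
  }
})

test_that("RMSE follows the 3-4-5 example and the direct formula", {
  m <- new("MatchResult", pairs = matrix(1L, 1L, 2L), nTP = 1L, nFP = 0L,
           nFN = 0L, lateralErrors = 5, axialErrors = 12)
  r <- rmseErrors(m)
  expect_equal(r[["lateral"]], 5)
  expect_equal(r[["axial"]], 12)
  set.seed(53)
  lat <- runif(40, 0, 80); ax <- runif(40, 0, 150)
  m2 <- new("MatchResult", pairs = cbind(1:40, 1:40), nTP = 40L, nFP = 0L,
            nFN = 0L, lateralErrors = lat, axialErrors = ax)
  expect_equal(rmseErrors(m2),
               c(lateral = sqrt(mean(lat^2)), axial = sqrt(mean(ax^2))))
})

test_that("efficiency scores follow the challenge formula", {
  perfect <- efficiency(1, 0, 0)
  expect_equal(unname(perfect), c(100, 100, 100))
  zero <- efficiency(0, 0, 0)
  expect_equal(unname(zero), c(0, 0, 0))
  e <- efficiency(0.8, 30, 80)
  expect_equal(e[["lateral"]], 100 - sqrt(20^2 + 30^2))
  expect_equal(e[["axial"]], 100 - sqrt(20^2 + 40^2))
  expect_equal(e[["overall"]], mean(e[c("lateral", "axial")]))
})

test_that("FRC: identical images never cross, independent noise decorrelates", {
  set.seed(54)
  img <- renderGaussianImage(
    data.frame(x_nm = runif(300, 100, 900), y_nm = runif(300, 100, 900)),
    extentNm = c(1066, 1066), pixelSize = 100 / 6, sigmaNm = 25)
  same <- frc(img, img, pixelSize = 100 / 6)
  expect_true(all(abs(same$correlation - 1) < 1e-9))
  expect_true(is.na(same$resolution))
  expect_identical(length(same$crossings), 0L)
  a <- matrix(rnorm(64^2), 64, 64)
  b <- matrix(rnorm(64^2), 64, 64)
  ind <- frc(a, b, pixelSize = 10, smooth = 1L)
  # innermost rings hold only a handful of Fourier coefficients, so
  # judge decorrelation from ring 3 outward plus the overall mean
  expect_lt(max(abs(ind$correlation[-(1:3)])), 0.5)
  expect_lt(mean(abs(ind$correlation[-1L])), 0.15)
})

test_that("FRC rings match an independent loop implementation and locate resolution", {
  set.seed(55)
  locs <- data.frame(x_nm = runif(400, 50, 950), y_nm = runif(400, 50, 950))
  jitter <- function(d) data.frame(x_nm = d$x_nm + rnorm(400, 0, 30),
                                   y_nm = d$y_nm + rnorm(400, 0, 30))
  a <- renderGaussianImage(jitter(locs), c(1066, 1066), 1066 / 64, 25)
  b <- renderGaussianImage(jitter(locs), c(1066, 1066), 1066 / 64, 25)
  got <- frc(a, b, pixelSize = 1066 / 64, smooth = 1L)
  want <- oracleFRC(a, b)
  expect_equal(got$correlation, as.numeric(want), tolerance = 1e-10)
  # correlated at low frequency, decorrelated at high frequency
  expect_gt(got$correlation[2L], 0.8)
  sm <- frc(a, b, pixelSize = 1066 / 64, smooth = 3L)
  expect_false(is.na(sm$resolution))
  # resolution corresponds to its crossing ring: 1/(r/(n*px))
  r <- which(sm$smoothed < sm$threshold &
               seq_along(sm$smoothed) > 1)[1L] - 1L
  expect_equal(sm$resolution, 64 * (1066 / 64) / r)
})
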