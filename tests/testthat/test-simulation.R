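# EMCCD noise chain, Siemens-star geometry, bead stacks, blinking chain.

test_that("EMCCD noise reproduces the closed-form mean and variance", {
  noise <- emccdNoiseModel()  # baseline 100, gain 300, QE 0.9, ro 74.4, cic 2e-4
  n <- 400000L
  # zero-photon image: mean = baseline + gain * spurious = 100.06
  dark <- applyEMCCDNoise(matrix(0, 500, 800), noise, seed = 21L)
  expMean <- noise@baseline + noise@emGain * noise@spuriousCharge
  darkVar <- 2 * noise@emGain^2 * noise@spuriousCharge + noise@readoutNoise^2
  expect_lt(abs(mean(dark) - expMean), 3 * sqrt(darkVar / n))
  # n photons/pixel: mean = baseline + gain * QE * n
  nph <- 5
  lit <- applyEMCCDNoise(matrix(nph, 500, 800), noise, seed = 22L)
  litMean <- noise@baseline + noise@emGain *
    (noise@quantumEfficiency * nph + noise@spuriousCharge)
  litVar <- 2 * noise@emGain^2 * (noise@quantumEfficiency * nph +
                                    noise@spuriousCharge) +
    noise@readoutNoise^2
  expect_lt(abs(mean(lit) - litMean), 3 * sqrt(litVar / n))
  # variance matches the excess-noise-factor-2 EMCCD theory within 5%
  expect_lt(abs(var(as.numeric(lit)) - litVar) / litVar, 0.05)
  expect_error(applyEMCCDNoise(matrix(-1, 2, 2), noise), "non-negative")
})

test_that("the Siemens star honors its counts, min distance and axial staircase", {
  calib <- starCalib()
  mv <- simulateSiemensStar(45 * 30, 30, calib = calib, seed = 31L)
  gt <- groundTruth(mv)
  expect_identical(nrow(gt), 45L * 30L)
  expect_identical(length(frames(mv)), 30L)
  expect_identical(sort(unique(gt$frame)), 1:30)
  # per-frame minimum pairwise lateral distance
  for (f in unique(gt$frame)) {
    sub <- gt[gt$frame == f, ]
    dm <- as.matrix(dist(sub[, c("x", "y")]))
    diag(dm) <- Inf
    expect_gte(min(dm), 7.5)
  }
  # z values cluster on the 45 nm staircase with Normal(0, 25 nm) jitter
  levels <- -450 + 45 * (0:19)
  expect_true(all(gt$z0 %in% levels))
  expect_gt(length(unique(gt$z0)), 15L)
  resid <- gt$z - gt$z0
  expect_equal(sd(resid), 25, tolerance = 0.1)
  ks <- suppressWarnings(ks.test(resid / 25, "pnorm"))
  expect_gt(ks$p.value, 0.01)
  # emitters carry constant flux: peak scales with the sigma product
  sF <- sigmaOfZ(calib, calib@zFocus)
  s <- sigmaOfZ(calib, gt$z)
  expect_equal(gt$peak, 2000 * (sF$sx * sF$sy) / (s$sx * s$sy))
})

test_that("movies are bit-for-bit reproducible from their seed", {
  a <- simulateSiemensStar(200, 4, seed = 5L)
  b <- simulateSiemensStar(200, 4, seed = 5L)
  c <- simulateSiemensStar(200, 4, seed = 6L)
  expect_identical(frames(a), frames(b))
  expect_identical(groundTruth(a), groundTruth(b))
  expect_false(identical(frames(a), frames(c)))
})

test_that("noiseless rendering is the superposition of per-emitter PSFs", {
  calib <- starCalib()
  em <- data.frame(frame = 1L, x = c(12.3, 30.8), y = c(20.1, 40.6),
                   z = c(-100, 250), peak = c(1500, 900))
  frame <- lutSMLM:::renderExpectedFrame(calib, em, 48L, 48L)
  manual <- matrix(0, 48, 48)
  grid <- expand.grid(j = 0:47, i = 0:47)
  for (e in 1:2) {
    v <- psfValue(calib, em$x[e], em$y[e], em$z[e], grid$i, grid$j)
    manual <- manual + em$peak[e] * matrix(v, 48, 48)
  }
  # stamps span +-4 sigma, so superposition holds to the stamp truncation
  expect_equal(frame, manual, tolerance = 1e-3)
})

test_that("density beyond the min-distance constraint raises a generation error", {
  expect_error(
    simulateSiemensStar(500, 1, frameSize = 64L, outerRadius = 20,
                        innerRadius = 10, seed = 1L, maxAttempts = 50L),
    "minimum-distance")
})

test_that("bead stacks keep beads separated, centered and recoverable", {
  calib <- starCalib()
  z <- seq(-300, 300, by = 150)
  sim <- simulateBeadStack(calib, z, nBeads = 4L, peak = 2000, seed = 8L)
  expect_identical(length(sim$stack), length(z))
  expect_identical(nrow(sim$positions), 4L)
  # pairwise spacing >= 2 * window
  dm <- as.matrix(dist(sim$positions)); diag(dm) <- Inf
  expect_gte(min(dm), 30)
  # per-plane peak pixel sits at each bead position (noiseless)
  for (pl in seq_along(z)) {
    fr <- sim$stack[[pl]]
    for (b in 1:4) {
      rows <- sim$positions$y[b] + (-3:3) + 1L
      cols <- sim$positions$x[b] + (-3:3) + 1L
      patch <- fr[rows, cols]
      peakIdx <- which(patch == max(patch), arr.ind = TRUE)[1L, ]
      expect_identical(unname(peakIdx), c(4L, 4L))
    }
  }
})

test_that("blinking chain: empty start, stationary occupancy, power monotonicity", {
  # no activation, all dark: every frame empty
  m0 <- blinkingModel(nFluorophores = 500L, kOnBase = 0, kOnPerMw = 0.01,
                      kOff = 0.5, kBleach = 0)
  r0 <- simulateBlinkingMovie(m0, 50L, uvPower = 0, seed = 41L,
                              initialOnFraction = 0)
  expect_identical(sum(r0$counts), 0L)
  # no bleaching: mean active count ~ N pOn / (pOn + pOff)
  m1 <- blinkingModel(nFluorophores = 3000L, kOnBase = 0.05, kOnPerMw = 0,
                      kOff = 0.6, kBleach = 0)
  r1 <- simulateBlinkingMovie(m1, 400L, uvPower = 0, seed = 42L)
  pOn <- 1 - exp(-0.05); pOff <- 1 - exp(-0.6)
  expectMean <- 3000 * pOn / (pOn + pOff)
  expect_lt(abs(mean(r1$counts) - expectMean) / expectMean, 0.05)
  # raising the UV power raises the mean active count
  mp <- blinkingModel(nFluorophores = 2000L, kOnBase = 0.01, kOnPerMw = 0.005,
                      kOff = 0.7, kBleach = 0)
  lo <- simulateBlinkingMovie(mp, 300L, uvPower = 0, seed = 43L)
  hi <- simulateBlinkingMovie(mp, 300L, uvPower = 30, seed = 43L)
  expect_gt(mean(hi$counts), mean(lo$counts))
})

test_that("rendered blinking movies expose per-frame ground truth", {
  m <- blinkingModel(nFluorophores = 30L, kOnBase = 0.3, kOnPerMw = 0,
                     kOff = 0.5, kBleach = 0)
  r <- simulateBlinkingMovie(m, 5L, seed = 44L, render = TRUE,
                             frameSize = 48L)
  expect_s4_class(r$movie, "SyntheticMovie")
  expect_identical(length(frames(r$movie)), 5L)
  gt <- groundTruth(r$movie)
  expect_identical(as.integer(table(factor(gt$frame, levels = 1:5))),
                   r$counts)
})
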