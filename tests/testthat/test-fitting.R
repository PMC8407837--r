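# Grid-constrained Gauss-Newton fitting, CRLB, continuous reference.

test_that("a zero-residual window is a fixed point of the Gauss-Newton step", {
  tab <- smallTable()
  k <- indexOf(tab, 0.5, -1, 200)
  win <- 120 + 1800 * templateAt(tab, k)$psf
  theta <- c(bg = 120, p = 1800, x = 0.5, y = -1, z = 200)
  st <- gaussNewtonStep(win, tab, theta)
  expect_false(st$singular)
  expect_equal(st$theta, theta, tolerance = 1e-9)
  expect_equal(st$residualNorm, 0, tolerance = 1e-9)
})

test_that("the Gauss-Newton step equals an explicit pseudo-inverse solve", {
  tab <- smallTable()
  set.seed(15)
  w <- tab@spec@window
  for (r in 1:20) {
    k <- sample.int(nTemplates(tab), 1L)
    gp <- gridPointOf(tab, k)
    theta <- c(bg = runif(1, 50, 150), p = runif(1, 500, 3000),
               x = gp$x, y = gp$y, z = gp$z)
    win <- matrix(rnorm(w^2, 100, 40), w, w) +
      theta[["p"]] * templateAt(tab, k)$psf
    tm <- templateAt(tab, k)
    J <- cbind(1, as.numeric(tm$psf), theta[["p"]] * as.numeric(tm$dx),
               theta[["p"]] * as.numeric(tm$dy),
               theta[["p"]] * as.numeric(tm$dz))
    rres <- as.numeric(win) - (theta[["bg"]] + theta[["p"]] * as.numeric(tm$psf))
    deltaOracle <- as.numeric(pinv(J) %*% rres)
    st <- gaussNewtonStep(win, tab, theta)
    # compare the un-rounded update on the linear (bg, p) part and the
    # rounded positions against the oracle's snapped positions
    expect_equal(st$theta[["bg"]] - theta[["bg"]], deltaOracle[1L],
                 tolerance = 1e-8)
    expect_equal(st$theta[["p"]] - theta[["p"]], deltaOracle[2L],
                 tolerance = 1e-8)
    snapped <- lutSMLM:::snapToGrid(tab@spec, theta[["x"]] + deltaOracle[3L],
                                    theta[["y"]] + deltaOracle[4L],
                                    theta[["z"]] + deltaOracle[5L],
                                    tab@calib@zFocus)
    expect_equal(unname(st$theta[c("x", "y", "z")]), unname(snapped))
    # the normal matrix is symmetric by construction
    A <- crossprod(J)
    expect_identical(max(abs(A - t(A))), 0)
  }
})

test_that("noiseless on-grid emitters are recovered exactly", {
  tab <- defaultTable()
  calib <- tab@calib
  frame <- emitterFrame(calib, 20 + 0.2, 20 - 0.3, 50, peak = 2000,
                        baseline = 100)
  win <- lutSMLM:::extractWindow(frame, 20L, 20L, 9L)
  fit <- fitEmitter(win, tab, list(peak = max(win), bg = 100))
  expect_identical(fit$termination, "converged")
  expect_equal(fit$params[["x"]], 0.2)
  expect_equal(fit$params[["y"]], -0.3)
  expect_equal(fit$params[["z"]], 50)
  expect_equal(fit$params[["bg"]], 100, tolerance = 1e-6)
  expect_equal(fit$params[["p"]], 2000, tolerance = 1e-6)
})

test_that("noiseless off-grid emitters land within half a grid step of the continuous optimum", {
  tab <- defaultTable()
  calib <- tab@calib
  for (zt in c(-310, 7, 283)) {
    xt <- 0.23; yt <- -0.37
    frame <- emitterFrame(calib, 20 + xt, 20 + yt, zt, peak = 2000,
                          baseline = 100)
    win <- lutSMLM:::extractWindow(frame, 20L, 20L, 9L)
    fit <- fitEmitter(win, tab, list(peak = max(win), bg = 100),
                      maxIterations = 10L)
    expect_true(fit$termination %in% c("converged", "max_iterations"))
    cont <- fitEmitterContinuous(win, calib, list(peak = max(win), bg = 100))
    expect_true(cont$converged)
    # continuous recovers the truth; discrete is within half a step of it
    expect_equal(cont$params[["x"]], xt, tolerance = 1e-4)
    expect_equal(cont$params[["z"]], zt, tolerance = 1e-1)
    expect_lte(abs(fit$params[["x"]] - cont$params[["x"]]),
               tab@spec@dxy / 2 + 1e-9)
    expect_lte(abs(fit$params[["y"]] - cont$params[["y"]]),
               tab@spec@dxy / 2 + 1e-9)
    expect_lte(abs(fit$params[["z"]] - cont$params[["z"]]),
               tab@spec@dz / 2 + 1e-6)
    # x = +0.23 px specifically rounds to an adjacent 0.1 px column
    expect_true(fit$params[["x"]] %in% c(0.2, 0.3))
  }
})

test_that("fitFrame finds and fits well-separated emitters deterministically", {
  tab <- defaultTable()
  calib <- tab@calib
  expect_identical(nrow(fitFrame(matrix(100, 64, 64), tab, threshold = 300)),
                   0L)
  em <- data.frame(frame = 1L,
                   x = c(15.2, 40.7, 25.4), y = c(18.9, 22.3, 50.6),
                   z = c(-120, 0, 210), peak = 2000)
  frame <- lutSMLM:::renderExpectedFrame(calib, em, 64, 64) + 100
  locs <- fitFrame(frame, tab, threshold = 300)
  expect_identical(nrow(locs), 3L)
  ord <- order(locs$x_px)
  emo <- em[order(em$x), ]
  expect_equal(locs$x_px[ord], emo$x, tolerance = 0.05)
  expect_equal(locs$y_px[ord], emo$y, tolerance = 0.05)
  expect_equal(locs$z_nm[ord], emo$z, tolerance = 12.5)
  # determinism: identical tables on repeat
  expect_identical(locs, fitFrame(frame, tab, threshold = 300))
  d <- attr(locs, "diagnostics")
  expect_identical(d$nCandidates, 3L)
  expect_identical(d$nAccepted, 3L)
})

test_that("CRLB scales as 1/sqrt(N), matches a numerical Fisher oracle, and respects symmetry", {
  tab <- defaultTable()
  k <- indexOf(tab, 0.3, -0.4, 75)
  gp <- gridPointOf(tab, k)
  th1 <- c(bg = 0.5, p = 2000, x = gp$x, y = gp$y, z = gp$z)
  th4 <- th1; th4[["p"]] <- 4 * th1[["p"]]
  c1 <- crlb(tab, th1)
  c4 <- crlb(tab, th4)
  for (pn in c("x", "y", "z"))
    expect_equal(c4[[pn]] / c1[[pn]], 0.5, tolerance = 0.01)
  # numerical Fisher: finite-difference derivatives of the continuous
  # model mu(theta) under per-pixel Poisson statistics
  calib <- tab@calib
  w <- tab@spec@window
  ctr <- (w - 1) / 2
  grid <- expand.grid(j = 0:(w - 1), i = 0:(w - 1))
  muFun <- function(th) th[1L] + th[2L] *
    psfValue(calib, ctr + th[3L], ctr + th[4L], th[5L], grid$i, grid$j)
  th <- unname(th1)
  eps <- c(1e-3, 1e-1, 1e-5, 1e-5, 1e-3)
  D <- sapply(1:5, function(a) {
    hi <- th; hi[a] <- hi[a] + eps[a]
    lo <- th; lo[a] <- lo[a] - eps[a]
    (muFun(hi) - muFun(lo)) / (2 * eps[a])
  })
  infoNum <- crossprod(D, D / muFun(th))
  oracle <- sqrt(diag(solve(infoNum)))
  expect_equal(unname(c1), oracle, tolerance = 1e-3)
  # symmetric in-focus template: CRLB_x == CRLB_y
  flat <- flatCalibration(sigma = 1.4)
  tabF <- buildTable(lookupTableSpec(window = 9L, dxy = 0.5, rxy = 2,
                                     dz = 200, rz = 400), flat)
  cs <- crlb(tabF, c(bg = 10, p = 1000, x = 0, y = 0, z = 0))
  expect_equal(cs[["x"]], cs[["y"]], tolerance = 1e-6)
})

test_that("the EMCCD variance model inflates the CRLB by the excess-noise factor", {
  tab <- defaultTable()
  th <- c(bg = 100, p = 2000, x = 0, y = 0, z = 0)
  noise <- emccdNoiseModel()
  cP <- crlb(tab, th)
  cE <- crlb(tab, th, noise = noise)
  # EMCCD: var = 2 * gain * signal + readout^2 >> Poisson var = mu
  expect_gt(cE[["x"]], 5 * cP[["x"]])
  expect_gt(cE[["z"]], 5 * cP[["z"]])
})

test_that("degenerate windows terminate as singular, not as errors", {
  tab <- smallTable()
  win <- matrix(0, 9, 9)
  # p = 0 makes three Jacobian columns vanish
  st <- gaussNewtonStep(win, tab, c(bg = 0, p = 0, x = 0, y = 0, z = 0))
  expect_true(st$singular)
  fit <- fitEmitter(win, tab, list(peak = 0, bg = 0))
  expect_identical(fit$termination, "degenerate")
})
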