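# Lookup table: grid enumeration, index arithmetic, template content.

test_that("template count follows the grid convention (brute-force enumeration)", {
  # +-r/2 inclusive on every axis
  spec <- lookupTableSpec(window = 9L, dxy = 0.5, rxy = 1, dz = 100, rz = 200)
  enum <- expand.grid(x = seq(-0.5, 0.5, by = 0.5),
                      y = seq(-0.5, 0.5, by = 0.5),
                      z = seq(-100, 100, by = 100))
  expect_identical(nTemplates(spec), nrow(enum))
  spec2 <- lookupTableSpec()
  enum2 <- length(seq(-2, 2, by = 0.1))^2 * length(seq(-500, 500, by = 25))
  expect_identical(nTemplates(spec2), as.integer(enum2))
  # doubling dxy at fixed range shrinks the lateral axes ~4x
  coarse <- lookupTableSpec(dxy = 0.2)
  g1 <- lutSMLM:::gridSizes(spec2); g2 <- lutSMLM:::gridSizes(coarse)
  expect_equal(g1[["nxy"]]^2 / g2[["nxy"]]^2, (41 / 21)^2)
  expect_identical(g1[["nz"]], g2[["nz"]])
  # invalid grids are rejected
  expect_error(lookupTableSpec(window = 8L), "odd")
  expect_error(lookupTableSpec(dxy = 0.3), "multiple")
})

test_that("templates equal direct model evaluation at their grid points", {
  tab <- smallTable()
  calib <- tab@calib
  set.seed(9)
  ctr <- (tab@spec@window - 1) / 2
  grid <- expand.grid(j = 0:(tab@spec@window - 1), i = 0:(tab@spec@window - 1))
  for (k in sample.int(nTemplates(tab), 25L)) {
    gp <- gridPointOf(tab, k)
    tm <- templateAt(tab, k)
    v <- psfValue(calib, ctr + gp$x, ctr + gp$y, gp$z, grid$i, grid$j)
    g <- psfGradient(calib, ctr + gp$x, ctr + gp$y, gp$z, grid$i, grid$j)
    w <- tab@spec@window
    expect_equal(as.numeric(tm$psf), v, tolerance = 1e-12)
    expect_equal(as.numeric(tm$dx), g$dx, tolerance = 1e-12)
    expect_equal(as.numeric(tm$dy), g$dy, tolerance = 1e-12)
    expect_equal(as.numeric(tm$dz), g$dz, tolerance = 1e-12)
    expect_true(all(tm$psf > 0) && max(tm$psf) <= 1)
  }
  # center template peaks at 1 exactly
  kc <- indexOf(tab, 0, 0, tab@calib@zFocus)
  expect_equal(max(templateAt(tab, kc)$psf), 1.0)
})

test_that("index arithmetic: grid round-trip, nearest-step rounding, NN oracle", {
  tab <- smallTable()
  spec <- tab@spec
  n <- nTemplates(tab)
  # index_of o grid_point == identity for every template
  gp <- gridPointOf(tab, seq_len(n))
  expect_identical(indexOf(tab, gp$x, gp$y, gp$z), seq_len(n))
  # nearest-step rounding: dxy = 0.1 sends +0.23 to the +0.2 column
  d <- defaultTable()
  gpd <- gridPointOf(d, indexOf(d, 0.23, -0.16, 12))
  expect_equal(gpd$x, 0.2)
  expect_equal(gpd$y, -0.2)
  expect_equal(gpd$z, 0)
  # half steps round away from the center
  expect_equal(gridPointOf(d, indexOf(d, 0.25, -0.25, 12.5))$x, 0.3)
  expect_equal(gridPointOf(d, indexOf(d, 0.25, -0.25, 12.5))$y, -0.3)
  # 10 000 random in-range positions against per-axis brute-force search
  set.seed(10)
  m <- 10000L
  xs <- runif(m, -2, 2); ys <- runif(m, -2, 2)
  zs <- runif(m, tab@zValues[1L], tab@zValues[length(tab@zValues)])
  got <- indexOf(tab, xs, ys, zs)
  nxy <- length(tab@xOffsets); nz <- length(tab@zValues)
  oracle <- vapply(seq_len(m), function(q) {
    ix <- which.min(abs(tab@xOffsets - xs[q]))
    iy <- which.min(abs(tab@yOffsets - ys[q]))
    iz <- which.min(abs(tab@zValues - zs[q]))
    ((ix - 1L) * nxy + (iy - 1L)) * nz + iz
  }, integer(1))
  expect_identical(got, oracle)
  # out-of-range positions signal NA instead of erroring
  expect_true(is.na(indexOf(tab, 2.4, 0, 0)))
  expect_true(is.na(indexOf(tab, 0, 0, 560)))
})

test_that("table build is deterministic and reports its memory footprint", {
  spec <- lookupTableSpec(window = 7L, dxy = 0.5, rxy = 2, dz = 250, rz = 500)
  a <- buildTable(spec, starCalib())
  b <- buildTable(spec, starCalib())
  expect_identical(a@templates, b@templates)
  expect_identical(memoryFootprint(a),
                   nTemplates(a) * 7^2 * 4 * 8)
  expect_error(templateAt(a, 0L), "index")
  expect_error(templateAt(a, nTemplates(a) + 1L), "index")
  # calibration must cover the axial grid
  shallow <- calibrationFromCurves(seq(-200, 200, 50), rep(1.5, 9), rep(1.5, 9))
  expect_error(buildTable(lookupTableSpec(), shallow), "cover")
})

test_that("finite differences of z-neighboring templates approximate the dz channel", {
  tab <- smallTable()
  nz <- length(tab@zValues)
  set.seed(11)
  for (r in 1:10) {
    k <- sample.int(nTemplates(tab), 1L)
    iz <- (k - 1L) %% nz
    if (iz == 0L || iz == nz - 1L) next
    fd <- (templateAt(tab, k + 1L)$psf - templateAt(tab, k - 1L)$psf) /
      (2 * tab@spec@dz)
    ch <- templateAt(tab, k)$dz
    expect_lt(max(abs(fd - ch)), 0.1 * max(abs(ch)) + 1e-6)  # O(dz) accuracy
  }
})

test_that("phi != 0 tables agree with direct evaluation (slow path)", {
  rot <- quadCalibration(phi = 0.25, zMax = 400)
  spec <- lookupTableSpec(window = 7L, dxy = 1, rxy = 2, dz = 200, rz = 400)
  tab <- buildTable(spec, rot)
  ctr <- 3
  grid <- expand.grid(j = 0:6, i = 0:6)
  for (k in c(1L, 14L, nTemplates(tab))) {
    gp <- gridPointOf(tab, k)
    v <- psfValue(rot, ctr + gp$x, ctr + gp$y, gp$z, grid$i, grid$j)
    expect_equal(as.numeric(templateAt(tab, k)$psf), v, tolerance = 1e-12)
  }
})

test_that("integrated-model tables hold pixel-integrated values", {
  spec <- lookupTableSpec(window = 7L, dxy = 1, rxy = 2, dz = 250, rz = 500)
  tab <- buildTable(spec, starCalib(), model = "integrated")
  ctr <- 3
  grid <- expand.grid(j = 0:6, i = 0:6)
  k <- indexOf(tab, 1, -1, 250)
  gp <- gridPointOf(tab, k)
  v <- psfValueIntegrated(tab@calib, ctr + gp$x, ctr + gp$y, gp$z,
                          grid$i, grid$j)
  g <- psfGradientIntegrated(tab@calib, ctr + gp$x, ctr + gp$y, gp$z,
                             grid$i, grid$j)
  expect_equal(as.numeric(templateAt(tab, k)$psf), v, tolerance = 1e-12)
  expect_equal(as.numeric(templateAt(tab, k)$dz), g$dz, tolerance = 1e-12)
})
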