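test_that("ROI reflectivity follows the percent-difference formula", {
  expect_equal(reflectivityROI(120, 100), 20)
  expect_equal(reflectivityROI(100, 100), 0)
  expect_equal(reflectivityROI(80, 100), -20)
  expect_error(reflectivityROI(50, 0), "positive")
  expect_error(reflectivityROI(50, -3), "positive")
})

test_that("voxel-wise reflectivity: uniform and identity cases", {
  d <- c(5, 5, 5)
  ctl <- Volume3D(array(100, d))
  tst <- Volume3D(array(120, d))
  r <- reflectivityVoxelwise(tst, ctl)
  expect_equal(r@globalPercent, 20)
  expect_true(all(r@voxelMap == 20))
  expect_equal(r@nVoxels, 125L)

  same <- reflectivityVoxelwise(ctl, ctl)
  expect_equal(same@globalPercent, 0)
  expect_true(all(same@voxelMap == 0))
})

test_that("global sums equal an explicit double-loop oracle", {
  set.seed(81)
  d <- c(4, 4, 4)
  I <- array(runif(64, 50, 150), d)
  g <- array(runif(64, 50, 150), d)
  r <- reflectivityVoxelwise(Volume3D(I), Volume3D(g))
  num <- 0; den <- 0
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    num <- num + (I[i, j, k] - g[i, j, k])
    den <- den + g[i, j, k]
  }
  expect_equal(r@globalPercent, num / den * 100, tolerance = 1e-12)
  expect_equal(r@provenance$sumControl, den, tolerance = 1e-12)
})

test_that("ratio-of-sums equals the ROI formula on the same mask (identity)", {
  set.seed(82)
  d <- c(6, 6, 6)
  I <- array(runif(216, 10, 200), d)
  g <- array(runif(216, 10, 200), d)
  mask <- array(runif(216) > 0.4, d)
  r <- reflectivityVoxelwise(Volume3D(I), Volume3D(g), mask = mask)
  roi <- reflectivityROI(mean(I[mask]), mean(g[mask]))
  expect_equal(r@globalPercent, roi, tolerance = 1e-9 * abs(roi))
})

test_that("reflectivity is invariant to a common positive scale", {
  set.seed(83)
  d <- c(5, 5, 5)
  I <- array(runif(125, 50, 150), d)
  g <- array(runif(125, 50, 150), d)
  a <- reflectivityVoxelwise(Volume3D(I), Volume3D(g))
  b <- reflectivityVoxelwise(Volume3D(3.7 * I), Volume3D(3.7 * g))
  expect_equal(a@globalPercent, b@globalPercent, tolerance = 1e-12)
})

test_that("flagged voxels (g <= 0, invalid) are excluded from map and sums", {
  d <- c(3, 3, 3)
  g <- array(100, d); g[1, 1, 1] <- -5
  I <- array(120, d); I[2, 2, 2] <- NA
  r <- reflectivityVoxelwise(Volume3D(I), Volume3D(g))
  expect_true(is.na(r@voxelMap[1, 1, 1]))  # control <= 0
  expect_true(is.na(r@voxelMap[2, 2, 2]))  # invalid test voxel
  expect_equal(r@nVoxels, 26L)             # invalid excluded from N
  expect_error(reflectivityVoxelwise(Volume3D(I), Volume3D(array(-1, d))),
               "positive")
  expect_error(reflectivityVoxelwise(Volume3D(array(1, c(2, 2, 2))),
                                     Volume3D(array(1, d))), "grids")
})

test_that("color map endpoints, midpoint and inversion behave as specified", {
  d <- c(4, 4, 1)
  zero <- renderColorMap(array(0, d), c(-50, 50))
  expect_equal(length(unique(as.vector(zero$colors))), 1)
  # the uniform color inverts to a value within one step of zero
  expect_lt(max(abs(colorMapValues(zero))), 100 / 256)

  vals <- array(c(-50, 50, -999, 999, 0, 10, NA, -10,
                  rep(0, 8)), d)
  cm <- renderColorMap(vals, c(-50, 50))
  expect_equal(cm$colors[1, 1, 1], cm$legend$colors[1])        # lo endpoint
  expect_equal(cm$colors[2, 1, 1], cm$legend$colors[256])      # hi endpoint
  expect_equal(cm$colors[3, 1, 1], cm$legend$colors[1])        # clipped low
  expect_equal(cm$colors[4, 1, 1], cm$legend$colors[256])      # clipped high
  expect_equal(cm$colors[3, 2, 1], "#00000000")                # NA transparent

  inv <- colorMapValues(cm)
  step <- 100 / 256
  inRange <- !is.na(vals) & vals >= -50 & vals <= 50
  expect_true(all(abs(inv[inRange] - vals[inRange]) <= step))
  expect_true(is.na(inv[3, 2, 1]))
})

test_that("paired t-test matches the hand formula and a t-distribution oracle", {
  r <- pairedTTest(c(2, 4, 6), c(1, 2, 3))   # differences 1, 2, 3
  expect_equal(r@statistic, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r@df, 2)
  expect_equal(r@pValue, 2 * stats::pt(-abs(2 * sqrt(3)), df = 2),
               tolerance = 1e-12)

  same <- pairedTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same@statistic, 0)
  expect_equal(same@pValue, 1)

  a <- pairedTTest(c(5, 1, 8, 2), c(3, 3, 3, 3))
  b <- pairedTTest(c(3, 3, 3, 3), c(5, 1, 8, 2))
  expect_equal(a@statistic, -b@statistic, tolerance = 1e-12)
  expect_equal(a@pValue, b@pValue, tolerance = 1e-12)

  const <- pairedTTest(c(2, 3, 4), c(1, 2, 3))  # differences all 1
  expect_equal(const@pValue, 0)
  expect_true(is.infinite(const@statistic))
})

test_that("color maps export to PNG with the expected slice geometry", {
  skip_if_not_installed("png")
  cm <- renderColorMap(array(runif(4 * 5 * 3, -50, 50), c(4, 5, 3)),
                       c(-50, 50))
  f <- withr::local_tempfile(fileext = ".png")
  writeColorMapPNG(cm, f, slice = 2)
  img <- png::readPNG(f)
  expect_equal(dim(img), c(5, 4, 4))  # rows = y, cols = x, RGBA
})
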