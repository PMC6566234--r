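test_that("NIfTI write-read round trip is lossless for values and geometry", {
  ph <- generatePhantom(defaultPhantomSpec(seed = 2))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  writeNiftiVolume(ph@volume, f)
  back <- readNiftiVolume(f)
  expect_identical(back@values, ph@volume@values)
  expect_equal(back@spacing, ph@volume@spacing, tolerance = 1e-7)
  expect_equal(back@origin, ph@volume@origin, tolerance = 1e-5)

  # anisotropic spacing preserved exactly enough for voxel bookkeeping
  v <- Volume3D(array(rnorm(4 * 5 * 6), c(4, 5, 6)),
                spacing = c(0.3125, 0.3125, 1), origin = c(-3, 2, 7))
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  writeNiftiVolume(v, f2)
  b2 <- readNiftiVolume(f2)
  expect_identical(b2@values, v@values)
  expect_equal(b2@spacing, c(0.3125, 0.3125, 1), tolerance = 1e-7)
})

test_that("invalid voxels survive the NIfTI round trip as NaN/NA", {
  vals <- array(runif(3 * 3 * 3), c(3, 3, 3))
  vals[1, 1, 1] <- NA
  v <- Volume3D(vals)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  writeNiftiVolume(v, f)
  b <- readNiftiVolume(f)
  expect_false(validMask(b)[1, 1, 1])
  expect_equal(sum(!validMask(b)), 1)
})

test_that("non-3D NIfTI images are rejected", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(array(0, c(4, 4, 2, 3)))
  RNifti::writeNifti(img, f)
  expect_error(readNiftiVolume(f), "3D")
})

test_that("DICOM series round trip reproduces the protocol geometry", {
  # 128 x 128 matrix over a 40 x 40 mm^2 FOV, 13 slices of 1.0 mm:
  # in-plane spacing 40/128 = 0.3125 mm
  set.seed(10)
  vals <- array(round(runif(128 * 128 * 13, 0, 4000)), c(128, 128, 13))
  vol <- Volume3D(vals, spacing = c(0.3125, 0.3125, 1),
                  origin = c(-20, -20, -6),
                  meta = list(TR_ms = 500, TE_ms = 10))
  d <- withr::local_tempdir()
  writeDicomSeries(vol, d)
  back <- readDicomSeries(d)
  expect_equal(back@spacing, c(0.3125, 0.3125, 1), tolerance = 1e-9)
  expect_equal(back@origin, c(-20, -20, -6), tolerance = 1e-9)
  expect_equal(back@meta$TR_ms, 500)
  expect_equal(back@meta$TE_ms, 10)
  # rescale slope/intercept applied: values match to quantization precision
  expect_lt(max(abs(back@values - vals)), diff(range(vals)) / 65000)
})

test_that("shuffled slice file order reads identically to sorted order", {
  vals <- array(seq_len(16 * 16 * 5), c(16, 16, 5))
  vol <- Volume3D(vals, spacing = c(1, 1, 2), origin = c(0, 0, 0))
  d1 <- withr::local_tempdir()
  writeDicomSeries(vol, d1, seriesUID = "2.25.111")
  sorted <- readDicomSeries(d1)
  # rename so lexicographic file order no longer matches slice order
  files <- list.files(d1, full.names = TRUE)
  new <- file.path(d1, sprintf("z%02d.dcm", rev(seq_along(files))))
  file.rename(files, new)
  shuffled <- readDicomSeries(d1)
  expect_identical(shuffled@values, sorted@values)
  expect_identical(shuffled@origin, sorted@origin)
})

test_that("mixed series UIDs are rejected with the offending UIDs listed", {
  vol <- Volume3D(array(1, c(8, 8, 2)))
  d <- withr::local_tempdir()
  writeDicomSeries(vol, d, seriesUID = "2.25.1")
  writeDicomSeries(Volume3D(array(2, c(8, 8, 2))),
                   file.path(d, "b"), seriesUID = "2.25.2")
  file.copy(list.files(file.path(d, "b"), full.names = TRUE),
            file.path(d, c("x1.dcm", "x2.dcm")))
  unlink(file.path(d, "b"), recursive = TRUE)
  expect_error(readDicomSeries(d), "2\\.25\\.1.*2\\.25\\.2|2\\.25\\.2.*2\\.25\\.1")
})

test_that("water normalization divides by the water mean and records it", {
  vals <- array(4, c(6, 6, 6))
  water <- array(FALSE, c(6, 6, 6))
  water[1:3, , ] <- TRUE
  vals[water] <- 2
  v <- Volume3D(vals)
  nrm <- normalizeByWater(v, water)
  expect_equal(unique(as.numeric(nrm@values[!water])), 2)
  expect_equal(mean(nrm@values[water]), 1)
  expect_equal(nrm@meta$waterMean, 2)

  # water mean 1 leaves the scan unchanged
  v1 <- Volume3D(array(1, c(4, 4, 4)))
  expect_identical(normalizeByWater(v1, array(TRUE, c(4, 4, 4)))@values,
                   v1@values)
})

test_that("normalization is invariant to global intensity scaling", {
  ph <- generatePhantom(twoTubeSpec(signal = 100, seed = 6))
  water <- detectTubes(ph@volume, 200)[[2]]
  a <- normalizeByWater(ph@volume, water)
  scaled <- ph@volume
  scaled@values <- scaled@values * 3
  b <- normalizeByWater(scaled, water)
  expect_equal(a@values, b@values, tolerance = 1e-12)
})

test_that("empty or nonpositive water masks are rejected", {
  v <- Volume3D(array(1, c(4, 4, 4)))
  expect_error(normalizeByWater(v, array(FALSE, c(4, 4, 4))), "empty")
  vneg <- Volume3D(array(-2, c(4, 4, 4)))
  expect_error(normalizeByWater(vneg, array(TRUE, c(4, 4, 4))), "positive")
})
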