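test_that("a separable two-level volume thresholds exactly", {
  vals <- array(0, c(12, 12, 12))
  vals[4:8, 4:8, 4:8] <- 100
  fg <- removeBackground(Volume3D(vals))
  expect_identical(as.logical(fg), as.logical(vals == 100))
})

test_that("the threshold maximizes between-class variance (brute force)", {
  set.seed(21)
  for (q in 1:3) {
    v <- c(rnorm(2000, 40, 12), rnorm(1200, 160, 25))
    v <- round(pmin(pmax(v, 0), 255))
    thr <- otsuThreshold(v)
    expect_equal(thr, otsuOracle(v), tolerance = 1e-12)
  }
})

test_that("constant volumes are rejected (no threshold exists)", {
  expect_error(removeBackground(Volume3D(array(5, c(4, 4, 4)))), "constant")
})

test_that("region growing returns exactly the seeded component", {
  vals <- array(0, c(16, 16, 16))
  vals[3:7, 3:7, 3:7] <- 100          # cube A
  vals[10:14, 10:14, 10:14] <- 100    # cube B, disjoint
  v <- Volume3D(vals)
  mA <- growRegion3D(v, c(5, 5, 5), 50, 150)
  wantA <- array(FALSE, c(16, 16, 16))
  wantA[3:7, 3:7, 3:7] <- TRUE
  expect_identical(unname(mA), wantA)
  mB <- growRegion3D(v, c(12, 12, 12), 50, 150)
  expect_equal(sum(mB), 125)
  expect_false(any(mA & mB))
})

test_that("region growing equals a breadth-first flood-fill oracle", {
  set.seed(31)
  vals <- array(sample(c(0, 100), 12^3, replace = TRUE, prob = c(0.55, 0.45)),
                c(12, 12, 12))
  v <- Volume3D(vals)
  seeds <- which(vals == 100, arr.ind = TRUE)
  seed <- seeds[5, ]
  got <- growRegion3D(v, seed, 50, 150)
  want <- floodFillOracle(vals, seed, 50, 150)
  expect_identical(unname(got), want)
})

test_that("region growing is invariant to seed choice within a component", {
  vals <- array(0, c(10, 10, 10))
  vals[2:8, 2:8, 2:8] <- 80
  v <- Volume3D(vals)
  m1 <- growRegion3D(v, c(2, 2, 2), 50, 150)
  m2 <- growRegion3D(v, c(8, 8, 8), 50, 150)
  expect_identical(m1, m2)
})

test_that("seed values outside the band are rejected by value", {
  v <- Volume3D(array(0, c(4, 4, 4)))
  expect_error(growRegion3D(v, c(1, 1, 1), 50, 150), "0.*outside")
})

test_that("detectTubes finds the three phantom tubes with correct geometry", {
  ph <- generatePhantom(defaultPhantomSpec(seed = 3))
  vois <- detectTubes(ph@volume, minVoxels = 200,
                      roles = c("test", "control", "water"))
  expect_length(vois, 3)
  centers <- rbind(c(-20, 0, 0), c(0, 0, 0), c(20, 0, 0))
  for (q in 1:3) {
    expect_lt(max(abs(tubeCentroid(vois[[q]]) - centers[q, ])), 1)
    expect_lt(abs(tubeVoxelCount(vois[[q]]) - pi * 36 * 40) / (pi * 36 * 40),
              0.05)
  }
  expect_equal(vapply(vois, tubeRole, ""), c("test", "control", "water"))
  # masks pairwise disjoint
  expect_false(any(vois[[1]]@mask & vois[[2]]@mask))
  expect_false(any(vois[[2]]@mask & vois[[3]]@mask))
})

test_that("role assignment by seed points overrides ordering", {
  ph <- generatePhantom(defaultPhantomSpec(seed = 3))
  vois <- detectTubes(ph@volume, minVoxels = 200,
                      seeds = list(water = c(20, 0, 0), sample = c(-20, 0, 0)))
  roles <- vapply(vois, tubeRole, "")
  expect_equal(roles[vapply(vois, function(v) tubeCentroid(v)[1], 0) > 10],
               "water")
})

test_that("an all-background volume is rejected", {
  expect_error(detectTubes(Volume3D(array(0, c(8, 8, 8)))), "constant")
})

test_that("the noiseless full chain reproduces the ground-truth labels", {
  ph <- generatePhantom(defaultPhantomSpec(noiseSigma = 0))
  fg <- removeBackground(ph@volume)
  expect_identical(as.logical(fg), as.logical(ph@labels > 0))
  vois <- detectTubes(ph@volume, minVoxels = 200)
  expect_length(vois, 3)
  expect_identical(vois[[1]]@mask, ph@labels == 1)
  expect_identical(vois[[2]]@mask, ph@labels == 2)
  expect_identical(vois[[3]]@mask, ph@labels == 3)
})

test_that("extractVOI crops bbox plus padding and preserves physical coords", {
  ph <- generatePhantom(phantomSpec(
    list(tubeSpec(c(0, 0, 0), 5, 16, signal = 100)),
    gridShape = c(40L, 40L, 40L), noiseSigma = 0))
  voi <- detectTubes(ph@volume, 100)[[1]]
  crop0 <- extractVOI(ph@volume, voi, pad = 0)
  expect_equal(dim(crop0@values), unname(voi@bbox[2, ] - voi@bbox[1, ] + 1L))
  crop4 <- extractVOI(ph@volume, voi, pad = 4)
  expect_equal(dim(crop4@values), dim(crop0@values) + 8L)
  expect_false(attr(crop4, "clipped"))
  # tube centroid sits at the central voxel (within half a voxel)
  ctrIdx <- physicalToVoxel(crop4, tubeCentroid(voi))
  expect_lt(max(abs(ctrIdx - (dim(crop4@values) + 1) / 2)), 0.5 + 1e-9)
  # physical coordinate of a voxel is unchanged by cropping
  lo <- attr(crop4, "cropRange")[1, ]
  expect_equal(as.numeric(voxelToPhysical(crop4, c(1, 1, 1))),
               as.numeric(voxelToPhysical(ph@volume, lo)))
  inside <- voi@bbox[1, ]
  expect_equal(
    as.numeric(voxelToPhysical(ph@volume, inside)),
    as.numeric(voxelToPhysical(crop4, inside - lo + 1)))
})
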