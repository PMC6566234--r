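paperTRs <- c(6000, 4700, 3600, 2800, 2200, 1700, 1300, 1000, 800)

smallT1Spec <- function(noiseSigma = 0, seed = 1L) {
  tubes <- list(
    tubeSpec(c(-6, 0, 0), 4, 16, t1Ms = 800, s0 = 1000, role = "test"),
    tubeSpec(c(6, 0, 0), 4, 16, t1Ms = 1600, s0 = 900, role = "control"))
  phantomSpec(tubes, gridShape = c(24L, 24L, 24L), noiseSigma = noiseSigma,
              seed = seed)
}

test_that("noiseless nine-TR fits recover assigned T1 within 0.1%", {
  ser <- generateTRSeries(smallT1Spec(), paperTRs)
  m <- ser$labels > 0
  t1m <- fitT1Map(ser$series, ser$trMs, mask = m)
  expect_true(all(t1m@fitMask[m]))
  truth <- c(800, 1600)[ser$labels[m]]
  expect_lt(max(abs(t1m@t1[m] - truth) / truth), 0.001)
  expect_lt(max(abs(t1m@s0[m] - c(1000, 900)[ser$labels[m]])), 1)
  expect_lt(max(t1m@rmse[m]), 1e-6)
})

test_that("T1 fitting is scale-invariant (scaling changes s0 only)", {
  ser <- generateTRSeries(smallT1Spec(), paperTRs)
  m <- ser$labels > 0
  a <- fitT1Map(ser$series, ser$trMs, mask = m)
  scaled <- lapply(ser$series, function(v) {
    v@values <- v@values * 2.5
    v
  })
  b <- fitT1Map(scaled, ser$trMs, mask = m)
  expect_equal(b@t1[m], a@t1[m], tolerance = 1e-6)
  expect_equal(b@s0[m], 2.5 * a@s0[m], tolerance = 1e-6)
})

test_that("2% Rician noise keeps the median relative T1 error under 5%", {
  ser <- generateTRSeries(smallT1Spec(noiseSigma = 20, seed = 9), paperTRs)
  labels <- generateTRSeries(smallT1Spec(), paperTRs)$labels
  m <- labels > 0
  expect_gt(sum(m), 1000)   # >= 1000 fitted voxels
  t1m <- fitT1Map(ser$series, ser$trMs, mask = m)
  fit <- t1m@fitMask
  truth <- c(800, 1600)[labels[fit]]
  rel <- abs(t1m@t1[fit] - truth) / truth
  expect_lt(median(rel), 0.05)
})

test_that("T1 error decreases monotonically with SNR", {
  errAt <- function(snr, seed) {
    ser <- generateTRSeries(smallT1Spec(noiseSigma = 1000 / snr,
                                        seed = seed), paperTRs)
    labels <- generateTRSeries(smallT1Spec(), paperTRs)$labels
    m <- labels > 0
    t1m <- fitT1Map(ser$series, ser$trMs, mask = m)
    truth <- c(800, 1600)[labels[t1m@fitMask]]
    median(abs(t1m@t1[t1m@fitMask] - truth) / truth)
  }
  errs <- vapply(c(10, 25, 50, 100), errAt, 0, seed = 13)
  expect_true(all(diff(errs) < 0))
})

test_that("constant or non-recovering signal is flagged, not fitted", {
  d <- c(2, 2, 1)
  mk <- function(x) Volume3D(array(x, d))
  flat <- lapply(c(1, 2, 3), function(q) mk(500))
  t1m <- fitT1Map(flat, c(800, 2000, 6000))
  expect_false(any(t1m@fitMask))
  expect_true(all(t1m@reason == 2L))
  expect_error(fitT1Map(flat, c(800, 800, 800)), "distinct")
})

test_that("relaxivity regression recovers an exact synthetic line", {
  C <- c(0, 0.1, 0.25, 0.5)
  R1 <- 0.4 + 3.75 * C          # rates in s^-1
  fit <- fitRelaxivity(C, 1000 / R1)
  expect_equal(fit@r1, 3.75, tolerance = 1e-10)
  expect_equal(fit@intercept, 0.4, tolerance = 1e-10)
  expect_equal(fit@rSquared, 1, tolerance = 1e-10)
})

test_that("relaxivity equals the closed-form least-squares oracle", {
  set.seed(91)
  C <- runif(8, 0, 1)
  R1 <- 0.5 + 2.29 * C + rnorm(8, 0, 0.05)
  fit <- fitRelaxivity(C, 1000 / R1)
  # closed form: slope = cov(C, R1) / var(C)
  slope <- sum((C - mean(C)) * (R1 - mean(R1))) / sum((C - mean(C))^2)
  expect_equal(fit@r1, slope, tolerance = 1e-10)
  expect_equal(fit@intercept, mean(R1) - slope * mean(C), tolerance = 1e-10)
})

test_that("two points give the exact interpolating slope with r^2 = 1", {
  fit <- fitRelaxivity(c(0.1, 0.4), 1000 / c(1, 2.2))
  expect_equal(fit@r1, (2.2 - 1) / 0.3, tolerance = 1e-10)
  expect_equal(fit@rSquared, 1, tolerance = 1e-12)
})

test_that("noisy relaxivity slope stays within 10% over seeded repeats", {
  worst <- 0
  for (q in 1:100) {
    set.seed(1000 + q)
    C <- seq(0, 0.7, length.out = 8)
    R1 <- 0.4 + 3.75 * C
    R1n <- R1 * (1 + rnorm(8, 0, 0.02))
    fit <- fitRelaxivity(C, 1000 / R1n)
    worst <- max(worst, abs(fit@r1 - 3.75) / 3.75)
  }
  expect_lt(worst, 0.10)
})

test_that("degenerate relaxivity designs are rejected", {
  expect_error(fitRelaxivity(c(0.2, 0.2, 0.2), c(1000, 1100, 1200)),
               "distinct")
  expect_error(fitRelaxivity(c(0, 0.5), c(-1, 1000)), "positive")
})

test_that("T1 enhancement uses mask-mean rates (agent shortens T1)", {
  d <- c(3, 3, 3)
  mk <- function(t1) new("T1Map", t1 = array(t1, d), s0 = array(1000, d),
                         rmse = array(0, d), fitMask = array(TRUE, d),
                         reason = array(0L, d))
  expect_equal(as.numeric(t1Enhancement(mk(1000), mk(2000))), 100)
  expect_equal(as.numeric(t1Enhancement(mk(1500), mk(1500))), 0)
  expect_equal(attr(t1Enhancement(mk(1000), mk(2000)), "mode"), "rate")
  sig <- t1Enhancement(mk(1), mk(1), mode = "signal",
                       testSignalMean = 120, controlSignalMean = 100)
  expect_equal(as.numeric(sig), 20)
  expect_equal(attr(sig, "mode"), "signal")
})

test_that("phantom-assigned T1s propagate through fits to enhancement", {
  ser <- generateTRSeries(smallT1Spec(noiseSigma = 10, seed = 15), paperTRs)
  labels <- generateTRSeries(smallT1Spec(), paperTRs)$labels
  t1m <- fitT1Map(ser$series, ser$trMs, mask = labels > 0)
  testMap <- t1m; testMap@fitMask <- t1m@fitMask & (labels == 1)
  ctlMap <- t1m; ctlMap@fitMask <- t1m@fitMask & (labels == 2)
  enh <- as.numeric(t1Enhancement(testMap, ctlMap))
  want <- ((1000 / 800) - (1000 / 1600)) / (1000 / 1600) * 100   # +100%
  expect_lt(abs(enh - want), 5)
})
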