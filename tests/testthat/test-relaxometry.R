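test_that("noiseless voxel fits invert the forward model exactly", {
  te <- echoTrain()
  sig <- signalModel(100, 100, echoTimes(te))
  r <- fitVoxel(sig, te)
  expect_lt(abs(r$t2star - 100) / 100, 1e-4)
  expect_lt(abs(r$s0 - 100) / 100, 1e-4)
  expect_true(r$fitOk)
  expect_false(r$atBound)
  expect_equal(r$nConverged, 10L)
})

test_that("a non-decaying signal pins at the upper T2* bound and is flagged", {
  r <- fitVoxel(rep(50, 4), echoTrain())
  expect_equal(r$t2star, 800, tolerance = 1e-6)
  expect_true(r$atBound)
})

test_that("the log-linear closed form matches hand-computed values", {
  r <- loglinearFit(c(90, 45), c(10, 110))
  expect_equal(r$t2star, 100 / log(2), tolerance = 1e-10)
  r2 <- loglinearFit(signalModel(100, 150, echoTimes(echoTrain())),
                     echoTrain())
  expect_equal(r2$s0, 100, tolerance = 1e-10)
  expect_equal(r2$t2star, 150, tolerance = 1e-10)
  expect_error(loglinearFit(c(10, 0), c(10, 110)), "positive")
})

test_that("multi-start NLLS agrees with the log-linear oracle on noiseless data", {
  set.seed(42)
  te <- echoTrain()
  for (i in 1:25) {
    s0 <- runif(1, 20, 300); t2 <- runif(1, 25, 500)
    sig <- signalModel(s0, t2, echoTimes(te))
    nls <- fitVoxel(sig, te, voxelIndex = i)
    ll <- loglinearFit(sig, te)
    expect_lt(abs(nls$t2star - ll$t2star) / ll$t2star, 1e-4)
    expect_lt(abs(nls$s0 - ll$s0) / ll$s0, 1e-4)
  }
})

test_that("scale equivariance: k * signal scales S0 and leaves T2* unchanged", {
  te <- echoTrain()
  sig <- signalModel(80, 130, echoTimes(te))
  base <- fitVoxel(sig, te, voxelIndex = 3)
  for (k in c(0.25, 4, 50)) {
    r <- fitVoxel(k * sig, te, voxelIndex = 3)
    expect_equal(r$t2star, base$t2star, tolerance = 1e-6)
    expect_equal(r$s0, k * base$s0, tolerance = 1e-6)
  }
})

test_that("any 3-echo subset of noiseless data yields the same T2*", {
  te4 <- echoTimes(echoTrain())
  sig4 <- signalModel(120, 90, te4)
  # dropping the first echo shrinks the observed maximum below S0/2, so
  # give the S0 box headroom beyond the default 2x multiplier
  cfg <- fitConfig(s0Bounds = c(0.1, 4))
  full <- fitVoxel(sig4, te4, cfg)
  for (drop in 1:4) {
    sub <- fitVoxel(sig4[-drop], te4[-drop], cfg)
    expect_equal(sub$t2star, full$t2star, tolerance = 1e-6)
  }
})

test_that("the reported value is the median over converged starts, robust to poisoned starts", {
  te <- echoTrain()
  sig <- signalModel(100, 150, echoTimes(te))
  starts <- fitVoxelStarts(sig, te, fitConfig(nInit = 10L))
  conv <- starts[starts$converged == 1, ]
  r <- fitVoxel(sig, te)
  expect_equal(r$t2star, median(conv$t2star), tolerance = 1e-12)
  expect_equal(r$s0, median(conv$s0), tolerance = 1e-12)
  # poisoning floor((n-1)/2) starts with a wrong local value leaves the
  # median untouched when the remaining starts agree
  n <- nrow(conv)
  k <- (n - 1) %/% 2
  poisoned <- conv$t2star
  poisoned[seq_len(k)] <- 799
  expect_equal(median(poisoned), median(conv$t2star), tolerance = 1e-9)
})

test_that("map fitting is deterministic and independent of mask shape", {
  ph <- tinyPhantom(noiseSigma = 2, gridShape = c(12, 12, 12))
  cfg <- fitConfig(seed = 7L)
  m1 <- fitMap(ph$series, ph$brainMask, cfg)
  m2 <- fitMap(ph$series, ph$brainMask, cfg)
  expect_identical(t2star(m1), t2star(m2))
  # per-voxel RNG keyed on voxel index: estimates do not depend on which
  # other voxels are in the mask
  sub <- maskArray(ph$brainMask)
  sub[, , 1:6] <- FALSE
  m3 <- fitMap(ph$series, brainMask(sub, voxelSize(ph$brainMask)), cfg)
  expect_equal(t2star(m3)[sub], t2star(m1)[sub], tolerance = 1e-12)
})

test_that("noiseless map recovery is exact to < 0.01 ms and masks/skips behave", {
  ph <- tinyPhantom(noiseSigma = 0)
  map <- fitMap(ph$series, ph$brainMask, fitConfig())
  bm <- maskArray(ph$brainMask)
  expect_lt(max(abs(t2star(map)[bm] - ph$truthT2star[bm])), 0.01)
  expect_true(all(is.na(t2star(map)[!bm])))
  expect_false(any(fitOk(map)[!bm]))
  # signal floor skips dim voxels
  cfg <- fitConfig(minSignal = 1e9)
  map2 <- fitMap(ph$series, ph$brainMask, cfg)
  expect_false(any(fitOk(map2)))
})

test_that("fitting fewer than 3 echoes is a configuration error", {
  ph <- tinyPhantom(gridShape = c(8, 8, 8))
  arr <- seriesData(ph$series)[, , , 1:2]
  ser2 <- multiEchoSeries(arr, echoTrain(c(11.6, 68.4)))
  expect_error(fitMap(ser2, ph$brainMask), "at least 3 echoes")
  expect_error(fitVoxel(c(10, 5), echoTrain(c(11.6, 68.4))),
               "at least 3 echoes")
})

test_that("median T2* under Rician noise stays near truth at moderate sigma", {
  # 400 replicate voxels at S0=100, T2*=150, sigma=2 (SNR ~ 50)
  te <- echoTimes(echoTrain())
  set.seed(14)
  n <- 400
  clean <- signalModel(100, 150, te)
  sig <- matrix(rep(clean, each = n), n, 4)
  noisy <- sqrt((sig + matrix(rnorm(n * 4, 0, 2), n, 4))^2 +
                  matrix(rnorm(n * 4, 0, 2), n, 4)^2)
  est <- vapply(seq_len(n), function(i)
    fitVoxel(noisy[i, ], te, voxelIndex = i)$t2star, 0)
  expect_lt(abs(median(est) - 150), 2)
})
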