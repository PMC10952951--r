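test_that("the forward signal model matches its closed form", {
  expect_equal(signalModel(100, 123, 0), 100)
  expect_equal(signalModel(100, 100, 100), 100 / exp(1), tolerance = 1e-12)
  expect_equal(signalModel(0, 150, 50), 0)
  expect_error(signalModel(100, -5, 50), "> 0")
})

test_that("noiseless phantom voxels follow the forward model exactly and decay strictly", {
  ph <- tinyPhantom(noiseSigma = 0)
  te <- echoTimes(ph$series)
  arr <- seriesData(ph$series)
  idx <- which(maskArray(ph$tissueMask), arr.ind = TRUE)
  for (r in c(1L, nrow(idx) %/% 2L, nrow(idx))) {
    v <- arr[idx[r, 1], idx[r, 2], idx[r, 3], ]
    tr <- ph$truthT2star[idx[r, 1], idx[r, 2], idx[r, 3]]
    s0 <- ph$truthS0[idx[r, 1], idx[r, 2], idx[r, 3]]
    expect_equal(v, signalModel(s0, tr, te), tolerance = 1e-12)
    expect_true(all(diff(v) < 0))   # strictly decreasing across echoes
  }
  # background carries no signal without noise
  expect_true(all(arr[!maskArray(ph$brainMask)] == 0))
})

test_that("CSF is carved out of tissue and has the longer T2*", {
  ph <- tinyPhantom()
  expect_false(any(maskArray(ph$tissueMask) & maskArray(ph$csfMask)))
  expect_true(all(ph$truthT2star[maskArray(ph$csfMask)] >
                    max(ph$truthT2star[maskArray(ph$tissueMask)])))
})

test_that("the same spec and seed reproduce the phantom bit-identically", {
  p1 <- tinyPhantom(noiseSigma = 2, seed = 5L)
  p2 <- tinyPhantom(noiseSigma = 2, seed = 5L)
  expect_identical(seriesData(p1$series), seriesData(p2$series))
  p3 <- tinyPhantom(noiseSigma = 2, seed = 6L)
  expect_false(identical(seriesData(p1$series), seriesData(p3$series)))
})

test_that("observed first-echo mean matches a Monte-Carlo Rician oracle", {
  # oracle: direct simulation of |N(A, sigma^2) + i N(0, sigma^2)|
  sigma <- 2
  ph <- makePhantom(phantomSpec(gridShape = c(40, 40, 40),
                                noiseSigma = sigma), seed = 21L)
  tm <- maskArray(ph$tissueMask)
  expect_gt(sum(tm), 1e4)
  a <- signalModel(100, 160, echoTimes(ph$series)[1])
  set.seed(99)
  nmc <- 2e5
  oracle <- sqrt((a + rnorm(nmc, 0, sigma))^2 + rnorm(nmc, 0, sigma)^2)
  obs <- seriesData(ph$series)[, , , 1][tm]
  se <- sqrt(var(oracle) / nmc + var(obs) / length(obs))
  expect_lt(abs(mean(obs) - mean(oracle)), 3 * se)
})

test_that("zero-signal voxels reach the Rayleigh limit sigma * sqrt(pi/2)", {
  sigma <- 3
  ph <- makePhantom(phantomSpec(gridShape = c(24, 24, 24),
                                noiseSigma = sigma), seed = 31L)
  bg <- !maskArray(ph$brainMask)
  obs <- seriesData(ph$series)[, , , 1][bg]
  se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - sigma * sqrt(pi / 2)), 4 * se)
})

test_that("cohort simulation is deterministic and honours the null case", {
  spec <- cohortSimSpec(nPreterm = 2L, nControl = 2L, groupDelta = 0,
                        betweenSubjectSd = 0, noiseSigma = 0,
                        gridShape = c(10, 10, 10), pretermExtraSkew = 0)
  d1 <- file.path(tempdir(), "cohA"); d2 <- file.path(tempdir(), "cohB")
  s1 <- simulateCohort(spec, d1, seed = 3L)
  s2 <- simulateCohort(spec, d2, seed = 3L)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(readBin(s1$files[[1]]["image"], "raw", 1e6),
                   readBin(s2$files[[1]]["image"], "raw", 1e6))
  # no group effect, no noise: ground-truth T2* is a pure function of GA
  expect_equal(s1$truth$tissue_t2star,
               t2starTrajectory(s1$truth$ga_mri), tolerance = 1e-12)
})

test_that("default cohort sizes match the study design (25 vs 67)", {
  spec <- cohortSimSpec()
  expect_equal(spec@nPreterm, 25L)
  expect_equal(spec@nControl, 67L)
  expect_equal(spec@gaRange, c(19.3, 31.7))
})

test_that("a trajectory that goes non-positive raises a parameter error", {
  spec <- cohortSimSpec(nPreterm = 1L, nControl = 1L,
                        trajectory = c(0, 0, -5), betweenSubjectSd = 0)
  expect_error(simulateSummaryTable(spec, seed = 1L), "non-positive")
})

test_that("summary-level simulation reproduces the trajectory + offset structure", {
  spec <- cohortSimSpec(betweenSubjectSd = 0, pretermExtraSkew = 0)
  tab <- simulateSummaryTable(spec, seed = 8L)
  expect_equal(nrow(tab), 92L)
  expected <- t2starTrajectory(tab$ga_mri) +
    ifelse(tab$group == "preterm", -8, 0)
  expect_equal(tab$mean_t2star, expected, tolerance = 1e-12)
})
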