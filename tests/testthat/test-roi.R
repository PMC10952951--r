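test_that("erosion: identity at margin 0, cube shrinks as forced by the element", {
  g <- array(FALSE, c(9, 9, 9)); g[3:7, 3:7, 3:7] <- TRUE
  m <- brainMask(g)
  expect_identical(maskArray(erodeMask(m, 0L)), g)
  e1 <- erodeMask(m, 1L)
  expect_equal(nVoxels(e1), 27L)                       # 5^3 cube -> 3^3
  expect_true(all(maskArray(e1) <= g))                 # subset
  expect_error(erodeMask(m, 5L), "margin 5")           # emptied
})

test_that("erosion matches the brute-force neighbourhood oracle on a random blob", {
  set.seed(77)
  g <- array(runif(12^3) < 0.6, c(12, 12, 12))
  expect_identical(maskArray(erodeMask(brainMask(g), 1L)), bruteErode(g))
})

test_that("CSF thresholding removes exactly the CSF compartment of a phantom", {
  ph <- tinyPhantom()                                  # noiseless
  map <- fitMap(ph$series, ph$brainMask, fitConfig())
  kept <- applyCsfThreshold(map, ph$brainMask, cutoff = 250)
  expect_equal(nVoxels(ph$brainMask) - nVoxels(kept), nVoxels(ph$csfMask))
  expect_identical(maskArray(kept), maskArray(ph$tissueMask))
  # all tissue below cutoff -> unchanged; cutoff below min -> error
  expect_identical(maskArray(applyCsfThreshold(map, ph$tissueMask, 250)),
                   maskArray(ph$tissueMask))
  expect_error(applyCsfThreshold(map, ph$brainMask, cutoff = 10),
               "no voxels")
})

test_that("skewness matches the adjusted Fisher-Pearson closed form", {
  expect_equal(sampleSkewness(c(1, 1, 1, 5)), 2.0, tolerance = 1e-12)
  expect_equal(sampleSkewness(c(1, 2, 3, 4, 5)), 0, tolerance = 1e-12)
  expect_equal(sampleSkewness(c(1, 1, 1, 5), type = "g1"),
               6 / 3^1.5, tolerance = 1e-12)
  expect_warning(sk <- sampleSkewness(rep(3, 10)), "zero variance")
  expect_true(is.na(sk))
})

test_that("low-value subpopulations drive skewness negative, high-value positive", {
  base <- rep(c(140, 150, 160), each = 200)            # symmetric
  expect_equal(sampleSkewness(base), 0, tolerance = 1e-12)
  expect_lt(sampleSkewness(c(base, rep(90, 60))), 0)
  expect_gt(sampleSkewness(c(base, rep(210, 60))), 0)
})

test_that("ROI summary reports mean, volume and exclusions correctly", {
  ph <- tinyPhantom()
  map <- fitMap(ph$series, ph$brainMask, fitConfig())
  suppressWarnings(   # noiseless constant tissue: skewness undefined
    s <- summarizeROI(map, ph$tissueMask, subjectId = "p1", gaMri = 24))
  expect_equal(s$mean_t2star, 160, tolerance = 1e-6)
  expect_equal(s$volume, nVoxels(ph$tissueMask) * 27 / 1000)
  expect_equal(s$n_voxels, nVoxels(ph$tissueMask))
  expect_equal(s$n_excluded_fit, 0L)
  expect_error(summarizeROI(map, brainMask(array(FALSE, dim(t2star(map)))),
                            "x"), "empty")
})

test_that("constant 150 ms over 1000 voxels: mean 150, volume 27 mL, skewness missing", {
  d <- c(10, 10, 10)
  t2 <- array(150, d)
  map <- new("T2StarMap", t2star = t2, s0 = array(100, d),
             fitOk = array(TRUE, d), residualRms = array(0, d),
             nConverged = array(10L, d), atBound = array(FALSE, d),
             voxelSize = c(3, 3, 3), affine = diag(4), provenance = list())
  suppressWarnings(s <- summarizeROI(map, brainMask(array(TRUE, d))))
  expect_equal(s$mean_t2star, 150)
  expect_equal(s$volume, 27.0)
  expect_true(is.na(s$skewness))
})

test_that("erode-then-threshold is nested within every intermediate mask", {
  ph <- tinyPhantom(noiseSigma = 1, gridShape = c(14, 14, 14))
  map <- fitMap(ph$series, ph$brainMask, fitConfig())
  eroded <- erodeMask(ph$brainMask, 1L)
  final <- applyCsfThreshold(map, eroded, 250)
  expect_true(all(maskArray(eroded) <= maskArray(ph$brainMask)))
  expect_true(all(maskArray(final) <= maskArray(eroded)))
})

test_that("volume is additive over disjoint masks and mean is mask-shape invariant", {
  d <- c(8, 8, 8)
  t2 <- array(rep(c(100, 200), length.out = prod(d)), d)
  map <- new("T2StarMap", t2star = t2, s0 = array(1, d),
             fitOk = array(TRUE, d), residualRms = array(0, d),
             nConverged = array(1L, d), atBound = array(FALSE, d),
             voxelSize = c(3, 3, 3), affine = diag(4), provenance = list())
  g1 <- array(FALSE, d); g1[1:4, , ] <- TRUE
  g2 <- array(FALSE, d); g2[5:8, , ] <- TRUE
  s1 <- summarizeROI(map, brainMask(g1))
  s2 <- summarizeROI(map, brainMask(g2))
  sU <- summarizeROI(map, brainMask(g1 | g2))
  expect_equal(s1$volume + s2$volume, sU$volume)
  # constant map: mean equals the constant whatever the mask shape
  mapC <- new("T2StarMap", t2star = array(150, d), s0 = array(1, d),
              fitOk = array(TRUE, d), residualRms = array(0, d),
              nConverged = array(1L, d), atBound = array(FALSE, d),
              voxelSize = c(3, 3, 3), affine = diag(4), provenance = list())
  set.seed(5)
  gR <- array(runif(prod(d)) < 0.4, d)
  suppressWarnings({
    expect_equal(summarizeROI(mapC, brainMask(gR))$mean_t2star, 150)
    expect_equal(summarizeROI(mapC, brainMask(g1))$mean_t2star, 150)
  })
})
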