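test_that("8-bit conversion rescales, rounds half up, and degenerates to zero", {
  expect_identical(to8bit(matrix(c(0, 1000), 1))[1, ], c(0L, 255L))
  # exact midrange rounds up to 128
  x <- matrix(c(0, 510, 255), 1)
  expect_identical(to8bit(x)[1, 2:3], c(255L, 128L))
  ident <- matrix(0:255, 16)
  expect_identical(to8bit(ident), ident)
  expect_true(all(to8bit(matrix(7, 4, 4)) == 0L))
  expect_error(to8bit(matrix(-1, 2, 2)), "non-negative")
})

test_that("default threshold is the intermeans fixed point", {
  x <- matrix(c(rep(20L, 500), rep(200L, 500)), 50)
  t <- defaultThreshold(x)
  expect_lte(abs(t - 110L), 2L)
  expect_identical(t, intermeansOracle(as.integer(x)))

  # noisy bimodal histograms agree with the exhaustive oracle
  for (s in 1:10) {
    set.seed(s)
    v <- as.integer(pmin(255, pmax(0, round(c(rnorm(400, 30, 8),
                                              rnorm(400, 190, 15))))))
    expect_identical(defaultThreshold(matrix(v, 40)), intermeansOracle(v))
  }

  # uniform image: threshold at the single value, zero signal pixels
  u <- matrix(90L, 10, 10)
  expect_identical(defaultThreshold(u), 90L)
  expect_identical(sum(u > defaultThreshold(u)), 0L)

  # shifting all pixels by a constant shifts the threshold by it
  for (s in 1:5) {
    set.seed(s)
    v <- as.integer(round(c(runif(300, 0, 80), runif(300, 120, 200))))
    t0 <- defaultThreshold(matrix(v, 30))
    t1 <- defaultThreshold(matrix(v + 30L, 30))
    expect_lte(abs(t1 - (t0 + 30L)), 1L)
  }

  expect_error(defaultThreshold(matrix(integer(), 0, 0)), "empty")
})

test_that("ROI intensity sums strictly-above-threshold pixels", {
  x <- matrix(0L, 10, 10)
  roi <- matrix(FALSE, 10, 10)
  roi[1, 1:10] <- TRUE
  x[1, 1:10] <- 100L
  expect_equal(roiIntensity(x, roi, 50), 1000)
  expect_equal(roiIntensity(x, roi, 100), 0)  # strict inequality
  expect_error(roiIntensity(x, matrix(FALSE, 10, 10), 0), "empty ROI")

  for (s in 1:100) {
    set.seed(s)
    img <- matrix(sample(0:255, 144, replace = TRUE), 12)
    roi <- matrix(runif(144) < 0.4, 12)
    if (!any(roi)) next
    thr <- sample(0:255, 1)
    oracle <- sum(img[roi & img > thr])
    expect_equal(roiIntensity(img, roi, thr), oracle)
  }
})

test_that("F and FC follow their defining arithmetic and error on zeros", {
  expect_equal(relativeIntensity(calibrationReads(10, 10, 7, 7)), 1)
  expect_equal(relativeIntensity(calibrationReads(100, 42, 50, 25)), 0.84)
  expect_error(relativeIntensity(calibrationReads(0, 1, 1, 1)), "undefined")
  expect_error(calibrationReads(-1, 1, 1, 1))

  expect_equal(enrichment(enrichmentReads(5, 5, 2, 2)), 1)
  expect_equal(enrichment(enrichmentReads(300, 100, 2, 2)), 3)
  expect_error(enrichment(enrichmentReads(1, 0, 1, 1)), "undefined")
})

test_that("F and FC are scale-free and cancel shared regional factors", {
  for (s in 1:20) {
    set.seed(s)
    r <- runif(4, 1, 100)
    f0 <- relativeIntensity(calibrationReads(r[1], r[2], r[3], r[4]))
    a <- runif(1, 0.01, 10)
    # shared factor on the test region's two channels cancels
    expect_equal(relativeIntensity(
      calibrationReads(r[1], a * r[2], r[3], a * r[4])), f0)
    # global rescale of all four reads changes nothing
    expect_equal(relativeIntensity(
      calibrationReads(a * r[1], a * r[2], a * r[3], a * r[4])), f0)
    fc0 <- enrichment(enrichmentReads(r[1], r[2], r[3], r[4]))
    expect_equal(enrichment(enrichmentReads(a * r[1], a * r[2],
                                            a * r[3], a * r[4])), fc0)
  }
})

test_that("the twin phantom recovers the density ratio under attenuation", {
  for (ratio in c(0.5, 0.84)) {
    st <- fAttenuationStudy(ratio = ratio, coef = 0.2)
    expect_equal(st$F, ratio, tolerance = 1e-7)
    expect_lt(st$rawRatio, 0.5 * ratio)  # raw reads are badly attenuated
  }
})

test_that("measured F between twin cells is 1 and tracks density ratios", {
  f1 <- fMeasurementStudy(nSeeds = 4L, rel = 1, seed = 3L, imageSize = 256L)
  expect_equal(mean(f1), 1, tolerance = 0.05)
  f084 <- fMeasurementStudy(nSeeds = 12L, rel = 0.84, seed = 3L,
                            imageSize = 256L)
  expect_equal(mean(f084), 0.84, tolerance = 0.05)
})

test_that("FC recovers the membrane amplification from rendered veins", {
  fc <- fcRecoveryStudy(ks = c(1, 3), nSeeds = 6L, seed = 5L)
  expect_equal(fc$medianFC[fc$k == 1], 1, tolerance = 0.1)
  expect_equal(fc$medianFC[fc$k == 3], 3, tolerance = 0.3)
})

test_that("measureCellPair validates its inputs", {
  vt <- generateVein(veinConfig(imageSize = 192L, seed = 2L))
  map <- vt$truth@cellMap
  notPP <- vt$truth@cells$label[vt$truth@cells$type == "SE"][1]
  pp <- vt$truth@cells$label[vt$truth@cells$type == "PP"]
  expect_error(measureCellPair(vt$image, map, pp[1], notPP), "PP-type")
})
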