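test_that("percentages round half away from zero", {
  expect_identical(percentage(200, 339), 59L)
  expect_identical(percentage(139, 339), 41L)
  expect_identical(percentage(0, 10), 0L)
  expect_identical(percentage(1, 200), 1L)   # 0.5% rounds away from zero
  expect_identical(percentage(3, 200), 2L)   # 1.5% likewise
  expect_error(percentage(1, 0), "positive")
  expect_error(percentage(5, 3))
})

test_that("pooled t matches the closed form and handles degeneracy", {
  r <- twoSampleT(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  expect_equal(r$t, -1)
  expect_equal(r$df, 8)

  same <- twoSampleT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_warning(d <- twoSampleT(c(2, 2, 2), c(2, 2, 2)), "zero variance")
  expect_equal(d$p, 1)

  for (s in 1:20) {
    set.seed(s)
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1), 0.5)
    got <- twoSampleT(x, y)
    want <- pooledTOracle(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-12)
    expect_equal(got$df, want$df)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("type-I error of the pooled t is calibrated", {
  r <- tTestCalibration(nReps = 2000L, n = 10L, seed = 4L)
  expect_lt(abs(r$rate - 0.05), 0.02)
})

test_that("correlation check reports r and errors on degenerate input", {
  expect_equal(correlationCheck(1:5, 2 * (1:5) + 3)$r, 1)
  expect_equal(correlationCheck(1:5, -(1:5))$r, -1)
  expect_error(correlationCheck(rep(2, 5), 1:5), "constant")
  expect_error(correlationCheck(1:2, 1:2), "3")
})

test_that("independent counts and areas rarely show spurious correlation", {
  hits <- 0L
  for (s in 1:60) {
    set.seed(s)
    n <- sample(1:4, 40, replace = TRUE)
    area <- runif(40, 100, 600)
    if (correlationCheck(n, area)$p > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 54L)  # >= 90% of null cohorts
})

test_that("vein summaries tally cells, PP TCs and abutting neighbours", {
  vt <- generateVein(veinConfig(imageSize = 256L, seed = 6L))
  meas <- suppressWarnings(measureVein(vt$image, vt$truth@cellMap))
  vs <- summarizeVein(vt$truth@cellMap, meas$cells, meas$interfaces)
  expect_equal(unname(vs$counts), c(3L, 4L, 5L, 2L), ignore_attr = TRUE)
  # default config: both PP cells carry ingrowths -> both are PP TCs
  expect_identical(vs$nPpTc, 2L)
  expect_equal(vs$veinArea, veinSize(vt$truth@cellMap))

  # brute-force recount of CC/SE abutters over several seeds
  for (s in 1:5) {
    vt <- generateVein(veinConfig(imageSize = 256L, seed = 100L + s))
    meas <- suppressWarnings(measureVein(vt$image, vt$truth@cellMap))
    vs <- summarizeVein(vt$truth@cellMap, meas$cells, meas$interfaces)
    it <- meas$interfaces
    for (j in seq_len(nrow(vs$abutting))) {
      p <- vs$abutting$label[j]
      mine <- it[it$cellA == p | it$cellB == p, ]
      pt <- ifelse(mine$cellA == p, mine$typeB, mine$typeA)
      expect_identical(vs$abutting$nCC[j], sum(pt == "CC"))
      expect_identical(vs$abutting$nSE[j], sum(pt == "SE"))
      expect_identical(vs$abutting$nCCIngrowth[j],
                       sum(pt == "CC" & !is.na(mine$coverage) & mine$coverage > 0))
    }
  }
})

test_that("cohort summaries aggregate and stay valid when empty", {
  empty <- cohortSummary(list())
  expect_identical(empty$nVeins, 0L)
  expect_true(is.na(empty$pctAbaxialPpTc))

  sums <- lapply(1:4, function(s) {
    vt <- generateVein(veinConfig(imageSize = 256L, seed = 200L + s))
    meas <- suppressWarnings(measureVein(vt$image, vt$truth@cellMap))
    summarizeVein(vt$truth@cellMap, meas$cells, meas$interfaces)
  })
  co <- cohortSummary(sums)
  expect_identical(co$nVeins, 4L)
  expect_equal(unname(co$meanCounts), c(3, 4, 5, 2), ignore_attr = TRUE)
  expect_identical(co$pctAbaxialPpTc, 100L)  # default veins: abaxial PP TCs
  expect_true(co$fracCcAbuttingIngrowth >= 0 &&
                co$fracCcAbuttingIngrowth <= 1)
})

test_that("cohort position percentages stay inside the exact binomial CI", {
  cp <- cohortPositionStudy(nCohorts = 6L, nVeins = 50L, seed = 2L)
  expect_gte(cp$covered, 5L)
  expect_true(all(cp$pctAbaxial > 30 & cp$pctAbaxial < 90))
})
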