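test_that("thickness profile reads a uniform wall and degenerate faces", {
  # straight interface with a uniform 3-px wall on the measured side
  lab <- matrix(rep(1:2, each = 80), 16, 10)
  cm <- cellMap(lab, 0.2, data.frame(label = 1:2, type = c("PP", "SE")))
  ii <- extractInterface(cm, 1, 2)
  mask <- matrix(FALSE, 16, 10)
  mask[, 3:5] <- TRUE  # 3 px of wall inward from the boundary on cell 1's side
  pr <- thicknessProfile(mask, ii, side = 1L)
  expect_true(all(abs(pr$thicknessUm - 0.6) <= 0.1))

  # zero-width face: no wall at all
  pr0 <- thicknessProfile(matrix(FALSE, 16, 10), ii, side = 1L)
  expect_true(all(pr0$thicknessUm == 0))
})

test_that("k-fold thickening is recovered over the covered arc", {
  ph <- stripPhantom(coverage = 0.5, k = 3)
  mask <- to8bit(ph$wall) > defaultThreshold(to8bit(ph$wall))
  pr <- thicknessProfile(mask, ph$interface, side = 1L, map = ph$map)
  det <- detectIngrowth(pr, baseline = 0.6)
  n <- nrow(ph$interface@faces)
  expect_lte(abs(sum(det) - round(0.5 * n)), 1)
  covered <- pr$thicknessUm[det]
  expect_true(all(covered / 0.6 > 1.9))
})

test_that("detection despeckles and needs a positive baseline", {
  prof <- structure(list(thicknessUm = rep(0.6, 20), baselineUm = 0.6,
                         pixelSize = 0.2), class = "ThicknessProfile")
  expect_true(!any(detectIngrowth(prof)))

  spiky <- prof
  spiky$thicknessUm[c(9, 14)] <- 1.8  # isolated single faces
  expect_true(!any(detectIngrowth(spiky)))

  zero <- prof; zero$baselineUm <- 0
  expect_error(detectIngrowth(zero), "baseline")
})

test_that("coverage fraction is covered length over total length", {
  lab <- matrix(rep(1:2, each = 100), 10, 20)
  cm <- cellMap(lab, 0.2, data.frame(label = 1:2, type = c("PP", "SE")))
  ii <- extractInterface(cm, 1, 2)  # 10 faces
  expect_equal(coverageFraction(setIngrowthMask(ii, rep(FALSE, 10))), 0)
  expect_equal(coverageFraction(setIngrowthMask(ii, rep(TRUE, 10))), 1)
  mask <- rep(FALSE, 10); mask[1:7] <- TRUE
  i7 <- setIngrowthMask(ii, mask)
  expect_equal(coverageFraction(i7), 0.7)
  expect_equal(i7@coveredLengthUm, 1.4)
})

test_that("class assignment follows the five-class progression", {
  expect_identical(assignClass(0, c(0, 0)), "I")
  expect_identical(assignClass(0.5, c(0, 0)), "II")
  expect_identical(assignClass(1, 0.05), "III")
  expect_identical(assignClass(1, 0.4), "IV")
  expect_identical(assignClass(1, c(1, 0.3)), "V")
  # thresholds are inclusive as stated
  expect_identical(assignClass(0.95, 0.2), "III")
  expect_identical(assignClass(1, numeric()), "III")
  expect_warning(out <- assignClass(0, 0.3), "progression")
  expect_identical(out, "II")
})

test_that("class is monotone in SE coverage at fixed CC coverage", {
  for (s in 1:25) {
    set.seed(s)
    cc <- runif(2)
    covs <- sort(runif(6))
    idx <- vapply(covs, function(cse)
      match(suppressWarnings(assignClass(cse, cc)), c("I", "II", "III", "IV", "V")),
      integer(1))
    expect_true(all(diff(idx) >= 0))
  }
})

test_that("cell and vein scores map classes to 0..4 and sum over PP cells", {
  expect_identical(scoreCell("I"), 0L)
  expect_identical(scoreCell("V"), 4L)
  expect_identical(scoreVein(c("V", "V")), 8L)
  expect_identical(scoreVein(character()), 0L)
  expect_error(scoreCell("VI"), "class")
})

test_that("coverage recovery is within one face on straight boundaries", {
  for (cov in c(0, 0.25, 0.4, 0.6, 0.75, 0.9, 1)) {
    ph <- stripPhantom(coverage = cov, k = 3)
    mask <- to8bit(ph$wall) > defaultThreshold(to8bit(ph$wall))
    pr <- thicknessProfile(mask, ph$interface, side = 1L, map = ph$map)
    det <- detectIngrowth(pr, baseline = 0.6)
    n <- nrow(ph$interface@faces)
    expect_lte(abs(sum(det) - round(cov * n)), 1)
  }
})

test_that("coverage recovery on full veins respects the junction bounds", {
  cr <- suppressWarnings(
    coverageRecoveryStudy(nConfigs = 12L, seed = 7L, imageSize = 512L))
  # most interfaces recover to within a few faces; junction-zone coupling
  # between adjacent arcs can extend a run by up to about the hysteresis
  # margin on either end
  expect_gte(mean(cr$errFaces <= 3 + 1e-9), 0.85)
  expect_true(all(cr$errFaces <= 12 + 1e-9))
  expect_gt(cor(cr$configured, cr$measured), 0.95)
})

test_that("five class presets are recovered by the full pipeline", {
  for (cl in c("I", "III", "V")) {
    vt <- generateVein(classPreset(cl, imageSize = 512L, seed = 21L,
                                   noiseSd = 0))
    m <- suppressWarnings(measureVein(vt$image, vt$truth@cellMap))
    expect_identical(m$cells$class, rep(cl, 2L))
  }
})

test_that("no PP cell without an SE neighbour is scored class II or higher", {
  # ingrowths only on SE-facing interfaces; the adaxial PP has no SE contact
  for (s in 1:6) {
    cfg <- veinConfig(ppPositions = c("abaxial", "adaxial"),
                      ingrowth = list(ingrowthSpec(se = 1, cc = 0, k = 3),
                                      ingrowthSpec(se = 0, cc = 0, k = 1)),
                      imageSize = 256L, seed = s)
    vt <- generateVein(cfg)
    m <- suppressWarnings(measureVein(vt$image, vt$truth@cellMap))
    g <- buildAdjacency(vt$truth@cellMap)
    ty <- cellTypes(vt$truth@cellMap)
    for (j in seq_len(nrow(m$cells))) {
      nb <- igraph::neighbors(g, as.character(m$cells$label[j]))$name
      if (!any(ty[nb] == "SE"))
        expect_identical(m$cells$class[j], "I")
    }
  }
})
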