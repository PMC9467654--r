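test_that("generation is deterministic and honours configured counts", {
  cfg <- veinConfig(nCells = c(XY = 3L, SE = 4L, CC = 5L, PP = 2L, BS = 6L),
                    imageSize = 192L, seed = 11L)
  a <- generateVein(cfg)
  b <- generateVein(cfg)
  expect_identical(a$image@pixels, b$image@pixels)
  expect_identical(cellLabels(a$truth@cellMap), cellLabels(b$truth@cellMap))

  counts <- table(a$truth@cells$type)
  expect_equal(unname(counts[c("PP", "SE", "CC", "XY", "BS")]),
               c(2L, 4L, 5L, 3L, 6L), ignore_attr = TRUE)
})

test_that("invalid or infeasible configurations are rejected", {
  expect_error(veinConfig(ingrowth = rep(list(ingrowthSpec(se = 1.5)), 2L)),
               "coverage")
  expect_error(veinConfig(ingrowth = rep(list(ingrowthSpec(se = 1, k = 0.5)), 2L)),
               "k")
  expect_error(veinConfig(nCells = c(XY = 3L, SE = 0L, CC = 5L, PP = 2L, BS = 8L)),
               "SE")
  crowded <- veinConfig(nCells = c(XY = 10L, SE = 20L, CC = 30L, PP = 2L,
                                   BS = 30L),
                        ingrowth = rep(list(ingrowthSpec(0, 0, 1)), 2L),
                        imageSize = 48L)
  expect_error(generateVein(crowded), "geometry")
})

test_that("zero coverage leaves the wall at primary thickness everywhere", {
  cfg <- veinConfig(ingrowth = rep(list(ingrowthSpec(0, 0, 1)), 2L),
                    noiseSd = 0, imageSize = 192L, seed = 5L)
  vt <- generateVein(cfg)
  lab <- cellLabels(vt$truth@cellMap)
  wall <- channel(vt$image, "wall") > 0
  # no pixel deeper than the primary half-width is wall
  f <- veinTC:::.allFaces(lab)
  B <- matrix(FALSE, nrow(lab), ncol(lab))
  B[cbind(f$r1, f$c1)] <- TRUE; B[cbind(f$r2, f$c2)] <- TRUE
  B[c(1, nrow(lab)), ] <- B[c(1, nrow(lab)), ] | lab[c(1, nrow(lab)), ] > 0
  B[, c(1, ncol(lab))] <- B[, c(1, ncol(lab))] | lab[, c(1, ncol(lab))] > 0
  dtB <- as.matrix(EBImage::distmap(1 - B))
  h <- cfg@wallHalfWidth / cfg@pixelSize
  expect_true(all(dtB[wall] <= h + 1e-9))
  expect_true(all(vt$truth@interfaces$coverage == 0))
})

test_that("rendered coverage matches the configured fraction within one face", {
  for (s in 1:40) {
    set.seed(s)
    covs <- c(runif(1, 0.2, 1), runif(1, 0.2, 1))
    cfg <- veinConfig(
      ingrowth = list(ingrowthSpec(se = covs[1], cc = covs[2], k = 3),
                      ingrowthSpec(se = 0, cc = 0, k = 1)),
      imageSize = 128L, seed = s)
    geo <- generateCellMap(cfg)
    res <- veinTC:::.resolveArcs(geo$map, geo$cells, cfg)
    tr <- res$interfaces
    conf <- tr[tr$coverage > 0, , drop = FALSE]
    expect_true(all(abs(conf$coverage * conf$nFaces -
                          round(conf$coverage * conf$nFaces)) < 1 + 1e-9))
    p1 <- geo$cells$label[!is.na(geo$cells$ppIndex) & geo$cells$ppIndex == 1]
    se <- tr[(tr$cellA == p1 | tr$cellB == p1) &
               (tr$typeA == "SE" | tr$typeB == "SE"), ]
    expect_true(all(abs(se$coverage - covs[1]) * se$nFaces <= 1 + 1e-9))
  }
})

test_that("membrane amplification scales the marker sum by k", {
  # coverage 1.0 on the SE interface at k = 3: per-pixel marker along that
  # interface sums to ~3x an equal length of unamplified membrane
  ph <- stripPhantom(coverage = 1, k = 3)
  amp <- ph$marker[ph$marker > 0]
  expect_equal(max(amp) / min(amp), 3, tolerance = 0.02)

  vt <- generateVein(veinConfig(noiseSd = 0, imageSize = 256L, seed = 2L))
  mk <- channel(vt$image, "marker")
  vals <- sort(unique(round(mk[mk > 0], 6)))
  base <- min(vals)
  expect_equal(max(vals) / base, 3, tolerance = 0.02)
})

test_that("attenuation preserves channel ratios and follows the closed form", {
  vt <- generateVein(veinConfig(noiseSd = 0, imageSize = 192L, seed = 3L))
  img0 <- vt$image

  expect_identical(applyAttenuation(img0, coef = 0)@pixels, img0@pixels)

  img1 <- applyAttenuation(img0, coef = 0.2)
  w0 <- channel(img0, "wall"); m0 <- channel(img0, "marker")
  w1 <- channel(img1, "wall"); m1 <- channel(img1, "marker")
  both <- w0 > 0 & m0 > 0
  expect_equal(w1[both] / m1[both], w0[both] / m0[both], tolerance = 1e-12)

  # per-cell marker/wall ratio invariant to 6 significant digits when each
  # cell is dimmed by its (shared, region-constant) attenuation factor
  lab <- cellLabels(vt$truth@cellMap)
  cen <- vt$truth@cells
  px <- vt$image@pixels
  for (i in seq_len(nrow(cen))) {
    fac <- exp(-0.2 * (nrow(lab) - cen$row[i]) * 0.2)
    px[, , 1][lab == cen$label[i]] <- px[, , 1][lab == cen$label[i]] * fac
    px[, , 2][lab == cen$label[i]] <- px[, , 2][lab == cen$label[i]] * fac
  }
  for (p in cen$label[cen$type == "PP"]) {
    r0 <- sum(m0[lab == p]) / sum(w0[lab == p])
    r1 <- sum(px[, , 2][lab == p]) / sum(px[, , 1][lab == p])
    expect_equal(r1, r0, tolerance = 1e-6)
  }

  # two identical cells 10 um apart under coef = ln(2)/10: deeper is half
  ph <- twinPhantom(ratio = 1, sepRows = 50L)  # 50 px = 10 um at 0.2 um/px
  att <- applyAttenuation(ph$image, coef = log(2) / 10)
  mk <- channel(att, "marker")
  lab2 <- cellLabels(ph$map)
  expect_equal(mean(mk[lab2 == ph$deep & mk > 0]) /
                 mean(mk[lab2 == ph$shallow & mk > 0]),
               0.5, tolerance = 0.01)

  oneCh <- VeinImage(array(1, c(8, 8, 1)), 0.2)
  expect_error(applyAttenuation(oneCh, coef = 0.1), "two-channel")
})

test_that("attenuation maps are valid multiplicative factors", {
  vt <- generateVein(veinConfig(attenuationCoef = 0.3, imageSize = 128L,
                                seed = 9L))
  a <- vt$truth@attenuationMap
  expect_true(all(a > 0 & a <= 1))
  expect_equal(a[nrow(a), 1], 1)  # abaxial edge, zero depth
})
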