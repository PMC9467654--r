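test_that("adjacency follows 4-connectivity on constructed maps", {
  cm <- bandMap(c("PP", "SE", "CC"))
  g <- buildAdjacency(cm)
  el <- igraph::as_edgelist(g)
  edges <- sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  expect_identical(edges, c("1 2", "2 3"))

  # diagonal touch is not adjacency
  lab <- matrix(0L, 2, 2)
  lab[1, 1] <- 1L; lab[2, 2] <- 2L
  cm2 <- cellMap(lab, 0.2, data.frame(label = 1:2, type = c("PP", "SE")))
  expect_equal(igraph::ecount(buildAdjacency(cm2)), 0)

  empty <- cellMap(matrix(0L, 4, 4), 0.2,
                   data.frame(label = integer(), type = character()))
  expect_error(buildAdjacency(empty), "empty")
})

test_that("adjacency and face counts match exhaustive oracles on random maps", {
  for (s in 1:50) {
    cm <- randomMap(s)
    lab <- cellLabels(cm)
    g <- buildAdjacency(cm)
    el <- igraph::as_edgelist(g)
    edges <- sort(paste(pmin(as.integer(el[, 1]), as.integer(el[, 2])),
                        pmax(as.integer(el[, 1]), as.integer(el[, 2]))))
    expect_identical(edges, adjacencyOracle(lab))
    # spot-check two interfaces per map against the face-count oracle
    if (nrow(el)) {
      for (k in seq_len(min(2L, nrow(el)))) {
        a <- as.integer(el[k, 1]); b <- as.integer(el[k, 2])
        ii <- extractInterface(cm, a, b)
        expect_equal(nrow(ii@faces), faceCountOracle(lab, a, b))
        expect_equal(ii@lengthUm, faceCountOracle(lab, a, b) * pixelSize(cm))
      }
    }
  }
})

test_that("interface extraction is canonical and lengths are face counts", {
  lab <- matrix(rep(1:2, each = 50), 10, 10)
  cm <- cellMap(lab, 0.2, data.frame(label = 1:2, type = c("PP", "SE")))
  i12 <- extractInterface(cm, 1, 2)
  i21 <- extractInterface(cm, 2, 1)
  expect_equal(i12@lengthUm, 2.0)  # 10 faces x 0.2 um
  expect_identical(i12@faces, i21@faces)
  expect_identical(i12@cellA, i21@cellA)
  expect_error(extractInterface(cm, 1, 1), "not adjacent")

  # L-shaped boundary of 7 faces at 0.5 um/px
  lab2 <- matrix(1L, 5, 5)
  lab2[3:5, 1:2] <- 2L
  lab2[4:5, 3] <- 2L
  cm2 <- cellMap(lab2, 0.5, data.frame(label = 1:2, type = c("PP", "CC")))
  n <- faceCountOracle(lab2, 1, 2)
  ii <- extractInterface(cm2, 1, 2)
  expect_equal(nrow(ii@faces), n)
  expect_equal(ii@lengthUm, n * 0.5)
})

test_that("interface lengths of a cell sum to its internal perimeter", {
  # full partition, no background contact for the middle cell
  cm <- bandMap(c("PP", "SE", "CC"), bandHeight = 5L, width = 9L)
  lab <- cellLabels(cm)
  g <- buildAdjacency(cm)
  nb <- as.integer(igraph::neighbors(g, "2")$name)
  total <- sum(vapply(nb, function(b)
    extractInterface(cm, 2L, b)@lengthUm, numeric(1)))
  # internal 4-connected perimeter of cell 2 (faces to other cells only)
  perim <- sum(vapply(nb, function(b) faceCountOracle(lab, 2L, b),
                      integer(1))) * pixelSize(cm)
  expect_equal(total, perim)
})

test_that("abaxial axis points from xylem towards phloem", {
  cm <- bandMap(c("XY", "CC", "SE"))
  ax <- abaxialAxis(cm)
  expect_equal(ax, c(1, 0), tolerance = 1e-6)

  noPhloem <- bandMap(c("XY", "BS"))
  expect_error(abaxialAxis(noPhloem), "axis")
})

test_that("inferred axis matches the generator's abaxial direction", {
  angles <- vapply(1:100, function(s) {
    set.seed(s)
    geo <- generateCellMap(veinConfig(
      ingrowth = rep(list(ingrowthSpec(0, 0, 1)), 2L), imageSize = 96L,
      seed = s))
    ax <- abaxialAxis(geo$map)
    acos(pmin(1, sum(ax * c(1, 0)))) * 180 / pi
  }, numeric(1))
  expect_lt(max(angles), 15)
})

test_that("position rule: adjacency, one-cell separation, and middle", {
  # 1 hop to the abaxial BS
  cm <- bandMap(c("BS", "XY", "PP", "BS"))
  g <- buildAdjacency(cm)
  axis <- c(1, 0)
  expect_identical(classifyPosition(3L, g, cm, axis)$value, "abaxial")

  # exactly one intervening cell (2 hops)
  cm2 <- bandMap(c("BS", "XY", "OTHER", "PP", "CC", "BS"))
  g2 <- buildAdjacency(cm2)
  p <- classifyPosition(4L, g2, cm2, axis)
  expect_identical(p$value, "abaxial")
  expect_identical(p$hopsToAbaxialBS, 2L)

  # 3 hops from both halves -> middle
  cm3 <- bandMap(c("BS", "OTHER", "OTHER", "PP", "OTHER", "OTHER", "BS"))
  g3 <- buildAdjacency(cm3)
  expect_identical(classifyPosition(4L, g3, cm3, axis)$value, "middle")

  noBS <- bandMap(c("XY", "PP", "SE"))
  expect_error(classifyPosition(2L, buildAdjacency(noBS), noBS, axis), "BS")
})

test_that("generator placements are recovered exactly for 100 seeds", {
  wrong <- 0L
  for (s in 1:100) {
    set.seed(s)
    geo <- generateCellMap(veinConfig(
      ppPositions = c("abaxial", "adaxial"),
      ingrowth = rep(list(ingrowthSpec(0, 0, 1)), 2L),
      imageSize = 96L, seed = s))
    g <- buildAdjacency(geo$map)
    ax <- abaxialAxis(geo$map)
    pp <- geo$cells$label[geo$cells$type == "PP"]
    truth <- geo$cells$position[geo$cells$type == "PP"]
    got <- vapply(pp, function(p)
      classifyPosition(p, g, geo$map, ax)$value, character(1))
    wrong <- wrong + sum(got != truth)
  }
  expect_identical(wrong, 0L)
})

test_that("vein size sums xylem and phloem areas only", {
  cm <- cellMap(matrix(1L, 10, 10), 0.2,
                data.frame(label = 1L, type = "XY"))
  expect_equal(veinSize(cm), 100 * 0.04)

  cmBS <- bandMap(c("BS", "BS"))
  expect_equal(veinSize(cmBS), 0)

  for (s in 1:20) {
    cm2 <- randomMap(s)
    ty <- cellTypes(cm2)
    keep <- as.integer(names(ty)[ty %in% c("XY", "SE", "CC", "PP")])
    expect_equal(veinSize(cm2),
                 sum(cellLabels(cm2) %in% keep) * pixelSize(cm2)^2)
  }
})

test_that("euclidean length is exact on straight boundaries", {
  lab <- matrix(rep(1:2, each = 100), 20, 10)
  cm <- cellMap(lab, 0.2, data.frame(label = 1:2, type = c("PP", "SE")))
  ii <- extractInterface(cm, 1, 2)
  expect_equal(euclideanLength(ii), 20 * 0.2, tolerance = 0.011)
  # a diagonal boundary is sqrt(2) shorter than its Manhattan face count
  S <- 40L
  lab2 <- matrix(2L, S, S)
  lab2[row(lab2) > col(lab2)] <- 1L
  cm2 <- cellMap(lab2, 0.2, data.frame(label = 1:2, type = c("PP", "SE")))
  i2 <- extractInterface(cm2, 1, 2)
  expect_equal(euclideanLength(i2) / i2@lengthUm, 1 / sqrt(2),
               tolerance = 0.06)
})
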