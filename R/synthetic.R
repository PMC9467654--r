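## Seeded synthetic vein cross-sections with full ground truth.
##
## Geometry: a Voronoi tessellation of structured generator points --
## a bundle-sheath ring around an interior with xylem placed adaxially
## (top) and phloem abaxially (bottom); abaxial PP cells sit just inside
## the abaxial bundle sheath with their sieve elements radially inward,
## flanked by companion cells. Walls are rendered as a band of wall stain
## around every boundary; wall ingrowths as a k-fold local thickening on
## the PP side of configured interface arcs; the membrane marker as a
## ribbon along PP-cell boundaries whose per-length density scales with the
## local membrane amplification.

#' Per-PP-cell ingrowth specification
#'
#' @param se target coverage fraction of each SE-facing interface.
#' @param cc per-CC-interface coverage fractions, assigned to the cell's CC
#'   interfaces in order of decreasing length (remaining interfaces get 0).
#' @param k local wall-thickness/membrane amplification (>= 1).
#' @return List used in the \code{ingrowth} slot of [VeinConfig-class].
#' @export
ingrowthSpec <- function(se = 0, cc = 0, k = 3) list(se = se, cc = cc, k = k)

#' Construct a synthetic-vein configuration
#'
#' Defaults portray a typical mature Arabidopsis minor vein: 3 xylem, 4
#' sieve elements, 5 companion cells, 2 abaxially positioned PP transfer
#' cells inside an 8-cell bundle-sheath ring; each PP TC has its SE
#' interface fully covered and its longest CC interface half covered with
#' three-fold thickening. Images are 512 x 512 px at 0.2 um/px.
#'
#' @param nCells named counts for XY, SE, CC, PP, BS.
#' @param ppPositions position class per PP cell.
#' @param ingrowth list of [ingrowthSpec()]s, one per PP cell.
#' @param markerDensity marker fluorescence per um of membrane (au/um).
#' @param ppMarkerRel relative marker density per PP cell.
#' @param attenuationCoef per-um depth attenuation (0 disables).
#' @param pixelSize um per pixel.
#' @param noiseSd additive Gaussian noise sigma (au).
#' @param wallAmp rendered wall-stain intensity (au).
#' @param wallHalfWidth primary-wall half width (um).
#' @param imageSize image side length (px).
#' @param seed integer RNG seed.
#' @return A [VeinConfig-class].
#' @export
veinConfig <- function(nCells = c(XY = 3L, SE = 4L, CC = 5L, PP = 2L, BS = 8L),
                       ppPositions = rep("abaxial", nCells[["PP"]]),
                       ingrowth = rep(list(ingrowthSpec(se = 1, cc = 0.5, k = 3)),
                                      nCells[["PP"]]),
                       markerDensity = 300, ppMarkerRel = rep(1, nCells[["PP"]]),
                       attenuationCoef = 0, pixelSize = 0.2, noiseSd = 6,
                       wallAmp = 180, wallHalfWidth = 0.4, imageSize = 512L,
                       seed = 1L) {
  nc <- as.integer(nCells)
  names(nc) <- names(nCells)
  methods::new("VeinConfig", nCells = nc, ppPositions = ppPositions,
               ingrowth = ingrowth, markerDensity = markerDensity,
               ppMarkerRel = as.numeric(ppMarkerRel),
               attenuationCoef = attenuationCoef, pixelSize = pixelSize,
               noiseSd = noiseSd, wallAmp = wallAmp,
               wallHalfWidth = wallHalfWidth, imageSize = as.integer(imageSize),
               seed = as.integer(seed))
}

#' Canonical generator presets for deposition classes I--V
#'
#' Five configurations whose PP transfer cells carry the canonical
#' deposition extent of each class: I no ingrowths; II half the SE
#' interface; III the entire SE interface (the rendered deposition wraps
#' the junction corners, which yields the small covered CC section typical
#' of this class); IV entire SE interface plus half a CC interface; V
#' entire SE interface plus an entire CC interface.
#'
#' @param class one of \code{"I"} to \code{"V"}.
#' @param ... further arguments passed to [veinConfig()] (e.g. \code{seed},
#'   \code{imageSize}, \code{noiseSd}).
#' @return A [VeinConfig-class].
#' @export
classPreset <- function(class = c("I", "II", "III", "IV", "V"), ...) {
  class <- match.arg(class)
  spec <- switch(class,
    I   = ingrowthSpec(se = 0,   cc = 0,           k = 3),
    II  = ingrowthSpec(se = 0.5, cc = 0,           k = 3),
    III = ingrowthSpec(se = 1,   cc = 0,           k = 3),
    IV  = ingrowthSpec(se = 1,   cc = 0.5,         k = 3),
    V   = ingrowthSpec(se = 1,   cc = c(1, 0.3),   k = 3))
  veinConfig(ingrowth = rep(list(spec), 2L), ...)
}

## Place generator points for the Voronoi tessellation. Coordinate frame:
## angle 0 points abaxially (+row, image bottom), pi adaxially.
.placeSeeds <- function(config, S) {
  cx <- (S + 1) / 2
  Rb <- 0.36 * S
  pts <- function(r, th, type, ppIndex = NA_integer_, position = NA_character_) {
    n <- length(th)
    data.frame(row = cx + r * cos(th) + stats::rnorm(n, 0, 0.008 * S),
               col = cx + r * sin(th) + stats::rnorm(n, 0, 0.008 * S),
               type = type, ppIndex = ppIndex, position = position)
  }
  nc <- config@nCells
  out <- list()
  if (nc[["BS"]] > 0L) {
    th <- 2 * pi * (seq_len(nc[["BS"]]) - 0.5) / nc[["BS"]]
    out$bs <- pts(Rb, th, "BS")
  }
  if (nc[["XY"]] > 0L) {
    th <- if (nc[["XY"]] == 1L) pi else
      pi + seq(-0.7, 0.7, length.out = nc[["XY"]])
    out$xy <- pts(0.20 * S, th, "XY")
  }
  npp <- nc[["PP"]]
  ppTheta <- numeric(npp)
  if (npp > 0L) {
    posn <- config@ppPositions
    iAb <- which(posn == "abaxial")
    iAd <- which(posn == "adaxial")
    iMd <- which(posn == "middle")
    ppR <- numeric(npp)
    if (length(iAb)) {
      off <- (seq_along(iAb) - (length(iAb) + 1) / 2) * 0.55
      ppTheta[iAb] <- off; ppR[iAb] <- 0.28 * S
    }
    if (length(iAd)) {
      off <- 0.45 * (-1)^(seq_along(iAd)) * ceiling(seq_along(iAd) / 2)
      ppTheta[iAd] <- pi + off; ppR[iAd] <- 0.27 * S
    }
    if (length(iMd)) {
      ppTheta[iMd] <- (pi / 2) * (-1)^(seq_along(iMd))
      ppR[iMd] <- 0.07 * S
    }
    out$pp <- pts(ppR, ppTheta, "PP", ppIndex = seq_len(npp),
                  position = posn)
  }
  if (nc[["SE"]] > 0L) {
    ## one SE directly radially inward of each abaxial PP, the rest deeper
    nAb <- sum(config@ppPositions == "abaxial")
    thPaired <- ppTheta[config@ppPositions == "abaxial"][
      seq_len(min(nAb, nc[["SE"]]))]
    nFree <- nc[["SE"]] - length(thPaired)
    thFree <- if (nFree > 0L) {
      if (nFree == 1L) 0 else seq(-0.45, 0.45, length.out = nFree)
    } else numeric()
    out$se <- pts(c(rep(0.20 * S, length(thPaired)), rep(0.10 * S, nFree)),
                  c(thPaired, thFree), "SE")
  }
  if (nc[["CC"]] > 0L) {
    ## interleaved with the abaxial PP angles so CCs flank each PP/SE pair
    th <- 0.55 * (seq_len(nc[["CC"]]) - (nc[["CC"]] + 1) / 2)
    out$cc <- pts(0.245 * S, th, "CC")
  }
  seeds <- do.call(rbind, out)
  rownames(seeds) <- NULL
  seeds
}

## Nearest-seed (Voronoi) label assignment, masked to a disk.
.voronoiLabels <- function(seeds, S, Rout) {
  cx <- (S + 1) / 2
  rows <- seq_len(S); cols <- seq_len(S)
  best <- matrix(Inf, S, S)
  lab <- matrix(0L, S, S)
  for (i in seq_len(nrow(seeds))) {
    d2 <- outer((rows - seeds$row[i])^2, (cols - seeds$col[i])^2, "+")
    upd <- d2 < best
    best[upd] <- d2[upd]
    lab[upd] <- i
  }
  lab[outer((rows - cx)^2, (cols - cx)^2, "+") > Rout^2] <- 0L
  lab
}

## Feasibility checks on a generated map: every seed owns pixels and the
## required PP adjacencies exist.
.mapFeasible <- function(labels, seeds, config) {
  present <- sort(unique(labels[labels > 0]))
  if (!identical(present, seq_len(nrow(seeds)))) return(FALSE)
  itab <- NULL
  needs <- which(seeds$type == "PP")
  f <- .allFaces(labels)
  f <- f[f$l1 > 0 & f$l2 > 0, , drop = FALSE]
  for (p in needs) {
    i <- seeds$ppIndex[p]
    sp <- config@ingrowth[[i]]
    nb <- unique(c(f$l2[f$l1 == p], f$l1[f$l2 == p]))
    nbTypes <- seeds$type[nb]
    if (sp$se > 0 && !any(nbTypes == "SE")) return(FALSE)
    if (any(sp$cc > 0) && !any(nbTypes == "CC")) return(FALSE)
  }
  TRUE
}

#' Generate the label map of a synthetic vein
#'
#' The geometry stage of [generateVein()]: places structured generator
#' points (with seeded jitter), assigns pixels to the nearest point within
#' the vein disk, and verifies feasibility (every cell non-empty, every PP
#' cell with configured SE/CC ingrowth adjacent to an SE/CC). Useful on its
#' own for geometry-only studies where rendering the channels would be
#' wasted work.
#'
#' @param config a [VeinConfig-class].
#' @return List with \code{map} (a [CellMap-class]), \code{cells} (per-cell
#'   truth table) and \code{seeds} (generator points).
#' @export
generateCellMap <- function(config) {
  methods::validObject(config)
  S <- config@imageSize
  if (sum(config@nCells) < 2L) stop("infeasible geometry: need at least 2 cells")
  if (sum(config@nCells) > (S / 8)^2)
    stop("infeasible geometry: more cells than fit at this pixel budget")
  for (attempt in 1:8) {
    seeds <- .placeSeeds(config, S)
    labels <- .voronoiLabels(seeds, S, 0.46 * S)
    if (.mapFeasible(labels, seeds, config)) {
      types <- data.frame(label = seq_len(nrow(seeds)), type = seeds$type)
      map <- cellMap(labels, config@pixelSize, types)
      cen <- .centroids(labels)
      cells <- data.frame(label = cen$label, type = seeds$type[cen$label],
                          position = seeds$position[cen$label],
                          ppIndex = seeds$ppIndex[cen$label],
                          row = cen$row, col = cen$col, npix = cen$npix)
      cells$markerRel <- NA_real_
      isPP <- !is.na(cells$ppIndex)
      cells$markerRel[isPP] <- config@ppMarkerRel[cells$ppIndex[isPP]]
      return(list(map = map, cells = cells, seeds = seeds))
    }
  }
  stop("infeasible geometry: could not realise the configured adjacencies")
}

## Choose the covered arc (centred contiguous run) of an interface.
.arcIndices <- function(nFaces, coverage) {
  nArc <- round(coverage * nFaces)
  if (coverage > 0 && nArc == 0L) nArc <- 1L
  if (nArc == 0L) return(integer())
  start <- floor((nFaces - nArc) / 2) + 1L
  seq.int(start, start + nArc - 1L)
}

## Resolve the configured ingrowth specs against the realised geometry.
## Returns a list of arcs: list(pp=label, partner=label, k=, faces=df,
## nFaces=, nArc=) plus the full per-interface truth table.
.resolveArcs <- function(map, cells, config) {
  lab <- cellLabels(map)
  facesAll <- .allFaces(lab)
  itab <- interfaceTable(map)
  itab$coveredFaces <- 0L
  itab$k <- 1
  arcs <- list()
  pps <- cells[!is.na(cells$ppIndex), , drop = FALSE]
  for (r in seq_len(nrow(pps))) {
    p <- pps$label[r]
    sp <- config@ingrowth[[pps$ppIndex[r]]]
    mine <- itab[itab$cellA == p | itab$cellB == p, , drop = FALSE]
    partners <- ifelse(mine$cellA == p, mine$cellB, mine$cellA)
    ptype <- ifelse(mine$cellA == p, mine$typeB, mine$typeA)
    targets <- data.frame(partner = partners, type = ptype,
                          nFaces = mine$nFaces)
    covs <- rep(0, nrow(targets))
    covs[targets$type == "SE"] <- sp$se
    ccIdx <- which(targets$type == "CC")
    if (length(ccIdx)) {
      ccIdx <- ccIdx[order(targets$nFaces[ccIdx], decreasing = TRUE)]
      ccCov <- rep(0, length(ccIdx))
      nGiven <- min(length(sp$cc), length(ccIdx))
      ccCov[seq_len(nGiven)] <- sp$cc[seq_len(nGiven)]
      covs[ccIdx] <- ccCov
    }
    for (i in which(covs > 0)) {
      ii <- .interfaceFromFaces(facesAll, p, targets$partner[i],
                                config@pixelSize)
      idx <- .arcIndices(nrow(ii@faces), covs[i])
      if (length(idx) == 0L) next
      arcs[[length(arcs) + 1L]] <-
        list(pp = p, partner = targets$partner[i], k = sp$k,
             faces = ii@faces[idx, , drop = FALSE], fullFaces = ii@faces)
      row <- which(itab$cellA == ii@cellA & itab$cellB == ii@cellB)
      itab$coveredFaces[row] <- length(idx)
      itab$k[row] <- sp$k
    }
  }
  itab$coveredLengthUm <- itab$coveredFaces * config@pixelSize
  itab$coverage <- itab$coveredFaces / itab$nFaces
  list(arcs = arcs, interfaces = itab)
}

## Render the wall-stain and marker channels of a label map.
## markerRel: named vector label -> relative marker density (PP cells).
.renderChannels <- function(labels, pixelSize, wallAmp, wallHalfWidth,
                            markerDensity, markerRel, arcs) {
  H <- nrow(labels); W <- ncol(labels)
  f <- .allFaces(labels)
  B <- matrix(FALSE, H, W)
  if (nrow(f)) {
    B[cbind(f$r1, f$c1)] <- TRUE
    B[cbind(f$r2, f$c2)] <- TRUE
  }
  B[c(1L, H), ] <- B[c(1L, H), ] | labels[c(1L, H), ] > 0
  B[, c(1L, W)] <- B[, c(1L, W)] | labels[, c(1L, W)] > 0
  dtB <- .distTo(B)
  h <- wallHalfWidth / pixelSize
  wallMask <- dtB <= h
  ppLabels <- as.integer(names(markerRel))
  ribbon <- (labels %in% ppLabels) & dtB <= 1
  marker <- matrix(0, H, W)
  rel <- rep(0, max(labels) + 1L)
  rel[ppLabels + 1L] <- markerRel
  marker[ribbon] <- markerDensity * pixelSize * rel[labels[ribbon] + 1L]
  for (arc in arcs) {
    A <- matrix(FALSE, H, W)
    A[cbind(arc$faces$ra, arc$faces$ca)] <- TRUE
    A[cbind(arc$faces$rb, arc$faces$cb)] <- TRUE
    dtA <- .distTo(A)
    ## deposition depth: the arc competes only against the uncovered rest of
    ## its own interface, so ingrowths on a fully covered interface reach the
    ## junctions while partial arcs keep pixel-crisp ends
    If <- matrix(FALSE, H, W)
    If[cbind(arc$fullFaces$ra, arc$fullFaces$ca)] <- TRUE
    If[cbind(arc$fullFaces$rb, arc$fullFaces$cb)] <- TRUE
    If <- If & !A
    dtI <- if (any(If)) .distTo(If) else matrix(Inf, H, W)
    ## near a junction the deposit tapers against the walls of the
    ## neighbouring interface: its depth is capped by the distance to
    ## foreign boundaries plus one wall width
    Fo <- matrix(FALSE, H, W)
    Fo[cbind(arc$fullFaces$ra, arc$fullFaces$ca)] <- TRUE
    Fo[cbind(arc$fullFaces$rb, arc$fullFaces$cb)] <- TRUE
    X <- B & !Fo
    dtX <- if (any(X)) .distTo(X) else matrix(Inf, H, W)
    wallMask <- wallMask |
      (labels == arc$pp & dtA <= dtI & dtA <= pmin(arc$k * h, dtX + 1.5 * h))
    ## membrane amplification: a ribbon pixel is amplified iff its nearest
    ## boundary pixel lies on the covered arc
    O <- B & !A
    dtO <- if (any(O)) .distTo(O) else matrix(Inf, H, W)
    amp <- ribbon & labels == arc$pp & dtA <= dtO
    marker[amp] <- marker[amp] * arc$k
  }
  list(wall = wallAmp * wallMask, marker = marker)
}

#' Generate a synthetic vein cross-section with ground truth
#'
#' Renders a two-channel image (wall stain, membrane marker) of a synthetic
#' minor-vein cross-section together with its full ground truth: the label
#' map, per-cell table, per-interface table with exact rendered covered
#' lengths, and the attenuation map. Identical configurations (including
#' the seed) give bit-identical output.
#'
#' @param config a [VeinConfig-class].
#' @return List with \code{image} (a [VeinImage-class]) and \code{truth}
#'   (a [SyntheticTruth-class]).
#' @examples
#' vt <- generateVein(veinConfig(imageSize = 192L, seed = 7L))
#' vt$truth
#' @export
generateVein <- function(config) {
  methods::validObject(config)
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  }
  set.seed(config@seed)
  geo <- generateCellMap(config)
  map <- geo$map
  cells <- geo$cells
  res <- .resolveArcs(map, cells, config)
  markerRel <- cells$markerRel[!is.na(cells$markerRel)]
  names(markerRel) <- cells$label[!is.na(cells$markerRel)]
  ch <- .renderChannels(cellLabels(map), config@pixelSize, config@wallAmp,
                        config@wallHalfWidth, config@markerDensity,
                        markerRel, res$arcs)
  S <- config@imageSize
  depth <- (S - seq_len(S)) * config@pixelSize
  attn <- matrix(exp(-config@attenuationCoef * depth), S, S)
  wall <- ch$wall * attn
  marker <- ch$marker * attn
  if (config@noiseSd > 0) {
    wall <- pmax(wall + stats::rnorm(length(wall), 0, config@noiseSd), 0)
    marker <- pmax(marker + stats::rnorm(length(marker), 0, config@noiseSd), 0)
  }
  image <- VeinImage(list(wall, marker), config@pixelSize)
  truth <- methods::new("SyntheticTruth", cellMap = map, cells = cells,
                        interfaces = res$interfaces, attenuationMap = attn,
                        config = config)
  list(image = image, truth = truth)
}

#' Apply depth-dependent attenuation to a vein image
#'
#' Multiplies both channels pixel-wise by \code{exp(-coef * depth)}, with
#' depth measured along the adaxial direction from the abaxial image edge
#' (the last row, closest to the objective when imaging from the lower leaf
#' side). Because the factor is shared between channels, per-pixel channel
#' ratios are unchanged wherever both channels are positive -- the property
#' the internal-standard statistic F exploits.
#'
#' @param image a two-channel [VeinImage-class].
#' @param coef per-micrometre attenuation coefficient (>= 0); taken from
#'   \code{truth} when omitted.
#' @param truth optional [SyntheticTruth-class] supplying the coefficient.
#' @return The attenuated [VeinImage-class].
#' @export
applyAttenuation <- function(image, coef = NULL, truth = NULL) {
  if (is.null(coef)) {
    if (is.null(truth)) stop("supply 'coef' or 'truth'")
    coef <- truth@config@attenuationCoef
  }
  stopifnot(coef >= 0)
  if (nChannels(image) != 2L)
    stop("attenuation expects a two-channel image (wall, marker)")
  H <- dim(image@pixels)[1L]
  depth <- (H - seq_len(H)) * pixelSize(image)
  attn <- exp(-coef * depth)
  px <- image@pixels
  px[, , 1L] <- px[, , 1L] * attn
  px[, , 2L] <- px[, , 2L] * attn
  VeinImage(px, pixelSize(image), image@channelNames)
}

#' Build a twin-cell calibration phantom
#'
#' Two geometrically identical PP cells offset purely in depth (rows), with
#' relative marker densities 1 and \code{ratio}. Because the deeper cell is
#' an exact translate of the shallower one, an exponential depth attenuation
#' factorises out of every per-cell channel sum, making the phantom the
#' exact test case for the cancellation property of the F statistic.
#'
#' @param ratio marker density of the deep (adaxial) cell relative to the
#'   shallow (abaxial) one.
#' @param cellSize square cell side length (px).
#' @param sepRows vertical offset between the two cells (px).
#' @param imageSize image side length (px).
#' @param pixelSize um per pixel.
#' @param markerDensity marker density (au/um).
#' @param wallAmp wall-stain intensity (au).
#' @param wallHalfWidth primary-wall half width (um).
#' @return List with \code{image} (noise-free, unattenuated
#'   [VeinImage-class]), \code{map}, and labels \code{shallow} / \code{deep}.
#' @export
twinPhantom <- function(ratio = 0.84, cellSize = 40L, sepRows = 60L,
                        imageSize = 160L, pixelSize = 0.2,
                        markerDensity = 300, wallAmp = 180,
                        wallHalfWidth = 0.4) {
  S <- as.integer(imageSize)
  lab <- matrix(0L, S, S)
  c0 <- (S - cellSize) %/% 2L
  rDeep <- (S %/% 2L - sepRows %/% 2L) - cellSize %/% 2L
  rShal <- (S %/% 2L + sepRows %/% 2L) - cellSize %/% 2L
  if (rDeep < 4L || rShal + cellSize > S - 4L)
    stop("phantom does not fit: reduce cellSize or sepRows")
  lab[rDeep + seq_len(cellSize), c0 + seq_len(cellSize)] <- 1L
  lab[rShal + seq_len(cellSize), c0 + seq_len(cellSize)] <- 2L
  map <- cellMap(lab, pixelSize,
                 data.frame(label = 1:2, type = c("PP", "PP")))
  ch <- .renderChannels(lab, pixelSize, wallAmp, wallHalfWidth, markerDensity,
                        c(`1` = ratio, `2` = 1), list())
  list(image = VeinImage(list(ch$wall, ch$marker), pixelSize),
       map = map, shallow = 2L, deep = 1L)
}
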