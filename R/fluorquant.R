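## Fluorescence quantification: 8-bit conversion, default (intermeans)
## thresholding, ROI intensity sums, the internal-standard relative
## intensity F and the membrane-enrichment factor FC.

#' Convert a channel to 8-bit
#'
#' Linear min--max rescale of the whole frame to \[0, 255\], rounded half
#' up. A constant frame maps to all zeros (documented degenerate case).
#'
#' @param x numeric matrix of non-negative intensities.
#' @return Integer matrix with values in 0..255.
#' @examples
#' to8bit(matrix(c(0, 250, 500, 1000), 2))
#' @export
to8bit <- function(x) {
  if (any(x < 0)) stop("intensities must be non-negative")
  rng <- range(x)
  y <- if (rng[2L] == rng[1L]) array(0, dim(x)) else
    floor((x - rng[1L]) / (rng[2L] - rng[1L]) * 255 + 0.5)
  storage.mode(y) <- "integer"
  y
}

#' Default (iterative intermeans) threshold of an 8-bit image
#'
#' The IsoData-variant intermeans threshold used as the "default setting" of
#' common image-analysis software: starting from the frame mean, iterate
#' \code{t <- round((mean(x[x <= t]) + mean(x[x > t])) / 2)} until stable.
#' Pixels strictly above the returned threshold count as signal.
#'
#' @param x integer matrix with values in 0..255 (see [to8bit()]).
#' @return Integer threshold.
#' @examples
#' x <- matrix(c(rep(20L, 50), rep(200L, 50)), 10)
#' defaultThreshold(x)  # ~110
#' @export
defaultThreshold <- function(x) {
  if (length(x) == 0L) stop("empty image")
  v <- as.integer(x)
  if (any(v < 0 | v > 255)) stop("expected an 8-bit image (values 0..255)")
  h <- tabulate(v + 1L, nbins = 256L)
  lev <- 0:255
  t <- floor(sum(h * lev) / sum(h) + 0.5)
  for (i in 1:256) {
    below <- h[lev <= t]; lb <- lev[lev <= t]
    above <- h[lev > t];  la <- lev[lev > t]
    if (sum(above) == 0L || sum(below) == 0L) break
    tNew <- floor((sum(below * lb) / sum(below) +
                   sum(above * la) / sum(above)) / 2 + 0.5)
    if (tNew == t) break
    t <- tNew
  }
  as.integer(t)
}

#' Summed above-threshold intensity in a region of interest
#'
#' @param x numeric or integer matrix (typically 8-bit).
#' @param roi logical matrix of the same dimensions.
#' @param threshold only pixels with value strictly greater than this count.
#' @return The sum of above-threshold intensities inside the ROI.
#' @export
roiIntensity <- function(x, roi, threshold) {
  if (!identical(dim(x), dim(roi))) stop("ROI dimensions must match the image")
  if (!any(roi)) stop("empty ROI")
  vals <- x[roi]
  sum(as.numeric(vals[vals > threshold]))
}

#' Relative fluorescence intensity F with internal-standard calibration
#'
#' \deqn{F = (S_2 C_1) / (S_1 C_2)} where S are marker-channel and C
#' wall-stain-channel intensity sums in the reference region (subscript 1, a
#' PP transfer cell) and the test region (subscript 2, a PP cell). Because
#' depth-dependent excitation loss multiplies both channels of a region by
#' the same factor, that factor cancels: F estimates the true marker density
#' of the test region relative to the reference, with the reference's own F
#' equal to 1 by construction.
#'
#' @param reads a [CalibrationReads-class].
#' @return The statistic F (dimensionless).
#' @examples
#' relativeIntensity(calibrationReads(S1 = 100, S2 = 42, C1 = 50, C2 = 25))
#' @export
relativeIntensity <- function(reads) {
  stopifnot(methods::is(reads, "CalibrationReads"))
  if (reads@S1 <= 0 || reads@C2 <= 0)
    stop("undefined statistic: F requires S1 > 0 and C2 > 0")
  (reads@S2 * reads@C1) / (reads@S1 * reads@C2)
}

#' Membrane-enrichment factor FC
#'
#' \deqn{FC = (A_1 L_2) / (A_2 L_1)}: marker fluorescence per unit
#' primary-wall length at the ingrowth-bearing side (\code{A1}, \code{L1})
#' relative to the opposite, ingrowth-free side (\code{A2}, \code{L2}). The
#' ingrowth-free side's own FC is 1 by construction; a k-fold enlargement of
#' the plasma membrane by wall ingrowths gives FC close to k.
#'
#' @param reads an [EnrichmentReads-class].
#' @return The statistic FC (dimensionless).
#' @examples
#' enrichment(enrichmentReads(A1 = 300, A2 = 100, L1 = 2, L2 = 2))
#' @export
enrichment <- function(reads) {
  stopifnot(methods::is(reads, "EnrichmentReads"))
  if (reads@A2 <= 0 || reads@L1 <= 0)
    stop("undefined statistic: FC requires A2 > 0 and L1 > 0")
  (reads@A1 * reads@L2) / (reads@A2 * reads@L1)
}

## Distance of every pixel to a pixel set given as a logical mask.
.distTo <- function(mask) {
  m <- matrix(1, nrow(mask), ncol(mask))
  m[mask] <- 0
  as.matrix(EBImage::distmap(m))
}

## Boundary pixels of one cell (pixels of the cell 4-adjacent to non-cell,
## image border included).
.cellBoundary <- function(labels, cell) {
  inC <- labels == cell
  H <- nrow(labels); W <- ncol(labels)
  up <- rbind(TRUE, !inC[-H, , drop = FALSE])
  dn <- rbind(!inC[-1L, , drop = FALSE], TRUE)
  lf <- cbind(TRUE, !inC[, -W, drop = FALSE])
  rt <- cbind(!inC[, -1L, drop = FALSE], TRUE)
  inC & (up | dn | lf | rt)
}

#' Membrane-ribbon ROI of a cell
#'
#' Pixels within \code{width} pixels of the cell's boundary (either side),
#' the region holding the plasma-membrane marker signal and the wall stain.
#'
#' @param map a [CellMap-class].
#' @param cell a cell label.
#' @param width ribbon half-width in pixels (default 2).
#' @return Logical matrix.
#' @export
membraneRoi <- function(map, cell, width = 2) {
  lab <- cellLabels(map)
  b <- .cellBoundary(lab, cell)
  if (!any(b)) stop(sprintf("cell %d not present in the label map", cell))
  .distTo(b) <= width
}

## ROI restricted to one face set of a cell: pixels within `width` of the
## face pixels whose nearest boundary pixel belongs to that face set.
.roiForFaces <- function(map, cell, faces, width = 2) {
  lab <- cellLabels(map)
  H <- nrow(lab); W <- ncol(lab)
  A <- matrix(FALSE, H, W)
  A[cbind(faces$ra, faces$ca)] <- TRUE
  A[cbind(faces$rb, faces$cb)] <- TRUE
  f <- .allFaces(lab)
  B <- matrix(FALSE, H, W)
  B[cbind(f$r1, f$c1)] <- TRUE
  B[cbind(f$r2, f$c2)] <- TRUE
  B[c(1L, H), ] <- B[c(1L, H), ] | lab[c(1L, H), ] > 0
  B[, c(1L, W)] <- B[, c(1L, W)] | lab[, c(1L, W)] > 0
  O <- B & !A
  dtA <- .distTo(A)
  dtO <- if (any(O)) .distTo(O) else matrix(Inf, H, W)
  dtA <= width & dtA <= dtO & (lab == cell | A)
}

#' Measure the calibrated intensity ratio between two PP cells
#'
#' Runs the full measurement path of the F statistic on one two-channel
#' image: each channel is converted to 8-bit ([to8bit()]), thresholded with
#' the default intermeans method ([defaultThreshold()]), and summed over
#' each cell's membrane-ribbon ROI ([membraneRoi()]); the four sums form the
#' [CalibrationReads-class] of [relativeIntensity()].
#'
#' @param image a two-channel [VeinImage-class] (wall, marker).
#' @param map the matching [CellMap-class].
#' @param refCell label of the reference PP transfer cell (subscript 1).
#' @param testCell label of the test PP cell (subscript 2).
#' @param width ribbon half-width in pixels.
#' @return List with elements \code{reads}, \code{F} and the channel
#'   \code{thresholds} used.
#' @export
measureCellPair <- function(image, map, refCell, testCell, width = 2) {
  if (nChannels(image) < 2L) stop("need a two-channel image (wall, marker)")
  ty <- cellTypes(map)
  if (!identical(unname(ty[as.character(refCell)]), "PP") ||
      !identical(unname(ty[as.character(testCell)]), "PP"))
    stop("both cells must be PP-type")
  m8 <- to8bit(channel(image, "marker"))
  w8 <- to8bit(channel(image, "wall"))
  tm <- defaultThreshold(m8)
  tw <- defaultThreshold(w8)
  roiRef <- membraneRoi(map, refCell, width)
  roiTest <- membraneRoi(map, testCell, width)
  reads <- calibrationReads(S1 = roiIntensity(m8, roiRef, tm),
                            S2 = roiIntensity(m8, roiTest, tm),
                            C1 = roiIntensity(w8, roiRef, tw),
                            C2 = roiIntensity(w8, roiTest, tw))
  list(reads = reads, F = relativeIntensity(reads),
       thresholds = c(marker = tm, wall = tw))
}

#' Measure marker enrichment between two sides of one PP transfer cell
#'
#' Sums above-threshold marker fluorescence over the ribbon ROI of an
#' ingrowth-bearing face set and an ingrowth-free reference face set of the
#' same cell, pairs each with its primary-wall length (face count times
#' pixel size), and evaluates [enrichment()].
#'
#' @param image a two-channel [VeinImage-class].
#' @param map the matching [CellMap-class].
#' @param cell the PP transfer-cell label.
#' @param ingrowthFaces faces data.frame (as in [Interface-class]) of the
#'   ingrowth-bearing side, or an [Interface-class].
#' @param referenceFaces faces of the ingrowth-free side, same forms.
#' @param width ribbon half-width in pixels.
#' @param trim number of terminal faces dropped from each side before the
#'   ROI and its wall length are formed. The ribbon ROI bulges around the
#'   ends of a face run, which inflates the per-length fluorescence of
#'   short runs relative to long ones; trimming makes both sides interior
#'   estimates.
#' @param lengthMode how the primary-wall lengths L1, L2 are measured.
#'   \code{"ribbon"} (default): the marker-positive membrane footprint
#'   (above-threshold ROI pixel count scaled by the nominal two-pixel
#'   ribbon width) -- the raster analogue of tracing the visible membrane,
#'   and the only estimator whose pixels-per-micrometre density is
#'   independent of boundary orientation, which would otherwise bias FC by
#'   up to sqrt(2) between differently oriented sides. \code{"euclidean"}:
#'   chord length of the face run. \code{"faces"}: face count times pixel
#'   size (Manhattan).
#' @return List with \code{reads}, \code{FC} and the marker \code{threshold}.
#' @export
measureEnrichment <- function(image, map, cell, ingrowthFaces, referenceFaces,
                              width = 2, trim = 2L,
                              lengthMode = c("ribbon", "euclidean", "faces")) {
  lengthMode <- match.arg(lengthMode)
  if (nChannels(image) < 2L) stop("need a two-channel image (wall, marker)")
  asFaces <- function(x) if (methods::is(x, "Interface")) x@faces else x
  trimFaces <- function(f) {
    k <- min(as.integer(trim), max(0L, (nrow(f) - 3L) %/% 2L))
    if (k > 0L) f[seq.int(k + 1L, nrow(f) - k), , drop = FALSE] else f
  }
  f1 <- trimFaces(asFaces(ingrowthFaces))
  f2 <- trimFaces(asFaces(referenceFaces))
  m8 <- to8bit(channel(image, "marker"))
  tm <- defaultThreshold(m8)
  roi1 <- .roiForFaces(map, cell, f1, width)
  roi2 <- .roiForFaces(map, cell, f2, width)
  len <- function(f, roi) {
    switch(lengthMode,
      ribbon = sum(m8[roi] > tm) * pixelSize(map) / 2,
      euclidean = euclideanLength(f, pixelSize(map)),
      faces = nrow(f) * pixelSize(map))
  }
  reads <- enrichmentReads(A1 = roiIntensity(m8, roi1, tm),
                           A2 = roiIntensity(m8, roi2, tm),
                           L1 = len(f1, roi1), L2 = len(f2, roi2))
  list(reads = reads, FC = enrichment(reads), threshold = tm)
}
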