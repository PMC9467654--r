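## Wall-ingrowth detection along interfaces and the five-class grading of
## deposition extent (Class I: none; II: partial SE interface; III: entire
## SE interface; IV: entire SE interface plus a considerable part of a CC
## interface; V: some CC interface entirely covered).

#' Wall-thickness profile along an interface
#'
#' For every face of the interface, the local wall thickness on the given
#' cell's side: starting from the face, consecutive wall-mask pixels are
#' counted along the inward face normal (an axis-aligned ray), and the count
#' is converted to micrometres. The wall mask is obtained from the wall
#' channel by 8-bit conversion and default thresholding unless a logical
#' mask or an explicit threshold is supplied.
#'
#' @param wall numeric wall-channel matrix, or a logical wall mask.
#' @param interface an [Interface-class].
#' @param side label of the cell on whose side thickness is measured
#'   (typically the PP cell); defaults to \code{cellA}.
#' @param map optional [CellMap-class]; when given, the ray only counts
#'   wall pixels inside the measured cell (deposition is intracellular,
#'   foreign walls lie across the boundary and contiguity breaks at the
#'   lumen), and thickness is the deepest perpendicular penetration of the
#'   contiguous wall run rather than the raw ray length, which is robust to
#'   oblique rays on staircase boundaries.
#' @param threshold optional integer threshold for binarising the channel.
#' @param maxSteps maximum ray length in pixels.
#' @return Object of class \code{ThicknessProfile}: list with
#'   \code{thicknessUm} (one value per face, in face order), \code{baselineUm}
#'   (NA until set, see [wallBaseline()]), \code{side} and \code{pixelSize}.
#' @export
thicknessProfile <- function(wall, interface, side = NULL, map = NULL,
                             threshold = NULL, maxSteps = 50L) {
  if (is.logical(wall)) {
    mask <- wall
  } else {
    w8 <- to8bit(wall)
    if (is.null(threshold)) threshold <- defaultThreshold(w8)
    mask <- w8 > threshold
  }
  if (is.null(side)) side <- interface@cellA
  f <- interface@faces
  if (side == interface@cellA) {
    pr <- f$ra; pc <- f$ca; dr <- f$ra - f$rb; dc <- f$ca - f$cb
  } else if (side == interface@cellB) {
    pr <- f$rb; pc <- f$cb; dr <- f$rb - f$ra; dc <- f$cb - f$ca
  } else stop("'side' must be one of the interface's two cells")
  H <- nrow(mask); W <- ncol(mask)
  if (any(pr < 1L | pr > H | pc < 1L | pc > W))
    stop("interface lies outside the image")
  n <- nrow(f)
  if (!is.null(map)) {
    lab <- cellLabels(map)
    P <- matrix(FALSE, H, W)
    P[cbind(f$ra, f$ca)] <- TRUE
    P[cbind(f$rb, f$cb)] <- TRUE
    fa <- .allFaces(lab)
    Q <- matrix(FALSE, H, W)
    Q[cbind(fa$r1, fa$c1)] <- TRUE
    Q[cbind(fa$r2, fa$c2)] <- TRUE
    Q[c(1L, H), ] <- Q[c(1L, H), ] | lab[c(1L, H), ] > 0
    Q[, c(1L, W)] <- Q[, c(1L, W)] | lab[, c(1L, W)] > 0
    Q <- Q & !P
    dtP <- .distTo(P)
    dtQ <- if (any(Q)) .distTo(Q) else matrix(Inf, H, W)
    ## two restrictions: the ray counts only wall inside the measured cell
    ## (deposition is intracellular), and a pixel's penetration may exceed
    ## its distance to foreign boundaries only slightly -- this stops rays
    ## that run along the wall band of an adjoining same-cell interface
    ## while keeping junction-tapered deposits, whose depth is bounded the
    ## same way by construction
    mask <- mask & lab == side & (dtP <= dtQ + 3)
  } else dtP <- NULL
  ## inward normals, smoothed over neighbouring faces: on staircase
  ## (diagonal) boundaries the per-face axis-aligned normal points along
  ## the wall for every other face, so the ray direction is taken
  ## perpendicular to the local tangent of the ordered face midpoints and
  ## oriented by the face's own inward direction
  mr <- (f$ra + f$rb) / 2; mc <- (f$ca + f$cb) / 2
  w <- 3L
  th <- numeric(n)
  avail <- rep(Inf, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    tg <- c(mr[hi] - mr[lo], mc[hi] - mc[lo])
    nrm <- c(-tg[2L], tg[1L])
    nn <- sqrt(sum(nrm^2))
    nrm <- if (nn < 1e-9) c(dr[i], dc[i]) else nrm / nn
    if (nrm[1L] * dr[i] + nrm[2L] * dc[i] < 0) nrm <- -nrm
    ## two parallel rays half a pixel either side of the face midpoint:
    ## a single ray can die on a one-pixel notch of the rasterised wall
    tgu <- c(nrm[2L], -nrm[1L])
    best <- -Inf
    for (off in c(-0.5, 0.5)) {
      t <- 0; depth <- -1
      repeat {
        r <- as.integer(round(pr[i] + off * tgu[1L] + t * nrm[1L]))
        c <- as.integer(round(pc[i] + off * tgu[2L] + t * nrm[2L]))
        if (r < 1L || r > H || c < 1L || c > W || !mask[r, c] || t >= maxSteps)
          break
        if (!is.null(dtP)) depth <- max(depth, dtP[r, c])
        t <- t + 0.5
      }
      ## with a map, thickness is the deepest perpendicular penetration
      ## along the contiguous wall run (robust to oblique rays at boundary
      ## kinks); without one, the ray path length itself
      best <- max(best, if (is.null(dtP)) t else depth + 1)
    }
    th[i] <- best
    if (!is.null(dtP)) {
      ## available depth: how deep this face's ray could measure at all,
      ## decided by the cell's geometry alone (the ray leaves the cell or
      ## enters a foreign wall's territory), never by the wall signal
      t <- 0; depth <- -1
      repeat {
        r <- as.integer(round(pr[i] + t * nrm[1L]))
        c <- as.integer(round(pc[i] + t * nrm[2L]))
        if (r < 1L || r > H || c < 1L || c > W || t >= maxSteps ||
            (t > 0 && (lab[r, c] != side || dtP[r, c] > dtQ[r, c] + 3)))
          break
        depth <- max(depth, dtP[r, c])
        t <- t + 0.5
      }
      avail[i] <- depth + 1
    }
  }
  structure(list(thicknessUm = th * interface@pixelSize,
                 availUm = avail * interface@pixelSize,
                 baselineUm = NA_real_,
                 cellA = interface@cellA, cellB = interface@cellB,
                 side = side, pixelSize = interface@pixelSize),
            class = "ThicknessProfile")
}

#' Baseline (primary-wall) thickness of a cell
#'
#' The upper quartile of the thickness over reference faces known to carry
#' no deposition when such faces are available; otherwise the 25th
#' percentile of the cell's own pooled profile across all its interfaces.
#' On staircase (pixelated) boundaries the per-face thickness of a uniform
#' wall scatters about half a pixel below its geometric width on diagonal
#' stretches, so the reference estimate is the upper quartile of
#' deposition-free faces plus half a pixel (the sampling bias), which is
#' robust both to the diagonal lower mode and to stray thick reads near
#' junctions. Pooling across interfaces
#' matters because a fully covered SE interface has no uncovered faces of
#' its own.
#'
#' @param profiles list of \code{ThicknessProfile}s of one cell (or a single
#'   profile).
#' @param reference optional list of profiles over known-deposition-free
#'   faces.
#' @param trim number of faces dropped from each end of every reference
#'   profile: junction-zone faces carry ray-escape artefacts that would
#'   contaminate the baseline.
#' @return Baseline thickness in micrometres.
#' @export
wallBaseline <- function(profiles, reference = NULL, trim = 5L) {
  pool <- function(ps, tr = 0L) {
    if (inherits(ps, "ThicknessProfile")) ps <- list(ps)
    unlist(lapply(ps, function(p) {
      v <- p$thicknessUm
      k <- min(tr, max(0L, (length(v) - 3L) %/% 2L))
      if (k > 0L) v[seq.int(k + 1L, length(v) - k)] else v
    }))
  }
  px <- if (inherits(profiles, "ThicknessProfile")) profiles$pixelSize else
    profiles[[1L]]$pixelSize
  if (!is.null(reference))
    stats::quantile(pool(reference, trim), 0.75, names = FALSE) + 0.5 * px
  else stats::quantile(pool(profiles), 0.25, names = FALSE)
}

#' Detect wall-ingrowth deposition along a thickness profile
#'
#' A face is flagged iff its thickness exceeds \code{factor} times the
#' baseline; runs of fewer than \code{minRun} consecutive flagged faces are
#' suppressed (despeckle). The default factor 1.5 separates two-fold or
#' stronger thickening from pixel-level measurement noise.
#'
#' At the first and last \code{endMargin} faces -- the cell-corner junction
#' zone, where the walls of three cells merge and deposition tapers -- a
#' flagged run reaching the margin is continued outward under the relaxed
#' \code{weakFactor} threshold (hysteresis). Without this, an interface
#' whose deposition genuinely reaches the junction loses its terminal faces
#' to the taper, while junction nodes alone never seed a run.
#'
#' @param profile a \code{ThicknessProfile} (see [thicknessProfile()]).
#' @param factor detection factor (> 1).
#' @param minRun minimum run length of flagged faces.
#' @param baseline baseline thickness in micrometres; defaults to the
#'   profile's stored baseline, else its own 25th percentile.
#' @param endMargin number of junction-zone faces at each end scored by run
#'   continuation.
#' @param weakFactor relaxed threshold used when continuing a run into the
#'   junction zone.
#' @return Logical vector, one entry per face.
#' @export
detectIngrowth <- function(profile, factor = 1.5, minRun = 3L, baseline = NULL,
                           endMargin = 10L, weakFactor = 1.15) {
  stopifnot(factor > 1, weakFactor > 1, weakFactor <= factor)
  if (is.null(baseline)) baseline <- profile$baselineUm
  if (is.na(baseline))
    baseline <- stats::quantile(profile$thicknessUm, 0.25, names = FALSE)
  if (baseline <= 0) stop("profile baseline is zero: no wall detected")
  th <- profile$thicknessUm
  flag <- th > factor * baseline
  r <- rle(flag)
  r$values[r$values & r$lengths < minRun] <- FALSE
  flag <- inverse.rle(r)
  n <- length(flag)
  m <- min(as.integer(endMargin), max(0L, (n - as.integer(minRun)) %/% 2L))
  weak <- profile$thicknessUm > weakFactor * baseline
  if (m > 0L) {
    ## inside the margin a face is flagged only by continuation of the
    ## adjacent run: junction nodes alone cannot seed a run there
    for (i in seq(m, 1L)) flag[i] <- flag[i + 1L] && weak[i]
    for (i in seq(n - m + 1L, n)) flag[i] <- flag[i - 1L] && weak[i]
  }
  ## faces whose ray cannot reach ingrowth depth for purely geometric
  ## reasons (it exits the cell at a junction corner) carry no evidence
  ## either way: they take the state of the nearest measurable face
  if (!is.null(profile$availUm)) {
    bad <- profile$availUm <= factor * baseline
    if (any(bad) && !all(bad)) {
      ok <- which(!bad)
      for (i in which(bad)) flag[i] <- flag[ok[which.min(abs(ok - i))]]
    }
  }
  flag
}

#' Coverage fraction of an interface
#'
#' Covered length over total length, where the covered length is the number
#' of ingrowth-flagged faces times the pixel size.
#'
#' @param interface an [Interface-class] with a populated ingrowth mask (see
#'   [setIngrowthMask()]).
#' @return Fraction in \[0, 1\].
#' @export
coverageFraction <- function(interface) {
  if (interface@lengthUm <= 0) stop("zero-length interface")
  interface@coveredLengthUm / interface@lengthUm
}

#' Assign the five-class deposition grade of a PP cell
#'
#' Classes follow the canonical progression of wall-ingrowth deposition:
#' \describe{
#'   \item{I}{no discernible ingrowths on SE- or CC-facing interfaces.}
#'   \item{II}{partial coverage of the SE-facing interface.}
#'   \item{III}{SE interface entirely covered (>= \code{full}); at most a
#'     small portion (<= \code{smallCC}) of any CC interface.}
#'   \item{IV}{SE interface entirely covered and a considerable portion of
#'     some CC interface.}
#'   \item{V}{SE interface entirely covered and some CC interface entirely
#'     covered.}
#' }
#' A cell with zero SE coverage but non-zero CC coverage is not part of the
#' progression; it is flagged with a warning and returned as class II.
#'
#' @param coverageSE fraction of the cell's total SE-facing interface length
#'   covered.
#' @param coverageCC numeric vector of per-CC-interface coverage fractions
#'   (may be empty).
#' @param smallCC threshold for "a small portion" of a CC interface.
#' @param full threshold for "entirely covered".
#' @return Character, one of \code{"I"} to \code{"V"}.
#' @examples
#' assignClass(0, numeric())       # "I"
#' assignClass(0.5, c(0, 0))       # "II"
#' assignClass(1, c(0.05))         # "III"
#' assignClass(1, c(0.4))          # "IV"
#' assignClass(1, c(1, 0.3))       # "V"
#' @export
assignClass <- function(coverageSE, coverageCC = numeric(),
                        smallCC = 0.2, full = 0.95) {
  stopifnot(coverageSE >= 0, coverageSE <= 1,
            all(coverageCC >= 0), all(coverageCC <= 1))
  maxCC <- if (length(coverageCC)) max(coverageCC) else 0
  if (coverageSE == 0 && maxCC > 0) {
    warning("non-zero CC coverage with zero SE coverage: outside the ",
            "canonical progression; returning class II")
    return("II")
  }
  if (coverageSE == 0) "I"
  else if (coverageSE < full) "II"
  else if (any(coverageCC >= full)) "V"
  else if (maxCC > smallCC) "IV"
  else "III"
}

#' Ordinal ingrowth score of a cell
#'
#' The cell score is the class index minus one (Class I = 0 ... Class V = 4).
#'
#' @param class character class from [assignClass()].
#' @return Integer score 0--4.
#' @export
scoreCell <- function(class) {
  i <- match(class, .CLASSES)
  if (any(is.na(i))) stop("unknown deposition class")
  i - 1L
}

#' Ingrowth score of a vein
#'
#' Sum of the cell scores of all PP cells in the vein; a typical two-PP-TC
#' vein therefore scores 0--8.
#'
#' @param classes character vector of per-PP-cell classes (possibly empty).
#' @return Integer vein score.
#' @export
scoreVein <- function(classes) {
  if (length(classes) == 0L) return(0L)
  sum(scoreCell(classes))
}

#' Measure one vein end-to-end
#'
#' Full per-vein measurement: wall-mask extraction (8-bit conversion +
#' default threshold), adjacency graph, abaxial axis and PP position
#' classification, thickness profiles and ingrowth detection along every
#' PP-cell interface, coverage fractions, five-class assignment and ordinal
#' scores.
#'
#' @param image a two-channel [VeinImage-class] (wall, marker).
#' @param map the matching [CellMap-class].
#' @param factor,minRun ingrowth-detection parameters, see [detectIngrowth()].
#' @param smallCC,full class thresholds, see [assignClass()].
#' @param axis optional abaxial unit vector; inferred via [abaxialAxis()]
#'   when missing.
#' @return List with \code{cells} (label, type, position, SE/CC coverage,
#'   class, score), \code{interfaces} (all interfaces; coverage filled in
#'   for PP/SE and PP/CC pairs), \code{veinScore} and \code{wallThreshold}.
#' @export
measureVein <- function(image, map, factor = 1.5, minRun = 3L,
                        smallCC = 0.2, full = 0.95, axis = NULL) {
  if (nChannels(image) < 2L) stop("need a two-channel image (wall, marker)")
  lab <- cellLabels(map)
  ty <- cellTypes(map)
  w8 <- to8bit(channel(image, "wall"))
  thr <- defaultThreshold(w8)
  mask <- w8 > thr
  graph <- buildAdjacency(map)
  if (is.null(axis)) axis <- abaxialAxis(map)
  itab <- interfaceTable(map)
  itab$coveredLengthUm <- NA_real_
  itab$coverage <- NA_real_
  facesAll <- .allFaces(lab)
  pp <- as.integer(names(ty)[ty == "PP"])
  pos <- if (length(pp)) .classifyPositions(pp, graph, map, axis) else
    data.frame(label = integer(), position = character(),
               hopsToAbaxialBS = integer(), hopsToAdaxialBS = integer())
  cells <- data.frame(label = pp, type = "PP",
                      position = pos$position[match(pp, pos$label)],
                      coverageSE = 0, maxCoverageCC = 0,
                      class = NA_character_, cellScore = NA_integer_)
  for (j in seq_along(pp)) {
    p <- pp[j]
    nb <- as.integer(igraph::neighbors(graph, as.character(p))$name)
    ifs <- lapply(nb, function(b)
      .interfaceFromFaces(facesAll, p, b, pixelSize(map)))
    profs <- lapply(ifs, function(ii)
      thicknessProfile(mask, ii, side = p, map = map))
    ## deposition only occurs on SE- and CC-facing walls, so the cell's
    ## other interfaces are deposition-free baseline references
    refTypes <- !unname(ty[as.character(nb)]) %in% c("SE", "CC")
    base <- if (any(refTypes)) wallBaseline(profs, reference = profs[refTypes])
            else wallBaseline(profs)
    seLen <- 0; seCov <- 0
    ccCov <- numeric()
    for (i in seq_along(nb)) {
      pt <- unname(ty[as.character(nb[i])])
      if (!pt %in% c("SE", "CC")) next
      det <- detectIngrowth(profs[[i]], factor = factor, minRun = minRun,
                            baseline = base)
      ii <- setIngrowthMask(ifs[[i]], det)
      cov <- coverageFraction(ii)
      row <- which(itab$cellA == ii@cellA & itab$cellB == ii@cellB)
      itab$coveredLengthUm[row] <- ii@coveredLengthUm
      itab$coverage[row] <- cov
      if (pt == "SE") {
        seLen <- seLen + ii@lengthUm
        seCov <- seCov + ii@coveredLengthUm
      } else ccCov <- c(ccCov, cov)
    }
    covSE <- if (seLen > 0) seCov / seLen else 0
    cells$coverageSE[j] <- covSE
    cells$maxCoverageCC[j] <- if (length(ccCov)) max(ccCov) else 0
    cells$class[j] <- assignClass(covSE, ccCov, smallCC = smallCC, full = full)
    cells$cellScore[j] <- scoreCell(cells$class[j])
  }
  list(cells = cells, interfaces = itab,
       veinScore = scoreVein(cells$class), wallThreshold = thr)
}
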