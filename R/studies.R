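## Simulation studies: parameter-recovery and calibration experiments run
## against the synthetic generator. These drivers are shared between the
## test suite and the reproduction script so the same code path produces
## both. Problem sizes are arguments with defaults matching the package's
## standard study conditions.

.studySeed <- function(seed, i, stride = 1000L) {
  as.integer((as.numeric(seed) * stride + as.numeric(i)) %% 2147483629)
}

#' Attenuation-cancellation study of the F statistic
#'
#' Uses the twin-cell phantom ([twinPhantom()]): two identical PP cells at
#' different depths with true marker-density ratio \code{ratio}, imaged
#' noise-free under exponential depth attenuation. Channel sums are taken
#' raw over each cell's membrane ROI, so the attenuation factor cancels
#' exactly in F while the uncalibrated marker ratio S2/S1 is badly biased.
#'
#' @param ratio true marker-density ratio (deep cell over shallow cell).
#' @param coef attenuation coefficient (per um).
#' @param width ROI ribbon half-width in pixels.
#' @return List with \code{F}, \code{rawRatio} (= S2/S1), \code{trueRatio}
#'   and \code{reads}.
#' @export
fAttenuationStudy <- function(ratio = 0.84, coef = 0.15, width = 2) {
  ph <- twinPhantom(ratio = ratio)
  img <- applyAttenuation(ph$image, coef = coef)
  marker <- channel(img, "marker")
  wall <- channel(img, "wall")
  roiRef <- membraneRoi(ph$map, ph$shallow, width)
  roiTest <- membraneRoi(ph$map, ph$deep, width)
  reads <- calibrationReads(S1 = sum(marker[roiRef]),
                            S2 = sum(marker[roiTest]),
                            C1 = sum(wall[roiRef]),
                            C2 = sum(wall[roiTest]))
  list(F = relativeIntensity(reads), rawRatio = reads@S2 / reads@S1,
       trueRatio = ratio, reads = reads)
}

#' Measured F between PP transfer cells and PP cells
#'
#' Mirrors the fluorescence-intensity comparison between PP TCs and
#' non-transdifferentiated PP cells: veins with two ingrowth-free abaxial PP
#' cells whose marker densities differ by the factor \code{rel} are
#' generated at the default noise level and measured with the full 8-bit /
#' default-threshold path ([measureCellPair()]).
#'
#' @param nSeeds number of replicate veins.
#' @param rel true density ratio of the test cell.
#' @param seed base RNG seed.
#' @param imageSize image side length (px).
#' @return Numeric vector of measured F values, one per vein.
#' @export
fMeasurementStudy <- function(nSeeds = 50L, rel = 0.84, seed = 1L,
                              imageSize = 256L) {
  vapply(seq_len(nSeeds), function(i) {
    cfg <- veinConfig(
      ingrowth = rep(list(ingrowthSpec(se = 0, cc = 0, k = 1)), 2L),
      ppMarkerRel = c(1, rel), imageSize = imageSize,
      seed = .studySeed(seed, i))
    vt <- generateVein(cfg)
    cells <- vt$truth@cells
    ppIdx <- cells$ppIndex
    refCell <- cells$label[!is.na(ppIdx) & ppIdx == 1L]
    testCell <- cells$label[!is.na(ppIdx) & ppIdx == 2L]
    measureCellPair(vt$image, vt$truth@cellMap, refCell, testCell)$F
  }, numeric(1L))
}

#' FC parameter-recovery study
#'
#' Veins with PP transfer cells whose SE interface is fully covered at
#' membrane amplification k are generated at the default noise level; FC is
#' measured between the SE interface (ingrowth side) and the cell's longest
#' deposition-free interface (reference side).
#'
#' @param ks amplification factors to recover.
#' @param nSeeds replicate veins per k.
#' @param seed base RNG seed.
#' @param imageSize image side length (px); the default leaves room for the
#'   thickest rendered ingrowths.
#' @return data.frame with columns \code{k}, \code{medianFC} and
#'   \code{fc} (list column of per-seed values).
#' @export
fcRecoveryStudy <- function(ks = c(1, 2, 3, 5), nSeeds = 50L, seed = 1L,
                            imageSize = 512L) {
  res <- lapply(ks, function(k) {
    vapply(seq_len(nSeeds), function(i) {
      cfg <- veinConfig(
        ingrowth = rep(list(ingrowthSpec(se = 1, cc = 0, k = k)), 2L),
        imageSize = imageSize, seed = .studySeed(seed, i + 10000L * match(k, ks)))
      vt <- generateVein(cfg)
      map <- vt$truth@cellMap
      cells <- vt$truth@cells
      itab <- vt$truth@interfaces
      p <- cells$label[!is.na(cells$ppIndex) & cells$ppIndex == 1L]
      mine <- itab[itab$cellA == p | itab$cellB == p, , drop = FALSE]
      seIf <- mine[(mine$typeA == "SE" | mine$typeB == "SE") &
                     mine$coverage > 0, , drop = FALSE][1L, ]
      free <- mine[mine$coverage == 0, , drop = FALSE]
      free <- free[which.max(free$nFaces), ]
      ingrowthIf <- extractInterface(map, seIf$cellA, seIf$cellB)
      refIf <- extractInterface(map, free$cellA, free$cellB)
      measureEnrichment(vt$image, map, p, ingrowthIf, refIf)$FC
    }, numeric(1L))
  })
  data.frame(k = ks, medianFC = vapply(res, stats::median, numeric(1L)),
             fc = I(res))
}

#' Class I--V recovery study
#'
#' Generates veins from the five canonical class presets and asks the full
#' measurement pipeline ([measureVein()]) to recover each PP cell's class.
#'
#' @param nPerClass replicate veins per class.
#' @param noiseSd noise level; \code{NULL} uses the generator default.
#' @param seed base RNG seed.
#' @param imageSize image side length (px).
#' @return List with \code{accuracy} (fraction of PP cells classified
#'   correctly), \code{n} (cells judged) and the \code{confusion} table.
#' @export
classRecoveryStudy <- function(nPerClass = 40L, noiseSd = NULL, seed = 1L,
                               imageSize = 256L) {
  truthV <- character(); predV <- character()
  for (cl in .CLASSES) {
    for (i in seq_len(nPerClass)) {
      args <- list(class = cl, imageSize = imageSize,
                   seed = .studySeed(seed, i + 1000L * match(cl, .CLASSES)))
      if (!is.null(noiseSd)) args$noiseSd <- noiseSd
      cfg <- do.call(classPreset, args)
      vt <- generateVein(cfg)
      meas <- measureVein(vt$image, vt$truth@cellMap)
      truthV <- c(truthV, rep(cl, nrow(meas$cells)))
      predV <- c(predV, meas$cells$class)
    }
  }
  list(accuracy = mean(truthV == predV), n = length(truthV),
       confusion = table(truth = truthV, predicted = predV))
}

#' Coverage-fraction recovery study
#'
#' Random ingrowth coverages are configured, rendered noise-free, and
#' re-measured by the detection pipeline; recovery error is reported in
#' face-lengths per interface. Configured coverages are drawn from {0}
#' union [0.2, 1] at the canonical three-fold amplification: arcs shorter
#' than the three-face despeckle run are not a detectable signal by
#' construction. Arcs whose ends fall inside the junction hysteresis zone
#' (the outer \code{endMargin} faces of an interface) are scored by run
#' continuation there and may be extended to the junction; the returned
#' \code{endDistance} column (faces between the configured arc end and the
#' interface end) lets callers separate interior arcs, which recover within
#' a face, from junction-reaching arcs.
#'
#' @param nConfigs number of random configurations.
#' @param seed base RNG seed.
#' @param imageSize image side length (px).
#' @param noiseSd noise level (default 0: noise-free recovery).
#' @return data.frame with one row per assessed interface: configured and
#'   measured coverage, face count, and the error in face units.
#' @export
coverageRecoveryStudy <- function(nConfigs = 100L, seed = 1L,
                                  imageSize = 256L, noiseSd = 0) {
  rows <- list()
  for (i in seq_len(nConfigs)) {
    set.seed(.studySeed(seed, i))
    rcov <- function() {
      if (stats::runif(1) < 0.25) 0 else stats::runif(1, 0.2, 1)
    }
    spec1 <- ingrowthSpec(se = rcov(), cc = c(rcov(), rcov()), k = 3)
    spec2 <- ingrowthSpec(se = rcov(), cc = rcov(), k = 3)
    cfg <- veinConfig(ingrowth = list(spec1, spec2), noiseSd = noiseSd,
                      imageSize = imageSize, seed = .studySeed(seed, i))
    vt <- generateVein(cfg)
    meas <- measureVein(vt$image, vt$truth@cellMap)
    tru <- vt$truth@interfaces
    mi <- meas$interfaces
    key <- paste(tru$cellA, tru$cellB)
    mkey <- paste(mi$cellA, mi$cellB)
    assessed <- !is.na(mi$coverage)
    m <- mi[assessed, , drop = FALSE]
    t2 <- tru[match(paste(m$cellA, m$cellB), key), , drop = FALSE]
    rows[[i]] <- data.frame(
      config = i, cellA = m$cellA, cellB = m$cellB, nFaces = t2$nFaces,
      configured = t2$coverage, measured = m$coverage,
      errFaces = abs(m$coverage - t2$coverage) * t2$nFaces,
      endDistance = floor((1 - t2$coverage) * t2$nFaces / 2))
  }
  do.call(rbind, rows)
}

#' Cohort position-recovery study
#'
#' Generates synthetic cohorts in which each PP cell is abaxially placed
#' with probability \code{pAbaxial} (defaulting to the 200/339 survey
#' proportion), classifies positions from the geometry alone, and checks
#' whether each cohort's exact binomial (Clopper--Pearson) 95% interval for
#' the abaxial percentage covers the generating probability.
#'
#' @param nCohorts number of cohort replicates.
#' @param nVeins veins per cohort.
#' @param pAbaxial abaxial placement probability per PP cell.
#' @param seed base RNG seed.
#' @param imageSize image side length (px); geometry only, so small images
#'   suffice.
#' @return List with \code{covered} (cohorts whose CI covers
#'   \code{pAbaxial}), \code{nCohorts}, \code{pctAbaxial} (per-cohort
#'   integer percentages) and \code{pAbaxial}.
#' @export
cohortPositionStudy <- function(nCohorts = 100L, nVeins = 156L,
                                pAbaxial = 200 / 339, seed = 1L,
                                imageSize = 96L) {
  pcts <- integer(nCohorts)
  covered <- logical(nCohorts)
  for (cohort in seq_len(nCohorts)) {
    set.seed(.studySeed(seed, cohort))
    nAb <- 0L; nTot <- 0L
    for (v in seq_len(nVeins)) {
      pos <- ifelse(stats::runif(2L) < pAbaxial, "abaxial", "adaxial")
      cfg <- veinConfig(
        ppPositions = pos,
        ingrowth = rep(list(ingrowthSpec(se = 0, cc = 0, k = 1)), 2L),
        imageSize = imageSize,
        seed = .studySeed(seed, cohort * 10000L + v, stride = 1L))
      geo <- generateCellMap(cfg)
      map <- geo$map
      graph <- buildAdjacency(map)
      axis <- abaxialAxis(map)
      pp <- geo$cells$label[geo$cells$type == "PP"]
      cls <- .classifyPositions(pp, graph, map, axis)
      nAb <- nAb + sum(cls$position == "abaxial")
      nTot <- nTot + length(pp)
    }
    pcts[cohort] <- percentage(nAb, nTot)
    ci <- stats::binom.test(nAb, nTot)$conf.int
    covered[cohort] <- pAbaxial >= ci[1L] && pAbaxial <= ci[2L]
  }
  list(covered = sum(covered), nCohorts = nCohorts, pctAbaxial = pcts,
       pAbaxial = pAbaxial)
}

#' Type-I error calibration of the Student's t-test
#'
#' Monte-Carlo rejection rate of [twoSampleT()] under the null (two equal-
#' mean normal samples) at a given significance level.
#'
#' @param nReps Monte-Carlo replicates.
#' @param n per-group sample size.
#' @param alpha significance level.
#' @param seed RNG seed.
#' @return List with \code{rate}, \code{nReps}, \code{alpha}.
#' @export
tTestCalibration <- function(nReps = 10000L, n = 10L, alpha = 0.05,
                             seed = 1L) {
  set.seed(seed)
  rej <- vapply(seq_len(nReps), function(i) {
    twoSampleT(stats::rnorm(n), stats::rnorm(n))$p < alpha
  }, logical(1L))
  list(rate = mean(rej), nReps = nReps, alpha = alpha)
}
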