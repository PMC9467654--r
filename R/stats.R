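## Survey statistics over per-cell / per-vein measurements: tallies,
## percentages, Student's t comparisons, correlation reporting and
## cohort-level aggregation.

#' Round half away from zero
#' @noRd
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Integer percentage
#'
#' \code{round(100 n / N)} to the nearest integer, halves away from zero
#' (so 200 of 339 gives 59).
#'
#' @param n count of events (0 <= n <= N).
#' @param N total count (> 0).
#' @return Integer percentage.
#' @examples
#' percentage(200, 339)  # 59
#' percentage(139, 339)  # 41
#' @export
percentage <- function(n, N) {
  if (N <= 0) stop("N must be positive")
  if (n < 0 || n > N) stop("n must lie in [0, N]")
  as.integer(.roundHalfAway(100 * n / N))
}

#' Two-sample Student's t-test
#'
#' Pooled-variance Student's t by default (Welch behind the \code{pooled}
#' flag), two-sided p-value. Degenerate input with zero pooled variance and
#' equal means reports t = 0, p = 1 with a warning.
#'
#' @param x,y numeric samples of size >= 2.
#' @param pooled use the pooled-variance statistic (default TRUE); FALSE
#'   gives the Welch variant.
#' @return List with \code{t}, \code{df} and \code{p}.
#' @examples
#' twoSampleT(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))  # t = -1, df = 8
#' @export
twoSampleT <- function(x, y, pooled = TRUE) {
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs >= 2 values")
  if (!all(is.finite(c(x, y)))) stop("samples must be finite")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    df <- length(x) + length(y) - 2L
    if (mean(x) == mean(y)) {
      warning("zero variance with equal means: reporting t = 0, p = 1")
      return(list(t = 0, df = df, p = 1))
    }
    warning("zero variance with different means: reporting |t| = Inf, p = 0")
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = df, p = 0))
  }
  res <- stats::t.test(x, y, var.equal = pooled)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Correlation between PP-TC count and vein size
#'
#' Pearson r with its two-sided p-value, reported (not asserted) -- used to
#' examine whether the number of PP transfer cells scales with
#' vascular-bundle area.
#'
#' @param nPpTc per-vein PP-TC counts (length >= 3).
#' @param veinArea per-vein xylem+phloem areas (um^2).
#' @return List with \code{r}, \code{p} and \code{n}.
#' @export
correlationCheck <- function(nPpTc, veinArea) {
  if (length(nPpTc) != length(veinArea)) stop("inputs must have equal length")
  if (length(nPpTc) < 3L) stop("need at least 3 veins")
  if (stats::sd(nPpTc) == 0 || stats::sd(veinArea) == 0)
    stop("undefined correlation: constant input")
  res <- stats::cor.test(nPpTc, veinArea)
  list(r = unname(res$estimate), p = res$p.value, n = length(nPpTc))
}

#' Summarise one measured vein
#'
#' Deterministic tallies over the outputs of [measureVein()]: cell counts
#' per type, PP transfer cells (PP with deposition class >= II), vein area,
#' per-PP position and score, the numbers of CCs/SEs abutting each PP TC
#' and how many of those abut wall ingrowths (interface coverage > 0), and
#' PP/SE vs PP/CC interface length and coverage statistics.
#'
#' @param map the vein's [CellMap-class].
#' @param cells per-cell data.frame from [measureVein()].
#' @param interfaces per-interface data.frame from [measureVein()].
#' @return List of class \code{VeinSummary}.
#' @export
summarizeVein <- function(map, cells, interfaces) {
  ty <- cellTypes(map)
  if (!all(cells$label %in% as.integer(names(ty))))
    stop("inconsistent label sets between map and cell table")
  if (nrow(interfaces)) {
    known <- c(interfaces$cellA, interfaces$cellB) %in% as.integer(names(ty))
    if (!all(known)) stop("inconsistent label sets in interface table")
  }
  counts <- vapply(c("XY", "SE", "CC", "PP"),
                   function(t) sum(ty == t), integer(1L))
  isTC <- cells$cellScore >= 1L
  tcLabels <- cells$label[isTC]
  pairType <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "/")
  it <- interfaces
  it$pair <- pairType(it$typeA, it$typeB)
  ppse <- it[it$pair == "PP/SE", , drop = FALSE]
  ppcc <- it[it$pair == "CC/PP", , drop = FALSE]
  abutting <- data.frame(label = tcLabels,
                         nCC = 0L, nSE = 0L, nCCIngrowth = 0L, nSEIngrowth = 0L)
  for (j in seq_along(tcLabels)) {
    p <- tcLabels[j]
    mine <- it[it$cellA == p | it$cellB == p, , drop = FALSE]
    pt <- ifelse(mine$cellA == p, mine$typeB, mine$typeA)
    cov <- mine$coverage
    abutting$nCC[j] <- sum(pt == "CC")
    abutting$nSE[j] <- sum(pt == "SE")
    abutting$nCCIngrowth[j] <- sum(pt == "CC" & !is.na(cov) & cov > 0)
    abutting$nSEIngrowth[j] <- sum(pt == "SE" & !is.na(cov) & cov > 0)
  }
  structure(list(
    counts = counts,
    nPpTc = sum(isTC),
    veinArea = veinSize(map),
    pp = cells[, c("label", "position", "coverageSE", "maxCoverageCC",
                   "class", "cellScore")],
    veinScore = scoreVein(cells$class),
    abutting = abutting,
    interfaceStats = data.frame(
      pair = c("PP/SE", "PP/CC"),
      n = c(nrow(ppse), nrow(ppcc)),
      meanLengthUm = c(mean(ppse$lengthUm), mean(ppcc$lengthUm)),
      meanCoverage = c(mean(ppse$coverage, na.rm = TRUE),
                       mean(ppcc$coverage, na.rm = TRUE)),
      meanCoveredLengthUm = c(mean(ppse$coveredLengthUm, na.rm = TRUE),
                              mean(ppcc$coveredLengthUm, na.rm = TRUE)))),
    class = "VeinSummary")
}

#' @export
print.VeinSummary <- function(x, ...) {
  cat(sprintf("VeinSummary: %s | %d PP TC(s), area %.1f um^2, score %d\n",
              paste(sprintf("%s:%d", names(x$counts), x$counts), collapse = " "),
              x$nPpTc, x$veinArea, x$veinScore))
  invisible(x)
}

#' Aggregate a cohort of vein summaries
#'
#' Cohort-level survey statistics: mean cell counts per type, the
#' percentage of abaxially positioned PP TCs, the share of veins with more
#' than two PP TCs, mean PP/SE and PP/CC interface lengths and coverages,
#' the fraction of CC neighbours of PP TCs that abut wall ingrowths, and
#' Student's t comparisons (abaxial vs adaxial cell scores; PP/SE vs PP/CC
#' covered lengths) where both groups have >= 2 values.
#'
#' @param summaries list of \code{VeinSummary} objects (may be empty).
#' @return List of class \code{CohortSummary}.
#' @export
cohortSummary <- function(summaries) {
  n <- length(summaries)
  empty <- list(nVeins = 0L,
                meanCounts = c(XY = NA_real_, SE = NA_real_, CC = NA_real_,
                               PP = NA_real_),
                nPpTcTotal = 0L, pctAbaxialPpTc = NA_integer_,
                pctVeinsMultiPpTc = NA_integer_,
                fracCcAbuttingIngrowth = NA_real_,
                meanLengthPpSe = NA_real_, meanLengthPpCc = NA_real_,
                meanCoveragePpSe = NA_real_, meanCoveragePpCc = NA_real_,
                tTests = list())
  if (n == 0L) return(structure(empty, class = "CohortSummary"))
  counts <- t(vapply(summaries, `[[`, numeric(4L), "counts"))
  pp <- do.call(rbind, lapply(summaries, `[[`, "pp"))
  tc <- pp[pp$cellScore >= 1L, , drop = FALSE]
  ab <- do.call(rbind, lapply(summaries, `[[`, "abutting"))
  istat <- do.call(rbind, lapply(summaries, `[[`, "interfaceStats"))
  se <- istat[istat$pair == "PP/SE", , drop = FALSE]
  cc <- istat[istat$pair == "PP/CC", , drop = FALSE]
  wm <- function(v, w) if (sum(w) > 0) sum(v * w, na.rm = TRUE) / sum(w) else NA_real_
  tTests <- list()
  sAb <- tc$cellScore[tc$position == "abaxial"]
  sAd <- tc$cellScore[tc$position == "adaxial"]
  if (length(sAb) >= 2L && length(sAd) >= 2L)
    tTests$scoreAbaxialVsAdaxial <- twoSampleT(sAb, sAd)
  covSe <- se$meanCoveredLengthUm[is.finite(se$meanCoveredLengthUm)]
  covCc <- cc$meanCoveredLengthUm[is.finite(cc$meanCoveredLengthUm)]
  if (length(covSe) >= 2L && length(covCc) >= 2L)
    tTests$coveredLengthSeVsCc <- twoSampleT(covSe, covCc)
  structure(list(
    nVeins = n,
    meanCounts = colMeans(counts),
    nPpTcTotal = nrow(tc),
    pctAbaxialPpTc = if (nrow(tc) > 0)
      percentage(sum(tc$position == "abaxial"), nrow(tc)) else NA_integer_,
    pctVeinsMultiPpTc = percentage(
      sum(vapply(summaries, `[[`, integer(1L), "nPpTc") > 2L), n),
    fracCcAbuttingIngrowth = if (sum(ab$nCC) > 0)
      sum(ab$nCCIngrowth) / sum(ab$nCC) else NA_real_,
    meanLengthPpSe = wm(se$meanLengthUm, se$n),
    meanLengthPpCc = wm(cc$meanLengthUm, cc$n),
    meanCoveragePpSe = wm(se$meanCoverage, se$n),
    meanCoveragePpCc = wm(cc$meanCoverage, cc$n),
    tTests = tTests), class = "CohortSummary")
}

#' @export
print.CohortSummary <- function(x, ...) {
  cat(sprintf("CohortSummary: %d veins, %d PP TCs (%s%% abaxial)\n",
              x$nVeins, x$nPpTcTotal,
              ifelse(is.na(x$pctAbaxialPpTc), "NA", x$pctAbaxialPpTc)))
  invisible(x)
}
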