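## File-format plumbing: multi-page TIFF images, label-map TIFF + type CSV,
## interface/cell CSV tables, YAML configs and JSON run summaries, plus the
## generate / measure / cohort entry points used by the command-line
## wrapper in inst/scripts/veintc.R.

.TIFF_MAX <- 65535

#' Write a vein image as multi-page 16-bit TIFF
#'
#' One page per channel; intensities are stored as-is (clamped to the
#' uint16 range), so arbitrary-unit images survive a round trip exactly
#' when their values are integers below 65536.
#'
#' @param image a [VeinImage-class].
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeVeinImage <- function(image, path) {
  chs <- lapply(seq_len(nChannels(image)), function(i)
    pmin(pmax(round(channel(image, i)), 0), .TIFF_MAX) / .TIFF_MAX)
  tiff::writeTIFF(chs, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' Read a vein image written by [writeVeinImage()]
#'
#' @param path TIFF file with one page per channel.
#' @param pixelSize micrometres per pixel (TIFF carries no calibrated size).
#' @param channelNames optional channel names.
#' @return A [VeinImage-class].
#' @export
readVeinImage <- function(path, pixelSize, channelNames = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  VeinImage(lapply(pages, function(p) p * 1.0), pixelSize, channelNames)
}

#' Write a cell map (label TIFF + type CSV)
#'
#' @param map a [CellMap-class].
#' @param tiffPath label image output (16-bit single page).
#' @param csvPath type table output with columns label, type.
#' @return Invisibly, the two paths.
#' @export
writeCellMap <- function(map, tiffPath, csvPath) {
  lab <- cellLabels(map)
  if (max(lab) > .TIFF_MAX) stop("too many labels for a 16-bit TIFF")
  tiff::writeTIFF(lab / .TIFF_MAX, tiffPath, bits.per.sample = 16L)
  utils::write.csv(map@types, csvPath, row.names = FALSE)
  invisible(c(tiffPath, csvPath))
}

#' Read a cell map written by [writeCellMap()]
#'
#' @param tiffPath label TIFF.
#' @param csvPath type CSV with columns label, type.
#' @param pixelSize micrometres per pixel.
#' @return A [CellMap-class].
#' @export
readCellMap <- function(tiffPath, csvPath, pixelSize) {
  if (!file.exists(tiffPath)) stop("label image not found: ", tiffPath)
  if (!file.exists(csvPath)) stop("type table not found: ", csvPath)
  lab <- tiff::readTIFF(tiffPath, as.is = TRUE)
  types <- utils::read.csv(csvPath, stringsAsFactors = FALSE)
  if (!all(c("label", "type") %in% names(types)))
    stop("malformed type table ", csvPath, ": need columns 'label', 'type'")
  cellMap(lab, pixelSize, types)
}

#' Write / read a generator configuration as YAML
#'
#' @param config a [VeinConfig-class].
#' @param path YAML file.
#' @return \code{writeVeinConfig}: the path, invisibly;
#'   \code{readVeinConfig}: a [VeinConfig-class].
#' @export
writeVeinConfig <- function(config, path) {
  lst <- list(nCells = as.list(config@nCells),
              ppPositions = config@ppPositions,
              ingrowth = config@ingrowth,
              markerDensity = config@markerDensity,
              ppMarkerRel = config@ppMarkerRel,
              attenuationCoef = config@attenuationCoef,
              pixelSize = config@pixelSize, noiseSd = config@noiseSd,
              wallAmp = config@wallAmp, wallHalfWidth = config@wallHalfWidth,
              imageSize = config@imageSize, seed = config@seed)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writeVeinConfig
#' @export
readVeinConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lst <- yaml::read_yaml(path)
  need <- c("nCells", "ppPositions", "ingrowth")
  miss <- setdiff(need, names(lst))
  if (length(miss))
    stop("malformed config ", path, ": missing field(s) ",
         paste(miss, collapse = ", "))
  veinConfig(nCells = unlist(lst$nCells),
             ppPositions = unlist(lst$ppPositions),
             ingrowth = lapply(lst$ingrowth, function(s)
               ingrowthSpec(se = s$se, cc = unlist(s$cc), k = s$k)),
             markerDensity = lst$markerDensity %||% 300,
             ppMarkerRel = unlist(lst$ppMarkerRel %||%
                                    rep(1, length(lst$ppPositions))),
             attenuationCoef = lst$attenuationCoef %||% 0,
             pixelSize = lst$pixelSize %||% 0.2,
             noiseSd = lst$noiseSd %||% 6,
             wallAmp = lst$wallAmp %||% 180,
             wallHalfWidth = lst$wallHalfWidth %||% 0.4,
             imageSize = lst$imageSize %||% 512L,
             seed = lst$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Audit hash of a configuration (md5 of its YAML serialisation).
.configHash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeVeinConfig(config, tf)
  unname(tools::md5sum(tf))
}

.writeRunInfo <- function(path, config, extra = list()) {
  info <- c(list(seed = config@seed, configHash = .configHash(config)), extra)
  jsonlite::write_json(info, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Generate a synthetic vein and write it to disk
#'
#' Writes the two-channel image, label map, per-cell and per-interface
#' truth tables, the configuration and a run-info JSON (seed and config
#' hash) into \code{outDir}.
#'
#' @param config a [VeinConfig-class] or path to a YAML config.
#' @param outDir output directory (created if needed).
#' @return Invisibly, the [generateVein()] result.
#' @export
runGenerate <- function(config, outDir) {
  if (is.character(config)) config <- readVeinConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  vt <- generateVein(config)
  writeVeinImage(vt$image, file.path(outDir, "image.tif"))
  writeCellMap(vt$truth@cellMap, file.path(outDir, "labels.tif"),
               file.path(outDir, "types.csv"))
  utils::write.csv(vt$truth@cells, file.path(outDir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(vt$truth@interfaces, file.path(outDir, "interfaces.csv"),
                   row.names = FALSE)
  writeVeinConfig(config, file.path(outDir, "config.yaml"))
  .writeRunInfo(file.path(outDir, "run_info.json"), config)
  invisible(vt)
}

#' Measure a vein from files (or objects) and write result tables
#'
#' Runs [measureVein()] and writes per-cell and per-interface CSVs plus a
#' JSON summary (vein score, wall threshold, seed, config hash when the
#' vein came from the generator).
#'
#' @param image a [VeinImage-class] or path to an image TIFF.
#' @param map a [CellMap-class], or the label TIFF path when \code{typesCsv}
#'   is given.
#' @param outDir output directory.
#' @param typesCsv type table path (when reading the map from files).
#' @param pixelSize micrometres per pixel (needed when reading from files).
#' @param config optional [VeinConfig-class] recorded in the run info.
#' @param ... further arguments for [measureVein()].
#' @return Invisibly, the [measureVein()] result.
#' @export
runMeasure <- function(image, map, outDir, typesCsv = NULL, pixelSize = NULL,
                       config = NULL, ...) {
  if (is.character(image)) {
    if (is.null(pixelSize)) stop("pixelSize is required when reading files")
    image <- readVeinImage(image, pixelSize)
  }
  if (is.character(map)) {
    if (is.null(typesCsv)) stop("typesCsv is required when reading files")
    map <- readCellMap(map, typesCsv, pixelSize %||% pixelSize(image))
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  meas <- measureVein(image, map, ...)
  utils::write.csv(meas$cells, file.path(outDir, "cells_measured.csv"),
                   row.names = FALSE)
  utils::write.csv(meas$interfaces,
                   file.path(outDir, "interfaces_measured.csv"),
                   row.names = FALSE)
  summary <- list(veinScore = meas$veinScore,
                  wallThreshold = meas$wallThreshold,
                  nPpTc = sum(meas$cells$cellScore >= 1L))
  if (!is.null(config)) {
    summary$seed <- config@seed
    summary$configHash <- .configHash(config)
  }
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(meas)
}

#' Generate and measure a cohort of synthetic veins
#'
#' Loops generate-and-measure over a list of configurations, writes one
#' cohort CSV row per vein and the aggregated [cohortSummary()] as JSON.
#' An empty configuration list yields a valid empty report.
#'
#' @param configs list of [VeinConfig-class] objects (possibly empty).
#' @param outDir output directory.
#' @param ... further arguments for [measureVein()].
#' @return Invisibly, the \code{CohortSummary}.
#' @export
runCohort <- function(configs, outDir, ...) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  summaries <- vector("list", length(configs))
  rows <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    vt <- generateVein(configs[[i]])
    meas <- measureVein(vt$image, vt$truth@cellMap, ...)
    vs <- summarizeVein(vt$truth@cellMap, meas$cells, meas$interfaces)
    summaries[[i]] <- vs
    rows[[i]] <- data.frame(
      vein = i, seed = configs[[i]]@seed, nPpTc = vs$nPpTc,
      veinScore = vs$veinScore, veinAreaUm2 = vs$veinArea,
      nXY = vs$counts[["XY"]], nSE = vs$counts[["SE"]],
      nCC = vs$counts[["CC"]], nPP = vs$counts[["PP"]])
  }
  cohort <- cohortSummary(summaries)
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(vein = integer(), seed = integer(), nPpTc = integer(),
               veinScore = integer(), veinAreaUm2 = numeric(),
               nXY = integer(), nSE = integer(), nCC = integer(),
               nPP = integer())
  utils::write.csv(tab, file.path(outDir, "cohort.csv"), row.names = FALSE)
  out <- cohort
  out$tTests <- lapply(out$tTests, function(t) t[c("t", "df", "p")])
  jsonlite::write_json(out, file.path(outDir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(cohort)
}
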