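## Accessor and show methods for the core classes.

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "VeinImage", function(x) x@pixelSize)

#' @rdname pixelSize
#' @export
setMethod("pixelSize", "CellMap", function(x) x@pixelSize)

#' @rdname channel
#' @export
setMethod("channel", "VeinImage", function(x, which) {
  if (is.character(which)) which <- match(which, x@channelNames)
  if (is.na(which) || which < 1L || which > dim(x@pixels)[3L])
    stop("no such channel")
  x@pixels[, , which]
})

#' @rdname nChannels
#' @export
setMethod("nChannels", "VeinImage", function(x) dim(x@pixels)[3L])

#' @rdname cellLabels
#' @export
setMethod("cellLabels", "CellMap", function(x) x@labels)

#' @rdname cellTypes
#' @export
setMethod("cellTypes", "CellMap", function(x)
  stats::setNames(x@types$type, x@types$label))

setMethod("show", "VeinImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("VeinImage: %d x %d px (%.3g x %.3g um), %d channel(s): %s\n",
              d[1L], d[2L], d[1L] * object@pixelSize, d[2L] * object@pixelSize,
              d[3L], paste(object@channelNames, collapse = ", ")))
})

setMethod("show", "CellMap", function(object) {
  tab <- table(factor(object@types$type, levels = .CELL_TYPES))
  cat(sprintf("CellMap: %d x %d px, %d cells (%s)\n",
              nrow(object@labels), ncol(object@labels), nrow(object@types),
              paste(sprintf("%s:%d", names(tab)[tab > 0], tab[tab > 0]),
                    collapse = " ")))
})

setMethod("show", "Interface", function(object) {
  cat(sprintf("Interface %d/%d: %d faces, %.3g um, covered %.3g um (%.1f%%)\n",
              object@cellA, object@cellB, nrow(object@faces), object@lengthUm,
              object@coveredLengthUm,
              100 * object@coveredLengthUm / object@lengthUm))
})

setMethod("show", "VeinConfig", function(object) {
  cat(sprintf(
    "VeinConfig: %s | PP positions: %s | %d x %d px @ %.3g um, noise sd %.3g, seed %d\n",
    paste(sprintf("%s:%d", names(object@nCells), object@nCells), collapse = " "),
    paste(object@ppPositions, collapse = ","), object@imageSize,
    object@imageSize, object@pixelSize, object@noiseSd, object@seed))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d cells, %d interfaces (%d with ingrowth)\n",
              nrow(object@cells), nrow(object@interfaces),
              sum(object@interfaces$coverage > 0)))
})

setMethod("show", "CalibrationReads", function(object) {
  cat(sprintf("CalibrationReads: S1=%.4g S2=%.4g C1=%.4g C2=%.4g\n",
              object@S1, object@S2, object@C1, object@C2))
})

setMethod("show", "EnrichmentReads", function(object) {
  cat(sprintf("EnrichmentReads: A1=%.4g A2=%.4g L1=%.4g um L2=%.4g um\n",
              object@A1, object@A2, object@L1, object@L2))
})
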