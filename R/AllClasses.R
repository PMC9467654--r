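## Central data containers. Cell types follow the minor-vein inventory:
## XY xylem, SE sieve element, CC companion cell, PP phloem parenchyma,
## BS bundle sheath, OTHER anything else.

.CELL_TYPES <- c("XY", "SE", "CC", "PP", "BS", "OTHER")
.PHLOEM_TYPES <- c("SE", "CC", "PP")
.POSITIONS <- c("abaxial", "middle", "adaxial")
.CLASSES <- c("I", "II", "III", "IV", "V")

#' VeinImage: a multi-channel vein cross-section
#'
#' Pixel grid of a 2D confocal cross-section. By convention channel 1 is the
#' general wall stain (calcofluor-white-like) and channel 2 the membrane
#' marker (AtSWEET11--GFP-like). Rows run adaxial (row 1, deep in the light
#' path) to abaxial (last row, closest to the objective).
#'
#' @slot pixels numeric array \code{[rows, cols, channels]}, non-negative.
#' @slot pixelSize pixel edge length in micrometres.
#' @slot channelNames one name per channel.
#' @export
setClass("VeinImage",
  slots = c(pixels = "array", pixelSize = "numeric", channelNames = "character"))

setValidity("VeinImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L) return("'pixels' must be a 3D array [rows, cols, channels]")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0) return("'pixelSize' must be a single positive number")
  if (length(object@channelNames) != d[3L])
    return("'channelNames' must name every channel")
  if (any(object@pixels < 0)) return("pixel intensities must be non-negative")
  TRUE
})

#' Construct a VeinImage
#'
#' @param pixels 3D numeric array \code{[rows, cols, channels]} or a list of
#'   equally sized matrices (one per channel).
#' @param pixelSize micrometres per pixel.
#' @param channelNames channel names; defaults to \code{c("wall", "marker")}
#'   for two channels.
#' @return A [VeinImage-class] object.
#' @examples
#' img <- VeinImage(array(0, c(8, 8, 2)), pixelSize = 0.2)
#' nChannels(img)
#' @export
VeinImage <- function(pixels, pixelSize, channelNames = NULL) {
  if (is.list(pixels))
    pixels <- array(unlist(pixels), dim = c(dim(pixels[[1L]]), length(pixels)))
  if (is.null(channelNames)) {
    channelNames <- if (dim(pixels)[3L] == 2L) c("wall", "marker") else
      paste0("ch", seq_len(dim(pixels)[3L]))
  }
  methods::new("VeinImage", pixels = pixels, pixelSize = as.numeric(pixelSize),
               channelNames = channelNames)
}

#' CellMap: integer label map with cell-type annotation
#'
#' @slot labels integer matrix; 0 is background, each positive label one cell.
#' @slot pixelSize micrometres per pixel.
#' @slot types data.frame with columns \code{label} and \code{type}
#'   (one of XY, SE, CC, PP, BS, OTHER) covering every non-zero label.
#' @export
setClass("CellMap",
  slots = c(labels = "matrix", pixelSize = "numeric", types = "data.frame"))

setValidity("CellMap", function(object) {
  lab <- object@labels
  if (!is.numeric(lab)) return("'labels' must be an integer matrix")
  if (any(lab < 0) || any(lab != round(lab))) return("labels must be non-negative integers")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    return("'pixelSize' must be a single positive number")
  tt <- object@types
  if (!all(c("label", "type") %in% names(tt)))
    return("'types' needs columns 'label' and 'type'")
  present <- sort(unique(lab[lab > 0]))
  if (!all(present %in% tt$label))
    return("every non-zero label must appear in 'types'")
  if (anyDuplicated(tt$label)) return("duplicated labels in 'types'")
  if (!all(tt$type %in% .CELL_TYPES))
    return(paste("cell types must be one of:", paste(.CELL_TYPES, collapse = ", ")))
  TRUE
})

#' Construct a CellMap
#'
#' @param labels integer matrix (0 = background).
#' @param pixelSize micrometres per pixel.
#' @param types data.frame with columns \code{label}, \code{type}.
#' @return A [CellMap-class] object.
#' @examples
#' lab <- matrix(rep(1:2, each = 8), 4, 4)
#' cm <- cellMap(lab, 0.2, data.frame(label = 1:2, type = c("PP", "SE")))
#' cellTypes(cm)
#' @export
cellMap <- function(labels, pixelSize, types) {
  storage.mode(labels) <- "integer"
  types$label <- as.integer(types$label)
  types$type <- as.character(types$type)
  methods::new("CellMap", labels = labels, pixelSize = as.numeric(pixelSize),
               types = types)
}

#' Interface: the shared boundary between two labelled cells
#'
#' The boundary is the set of pixel faces separating the two cells under
#' 4-connectivity; its physical length is the face count times the pixel
#' size (a Manhattan measure, documented in the methods vignette). Faces are
#' ordered along the boundary; \code{ingrowthMask} flags faces covered by
#' wall-ingrowth deposition.
#'
#' @slot cellA,cellB the two labels, with \code{cellA < cellB}.
#' @slot faces data.frame (ordered along the boundary) with pixel coordinates
#'   \code{ra, ca} on the \code{cellA} side and \code{rb, cb} on the
#'   \code{cellB} side of each face.
#' @slot lengthUm physical boundary length in micrometres.
#' @slot pixelSize micrometres per pixel.
#' @slot ingrowthMask logical, one entry per face.
#' @slot coveredLengthUm flagged faces times pixel size.
#' @export
setClass("Interface",
  slots = c(cellA = "integer", cellB = "integer", faces = "data.frame",
            lengthUm = "numeric", pixelSize = "numeric",
            ingrowthMask = "logical", coveredLengthUm = "numeric"))

setValidity("Interface", function(object) {
  if (object@cellA >= object@cellB) return("cellA must be < cellB")
  n <- nrow(object@faces)
  if (n < 1L) return("an interface needs at least one face")
  if (object@lengthUm <= 0) return("length must be positive")
  if (length(object@ingrowthMask) != n)
    return("ingrowthMask must have one entry per face")
  if (object@coveredLengthUm < 0 || object@coveredLengthUm > object@lengthUm + 1e-9)
    return("covered length must lie in [0, length]")
  TRUE
})

#' VeinConfig: parameters of the synthetic vein generator
#'
#' Describes one synthetic minor-vein cross-section: the cell inventory, the
#' position class of each phloem parenchyma (PP) cell, the target
#' wall-ingrowth coverage on its sieve-element (SE) and companion-cell (CC)
#' facing interfaces, marker density, depth attenuation and imaging noise.
#' Defaults portray a typical mature minor vein: two abaxial PP transfer
#' cells whose SE interface is fully covered and whose longest CC interface
#' is half covered, with three-fold wall thickening.
#'
#' @slot nCells named integer counts for XY, SE, CC, PP, BS.
#' @slot ppPositions position class per PP cell (abaxial/middle/adaxial).
#' @slot ingrowth per-PP list as built by [ingrowthSpec()]: SE-interface
#'   coverage, per-CC-interface coverages, thickness amplification k >= 1.
#' @slot markerDensity marker fluorescence per micrometre of membrane (au/um).
#' @slot ppMarkerRel per-PP relative marker density (dimensionless).
#' @slot attenuationCoef per-micrometre depth attenuation coefficient (>= 0).
#' @slot pixelSize micrometres per pixel.
#' @slot noiseSd additive Gaussian noise sigma (au).
#' @slot wallAmp wall-stain intensity of the rendered wall (au).
#' @slot wallHalfWidth primary-wall half width in micrometres.
#' @slot imageSize image side length in pixels (square image).
#' @slot seed integer RNG seed; identical configs give bit-identical output.
#' @export
setClass("VeinConfig",
  slots = c(nCells = "integer", ppPositions = "character", ingrowth = "list",
            markerDensity = "numeric", ppMarkerRel = "numeric",
            attenuationCoef = "numeric", pixelSize = "numeric",
            noiseSd = "numeric", wallAmp = "numeric", wallHalfWidth = "numeric",
            imageSize = "integer", seed = "integer"))

setValidity("VeinConfig", function(object) {
  if (!identical(sort(names(object@nCells)), sort(c("XY", "SE", "CC", "PP", "BS"))))
    return("'nCells' must be named counts for XY, SE, CC, PP, BS")
  if (any(object@nCells < 0)) return("cell counts must be >= 0")
  npp <- object@nCells[["PP"]]
  if (length(object@ppPositions) != npp)
    return("'ppPositions' must have one entry per PP cell")
  if (!all(object@ppPositions %in% .POSITIONS))
    return("PP positions must be abaxial, middle or adaxial")
  if (length(object@ingrowth) != npp)
    return("'ingrowth' must have one spec per PP cell")
  anySE <- FALSE
  for (sp in object@ingrowth) {
    if (!all(c("se", "cc", "k") %in% names(sp))) return("bad ingrowth spec")
    if (any(c(sp$se, sp$cc) < 0) || any(c(sp$se, sp$cc) > 1))
      return("coverage fractions must lie in [0, 1]")
    if (sp$k < 1) return("thickness amplification k must be >= 1")
    if (sp$se > 0) anySE <- TRUE
  }
  if (anySE && object@nCells[["SE"]] < 1L)
    return("SE-interface coverage configured but no SE cells")
  if (length(object@ppMarkerRel) != npp || any(object@ppMarkerRel < 0))
    return("'ppMarkerRel' must be one non-negative factor per PP cell")
  if (object@markerDensity < 0) return("markerDensity must be >= 0")
  if (object@attenuationCoef < 0) return("attenuationCoef must be >= 0")
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (object@wallAmp <= 0) return("wallAmp must be > 0")
  if (object@wallHalfWidth <= 0) return("wallHalfWidth must be > 0")
  if (object@imageSize < 48L) return("imageSize must be >= 48 pixels")
  TRUE
})

#' SyntheticTruth: ground truth of a generated vein
#'
#' @slot cellMap the generated [CellMap-class].
#' @slot cells per-cell table: label, type, position, centroid, relative
#'   marker density.
#' @slot interfaces per-interface table with exact rendered covered lengths.
#' @slot attenuationMap per-pixel multiplicative attenuation factor in (0, 1].
#' @slot config the [VeinConfig-class] that produced the vein.
#' @export
setClass("SyntheticTruth",
  slots = c(cellMap = "CellMap", cells = "data.frame", interfaces = "data.frame",
            attenuationMap = "matrix", config = "VeinConfig"))

setValidity("SyntheticTruth", function(object) {
  a <- object@attenuationMap
  if (length(a) && (any(a <= 0) || any(a > 1)))
    return("attenuation factors must lie in (0, 1]")
  TRUE
})

#' CalibrationReads: the four inputs of the relative-intensity statistic F
#'
#' Summed above-threshold fluorescence in the reference region (a PP transfer
#' cell) and the test region (a PP cell): \code{S1}, \code{S2} from the
#' membrane-marker channel and \code{C1}, \code{C2} from the wall-stain
#' channel used as internal standard.
#'
#' @slot S1,S2,C1,C2 non-negative intensity sums (arbitrary units).
#' @export
setClass("CalibrationReads",
  slots = c(S1 = "numeric", S2 = "numeric", C1 = "numeric", C2 = "numeric"))

setValidity("CalibrationReads", function(object) {
  v <- c(object@S1, object@S2, object@C1, object@C2)
  if (length(v) != 4L || any(!is.finite(v)) || any(v < 0))
    return("all four reads must be finite and >= 0")
  TRUE
})

#' @rdname CalibrationReads-class
#' @param S1,S2,C1,C2 intensity sums, see slot description.
#' @return A \code{CalibrationReads} object.
#' @export
calibrationReads <- function(S1, S2, C1, C2)
  methods::new("CalibrationReads", S1 = S1, S2 = S2, C1 = C1, C2 = C2)

#' EnrichmentReads: the four inputs of the enrichment statistic FC
#'
#' Summed marker fluorescence at the ingrowth-bearing side (\code{A1}) and at
#' the opposite, ingrowth-free side (\code{A2}), and the primary-wall lengths
#' of those sides (\code{L1}, \code{L2}, micrometres).
#'
#' @slot A1,A2 non-negative intensity sums (arbitrary units).
#' @slot L1,L2 non-negative lengths (micrometres).
#' @export
setClass("EnrichmentReads",
  slots = c(A1 = "numeric", A2 = "numeric", L1 = "numeric", L2 = "numeric"))

setValidity("EnrichmentReads", function(object) {
  v <- c(object@A1, object@A2, object@L1, object@L2)
  if (length(v) != 4L || any(!is.finite(v)) || any(v < 0))
    return("all four reads must be finite and >= 0")
  TRUE
})

#' @rdname EnrichmentReads-class
#' @param A1,A2,L1,L2 see slot description.
#' @return An \code{EnrichmentReads} object.
#' @export
enrichmentReads <- function(A1, A2, L1, L2)
  methods::new("EnrichmentReads", A1 = A1, A2 = A2, L1 = L1, L2 = L2)
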