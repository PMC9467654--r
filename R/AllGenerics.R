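#' Physical pixel size of an object
#'
#' @param x a [VeinImage-class] or [CellMap-class] object.
#' @return Pixel edge length in micrometres.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' Extract one channel of a multi-channel image
#'
#' @param x a [VeinImage-class].
#' @param which channel index or channel name.
#' @return A numeric matrix.
#' @export
setGeneric("channel", function(x, which) standardGeneric("channel"))

#' Number of channels in an image
#'
#' @param x a [VeinImage-class].
#' @return Integer channel count.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Integer label matrix of a cell map
#'
#' @param x a [CellMap-class].
#' @return Integer matrix; 0 denotes background.
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))

#' Cell-type annotation of a cell map
#'
#' @param x a [CellMap-class].
#' @return Named character vector mapping label to cell type.
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))
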