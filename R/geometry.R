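## Cell-adjacency and interface geometry from an integer label map.
## All adjacency is 4-connected; an interface is the set of pixel faces
## separating two labels and its length is faceCount * pixelSize.

## Enumerate every 4-connected pixel face with differing labels (background
## included). Columns: r1,c1,l1 / r2,c2,l2 with (r1,c1) the upper/left pixel.
.allFaces <- function(labels) {
  H <- nrow(labels); W <- ncol(labels)
  out <- vector("list", 2L)
  if (H > 1L) {
    a <- labels[-H, , drop = FALSE]; b <- labels[-1L, , drop = FALSE]
    idx <- which(a != b, arr.ind = TRUE)
    out[[1L]] <- data.frame(r1 = idx[, 1L], c1 = idx[, 2L],
                            l1 = a[idx], r2 = idx[, 1L] + 1L, c2 = idx[, 2L],
                            l2 = b[idx])
  }
  if (W > 1L) {
    a <- labels[, -W, drop = FALSE]; b <- labels[, -1L, drop = FALSE]
    idx <- which(a != b, arr.ind = TRUE)
    out[[2L]] <- data.frame(r1 = idx[, 1L], c1 = idx[, 2L],
                            l1 = a[idx], r2 = idx[, 1L], c2 = idx[, 2L] + 1L,
                            l2 = b[idx])
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1L))])
}

## Order faces along the boundary by greedy nearest-neighbour chaining of
## face midpoints, starting from the face farthest from the centroid (an
## endpoint for open boundaries). Returns an index permutation.
.orderFaces <- function(faces) {
  n <- nrow(faces)
  if (n <= 2L) return(seq_len(n))
  mr <- (faces$r1 + faces$r2) / 2; mc <- (faces$c1 + faces$c2) / 2
  d0 <- (mr - mean(mr))^2 + (mc - mean(mc))^2
  ord <- integer(n)
  used <- logical(n)
  cur <- which.max(d0)
  for (i in seq_len(n)) {
    ord[i] <- cur
    used[cur] <- TRUE
    if (i == n) break
    d <- (mr - mr[cur])^2 + (mc - mc[cur])^2
    d[used] <- Inf
    cur <- which.min(d)
  }
  ord
}

#' Build the cell-adjacency graph of a label map
#'
#' Two cells are adjacent iff some pixel of one is 4-adjacent to some pixel
#' of the other. The graph is undirected and simple; vertices are the cell
#' labels (as vertex names).
#'
#' @param map a [CellMap-class].
#' @return An \pkg{igraph} graph.
#' @examples
#' lab <- matrix(rep(1:3, each = 12), 6, 6)
#' cm <- cellMap(lab, 0.2, data.frame(label = 1:3, type = c("PP", "SE", "CC")))
#' igraph::as_edgelist(buildAdjacency(cm))
#' @export
buildAdjacency <- function(map) {
  lab <- cellLabels(map)
  labs <- sort(unique(lab[lab > 0]))
  if (length(labs) == 0L) stop("empty label map: no cells to build a graph from")
  f <- .allFaces(lab)
  f <- f[f$l1 > 0 & f$l2 > 0, , drop = FALSE]
  e <- unique(data.frame(a = pmin(f$l1, f$l2), b = pmax(f$l1, f$l2)))
  igraph::graph_from_data_frame(
    data.frame(from = as.character(e$a), to = as.character(e$b)),
    directed = FALSE, vertices = data.frame(name = as.character(labs)))
}

.interfaceFromFaces <- function(faces, a, b, pixelSize) {
  lo <- min(a, b); hi <- max(a, b)
  sel <- (faces$l1 == lo & faces$l2 == hi) | (faces$l1 == hi & faces$l2 == lo)
  ff <- faces[sel, , drop = FALSE]
  if (nrow(ff) == 0L)
    stop(sprintf("cells %d and %d are not adjacent", a, b))
  swap <- ff$l1 != lo
  out <- data.frame(ra = ifelse(swap, ff$r2, ff$r1),
                    ca = ifelse(swap, ff$c2, ff$c1),
                    rb = ifelse(swap, ff$r1, ff$r2),
                    cb = ifelse(swap, ff$c1, ff$c2))
  out <- out[.orderFaces(data.frame(r1 = out$ra, c1 = out$ca,
                                    r2 = out$rb, c2 = out$cb)), , drop = FALSE]
  rownames(out) <- NULL
  methods::new("Interface", cellA = as.integer(lo), cellB = as.integer(hi),
               faces = out, lengthUm = nrow(out) * pixelSize,
               pixelSize = pixelSize,
               ingrowthMask = rep(FALSE, nrow(out)), coveredLengthUm = 0)
}

#' Extract the interface between two adjacent cells
#'
#' Lists every pixel face separating the two cells, ordered along the
#' boundary, and computes the physical length as face count times pixel
#' size. The result is canonical: \code{extractInterface(map, a, b)} and
#' \code{extractInterface(map, b, a)} are identical.
#'
#' @param map a [CellMap-class].
#' @param a,b cell labels; must be adjacent.
#' @return An [Interface-class].
#' @examples
#' lab <- matrix(rep(1:2, each = 50), 10, 10)
#' cm <- cellMap(lab, 0.2, data.frame(label = 1:2, type = c("PP", "SE")))
#' extractInterface(cm, 1, 2)  # 10 faces x 0.2 um = 2 um
#' @export
extractInterface <- function(map, a, b) {
  .interfaceFromFaces(.allFaces(cellLabels(map)), a, b, pixelSize(map))
}

#' Set the ingrowth mask of an interface
#'
#' @param interface an [Interface-class].
#' @param mask logical vector, one entry per face (in face order).
#' @return The interface with \code{ingrowthMask} and covered length updated.
#' @export
setIngrowthMask <- function(interface, mask) {
  if (length(mask) != nrow(interface@faces))
    stop("mask length must equal the number of faces")
  interface@ingrowthMask <- as.logical(mask)
  interface@coveredLengthUm <- sum(mask) * interface@pixelSize
  interface
}

.centroids <- function(labels) {
  labs <- sort(unique(labels[labels > 0]))
  idx <- which(labels > 0)
  l <- labels[idx]
  r <- ((idx - 1L) %% nrow(labels)) + 1L
  cc <- ((idx - 1L) %/% nrow(labels)) + 1L
  data.frame(label = labs,
             row = as.numeric(tapply(r, l, mean)[as.character(labs)]),
             col = as.numeric(tapply(cc, l, mean)[as.character(labs)]),
             npix = as.integer(table(l)[as.character(labs)]))
}

#' Infer the abaxial axis of a vein cross-section
#'
#' In a leaf vascular bundle the xylem sits adaxially and the phloem
#' abaxially, so the unit vector from the xylem centroid towards the
#' combined phloem (SE, CC, PP) centroid points abaxially. The result is a
#' unit vector in (row, col) pixel coordinates; callers may override it when
#' the section orientation is known.
#'
#' @param map a [CellMap-class] containing at least one XY and one phloem cell.
#' @return Unit numeric vector \code{c(dRow, dCol)} pointing abaxially.
#' @export
abaxialAxis <- function(map) {
  ty <- cellTypes(map)
  cen <- .centroids(cellLabels(map))
  cen$type <- ty[as.character(cen$label)]
  xy <- cen[cen$type == "XY", , drop = FALSE]
  ph <- cen[cen$type %in% .PHLOEM_TYPES, , drop = FALSE]
  if (nrow(xy) == 0L || nrow(ph) == 0L)
    stop("cannot infer the abaxial axis: need xylem and phloem cells; ",
         "supply the axis explicitly")
  w1 <- xy$npix / sum(xy$npix); w2 <- ph$npix / sum(ph$npix)
  v <- c(sum(ph$row * w2) - sum(xy$row * w1),
         sum(ph$col * w2) - sum(xy$col * w1))
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) stop("xylem and phloem centroids coincide; supply the axis")
  v / nv
}

## Split BS cells into abaxial/adaxial halves by the median of their
## centroid projections on the abaxial axis; larger projection = more abaxial.
.bsSplit <- function(map, axis) {
  ty <- cellTypes(map)
  cen <- .centroids(cellLabels(map))
  cen$type <- ty[as.character(cen$label)]
  bs <- cen[cen$type == "BS", , drop = FALSE]
  if (nrow(bs) == 0L) stop("no bundle-sheath (BS) cells: cannot classify position")
  proj <- bs$row * axis[1L] + bs$col * axis[2L]
  med <- stats::median(proj)
  list(abaxialBS = bs$label[proj >= med], adaxialBS = bs$label[proj < med],
       median = med, centroids = cen)
}

#' Classify the abaxial/middle/adaxial position of a cell
#'
#' A cell is abaxial iff it is directly adjacent to, or just one cell away
#' from (graph distance <= 2 through cells of any type), an abaxial-half
#' bundle-sheath cell; adaxial iff within 2 hops of an adaxial-half BS cell
#' and not abaxial; otherwise middle. BS cells are split into halves by the
#' median of their centroid projections on the abaxial axis; a cell within
#' 2 hops of both halves is resolved by its own centroid projection.
#'
#' @param cell a cell label (typically a PP cell).
#' @param graph adjacency graph from [buildAdjacency()].
#' @param map the [CellMap-class].
#' @param axis abaxial unit vector, e.g. from [abaxialAxis()].
#' @return List with \code{value} (one of \code{"abaxial"}, \code{"middle"},
#'   \code{"adaxial"}), \code{hopsToAbaxialBS} and \code{hopsToAdaxialBS}.
#' @export
classifyPosition <- function(cell, graph, map, axis) {
  split <- .bsSplit(map, axis)
  .classifyOne(cell, graph, split, axis)
}

.classifyOne <- function(cell, graph, split, axis) {
  vn <- igraph::V(graph)$name
  dAll <- igraph::distances(graph, v = as.character(cell), to = vn)
  dAb <- suppressWarnings(min(dAll[1L, vn %in% as.character(split$abaxialBS)]))
  dAd <- suppressWarnings(min(dAll[1L, vn %in% as.character(split$adaxialBS)]))
  isAb <- is.finite(dAb) && dAb <= 2
  isAd <- is.finite(dAd) && dAd <= 2
  value <- if (isAb && isAd) {
    cen <- split$centroids[split$centroids$label == cell, , drop = FALSE]
    proj <- cen$row * axis[1L] + cen$col * axis[2L]
    if (proj >= split$median) "abaxial" else "adaxial"
  } else if (isAb) "abaxial" else if (isAd) "adaxial" else "middle"
  list(value = value,
       hopsToAbaxialBS = if (is.finite(dAb)) as.integer(dAb) else NA_integer_,
       hopsToAdaxialBS = if (is.finite(dAd)) as.integer(dAd) else NA_integer_)
}

## Vectorised position classification for many cells of one map.
.classifyPositions <- function(cells, graph, map, axis) {
  split <- .bsSplit(map, axis)
  res <- lapply(cells, .classifyOne, graph = graph, split = split, axis = axis)
  data.frame(label = cells,
             position = vapply(res, `[[`, "", "value"),
             hopsToAbaxialBS = vapply(res, `[[`, NA_integer_, "hopsToAbaxialBS"),
             hopsToAdaxialBS = vapply(res, `[[`, NA_integer_, "hopsToAdaxialBS"))
}

#' Vein size: combined xylem + phloem area
#'
#' Sum of the pixel areas of all XY, SE, CC and PP cells; bundle-sheath and
#' OTHER cells are excluded, following the convention that vascular-bundle
#' size is the combined area of phloem and xylem tissue.
#'
#' @param map a [CellMap-class].
#' @return Area in square micrometres.
#' @export
veinSize <- function(map) {
  lab <- cellLabels(map)
  ty <- cellTypes(map)
  keep <- as.integer(names(ty)[ty %in% c("XY", .PHLOEM_TYPES)])
  sum(lab %in% keep) * pixelSize(map)^2
}

#' Table of all cell/cell interfaces of a map
#'
#' @param map a [CellMap-class].
#' @return data.frame with one row per adjacent pair: labels, types, face
#'   count and physical length.
#' @export
interfaceTable <- function(map) {
  lab <- cellLabels(map)
  ty <- cellTypes(map)
  f <- .allFaces(lab)
  f <- f[f$l1 > 0 & f$l2 > 0, , drop = FALSE]
  if (nrow(f) == 0L)
    return(data.frame(cellA = integer(), cellB = integer(), typeA = character(),
                      typeB = character(), nFaces = integer(),
                      lengthUm = numeric()))
  key <- paste(pmin(f$l1, f$l2), pmax(f$l1, f$l2))
  tab <- table(key)
  ab <- do.call(rbind, strsplit(names(tab), " "))
  out <- data.frame(cellA = as.integer(ab[, 1L]), cellB = as.integer(ab[, 2L]),
                    nFaces = as.integer(tab))
  out$typeA <- unname(ty[as.character(out$cellA)])
  out$typeB <- unname(ty[as.character(out$cellB)])
  out$lengthUm <- out$nFaces * pixelSize(map)
  out <- out[order(out$cellA, out$cellB),
             c("cellA", "cellB", "typeA", "typeB", "nFaces", "lengthUm")]
  rownames(out) <- NULL
  out
}

#' Euclidean length of an interface
#'
#' Chord-length estimate of the physical boundary length: the ordered face
#' midpoints are sampled every few faces and the chord distances summed
#' (plus one pixel for the end caps). The plain face-count measure
#' ([extractInterface()]) is a Manhattan length that overstates diagonal
#' boundaries by up to sqrt(2); chords of a straight or gently curved
#' boundary do not.
#'
#' @param interface an [Interface-class] (or its faces data.frame).
#' @param pixelSize micrometres per pixel; taken from the interface when
#'   omitted.
#' @param step chord sampling stride in faces.
#' @return Length in micrometres.
#' @export
euclideanLength <- function(interface, pixelSize = NULL, step = 6L) {
  if (methods::is(interface, "Interface")) {
    if (is.null(pixelSize)) pixelSize <- interface@pixelSize
    f <- interface@faces
  } else f <- interface
  if (is.null(pixelSize)) stop("pixelSize required when passing bare faces")
  mr <- (f$ra + f$rb) / 2; mc <- (f$ca + f$cb) / 2
  n <- length(mr)
  if (n < 2L) return(n * pixelSize)
  idx <- unique(c(seq(1L, n, by = step), n))
  (sum(sqrt(diff(mr[idx])^2 + diff(mc[idx])^2)) + 1) * pixelSize
}
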