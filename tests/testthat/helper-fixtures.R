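# Small in-code fixtures and brute-force oracles.

# Horizontal bands (top to bottom), one cell per band.
bandMap <- function(types, bandHeight = 4L, width = 12L, pixelSize = 0.2) {
  n <- length(types)
  lab <- matrix(rep(seq_len(n), each = bandHeight * width),
                nrow = n * bandHeight, ncol = width, byrow = FALSE)
  lab <- matrix(0L, n * bandHeight, width)
  for (i in seq_len(n))
    lab[(i - 1L) * bandHeight + seq_len(bandHeight), ] <- i
  cellMap(lab, pixelSize, data.frame(label = seq_len(n), type = types))
}

# Random small Voronoi label map with random types.
randomMap <- function(seed, S = 40L, nCells = 6L, pixelSize = 0.2) {
  set.seed(seed)
  sr <- runif(nCells, 2, S - 1)
  sc <- runif(nCells, 2, S - 1)
  lab <- matrix(0L, S, S)
  for (r in seq_len(S)) for (co in seq_len(S)) {
    lab[r, co] <- which.min((r - sr)^2 + (co - sc)^2)
  }
  types <- sample(c("XY", "SE", "CC", "PP", "BS", "OTHER"), nCells,
                  replace = TRUE)
  cellMap(lab, pixelSize, data.frame(label = seq_len(nCells), type = types))
}

# Exhaustive O(N*4) adjacency oracle: scan every pixel's 4-neighbours.
adjacencyOracle <- function(labels) {
  H <- nrow(labels); W <- ncol(labels)
  pairs <- character()
  for (r in seq_len(H)) for (co in seq_len(W)) {
    a <- labels[r, co]
    if (a == 0L) next
    for (d in list(c(1L, 0L), c(0L, 1L))) {
      r2 <- r + d[1L]; c2 <- co + d[2L]
      if (r2 > H || c2 > W) next
      b <- labels[r2, c2]
      if (b != 0L && b != a)
        pairs <- c(pairs, paste(min(a, b), max(a, b)))
    }
  }
  sort(unique(pairs))
}

# Exhaustive face-count oracle for one cell pair.
faceCountOracle <- function(labels, a, b) {
  H <- nrow(labels); W <- ncol(labels)
  n <- 0L
  for (r in seq_len(H)) for (co in seq_len(W)) {
    if (r < H && ((labels[r, co] == a && labels[r + 1L, co] == b) ||
                  (labels[r, co] == b && labels[r + 1L, co] == a)))
      n <- n + 1L
    if (co < W && ((labels[r, co] == a && labels[r, co + 1L] == b) ||
                   (labels[r, co] == b && labels[r, co + 1L] == a)))
      n <- n + 1L
  }
  n
}

# Two-cell strip phantom with a straight vertical interface, rendered with
# a configurable covered arc. Used for strict coverage-recovery checks.
stripPhantom <- function(coverage, k = 3, S = 96L, pixelSize = 0.2) {
  lab <- matrix(2L, S, S)
  lab[, seq_len(S %/% 2L)] <- 1L
  map <- cellMap(lab, pixelSize,
                 data.frame(label = 1:2, type = c("PP", "SE")))
  ii <- extractInterface(map, 1, 2)
  idx <- veinTC:::.arcIndices(nrow(ii@faces), coverage)
  arcs <- if (length(idx))
    list(list(pp = 1L, partner = 2L, k = k,
              faces = ii@faces[idx, , drop = FALSE], fullFaces = ii@faces))
  else list()
  ch <- veinTC:::.renderChannels(lab, pixelSize, 180, 0.4, 300, c(`1` = 1),
                                 arcs)
  list(map = map, interface = ii, wall = ch$wall, marker = ch$marker)
}

# Pooled Student's t by the closed-form pooled-variance formula (oracle).
pooledTOracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Exhaustive intermeans threshold oracle: the t with t = round(mean of the
# below- and above-class means).
intermeansOracle <- function(v) {
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    if (t == floor((mean(lo) + mean(hi)) / 2 + 0.5)) return(t)
  }
  NA_integer_
}
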