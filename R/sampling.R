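#' Point-in-polygon test (even-odd ray casting)
#'
#' Tests which query points fall inside a simple ring by counting
#' crossings of a horizontal ray. Points exactly on an edge follow the
#' half-open crossing convention; pixel-center queries against polygon
#' edges aligned off the center lattice are unambiguous.
#'
#' @param pts two-column (x, y) matrix of query points.
#' @param ring two-column (x, y) matrix of polygon vertices (open ring).
#' @return Logical vector, one entry per query point.
#' @export
pointsInRing <- function(pts, ring) {
  x <- pts[, 1]; y <- pts[, 2]
  n <- nrow(ring)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

## Pixel (row, col) indices whose centers fall inside a ring; restricted to
## the ring's bounding box for speed. Returns a 2-column matrix.
.pixelsInRing <- function(grid, ring) {
  g <- gridGeoref(grid)
  ## candidate index window from the ring bounding box
  cmin <- max(1L, floor((min(ring[, 1]) - g$xll) / g$cellsize - 0.5) + 1L)
  cmax <- min(g$cols, ceiling((max(ring[, 1]) - g$xll) / g$cellsize + 0.5))
  rowFromY <- function(y) g$rows - (y - g$yll) / g$cellsize + 0.5
  rmin <- max(1L, floor(rowFromY(max(ring[, 2])) - 0.5))
  rmax <- min(g$rows, ceiling(rowFromY(min(ring[, 2])) + 0.5))
  if (cmin > cmax || rmin > rmax)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  idx <- expand.grid(row = rmin:rmax, col = cmin:cmax)
  ctr <- pixelCenters(grid, idx$row, idx$col)
  keep <- pointsInRing(ctr, ring)
  cbind(row = idx$row[keep], col = idx$col[keep])
}

#' Extract pixel values under labelled training polygons
#'
#' One row per unmasked pixel whose center lies inside a polygon, carrying
#' the polygon's class label and the pixel's NDVI and BBST. Pixels covered
#' by overlapping polygons of the same class are deduplicated; pixels
#' claimed by polygons of different classes are excluded (their count is
#' reported via a message and the "excluded_conflicts" attribute). A
#' polygon contributing no rows raises a warning.
#'
#' @param ndvi an \linkS4class{NdviGrid}.
#' @param bbst a \linkS4class{TemperatureGrid} in Celsius.
#' @param polygons a \linkS4class{TrainingPolygonSet} in the rasters'
#'   coordinate system.
#' @return data.frame with columns class, ndvi, bbst, row, col. Zero rows
#'   (with the full column set) if nothing was extracted.
#' @export
extractPixels <- function(ndvi, bbst, polygons) {
  checkCoregistered(ndvi, bbst)
  if (is(bbst, "TemperatureGrid") && bbst@unit != "celsius")
    bbst <- convertTemperature(bbst, "celsius")
  nr <- nrow(ndvi@values)
  hits <- vector("list", length(polygons@labels))
  for (k in seq_along(polygons@labels)) {
    px <- .pixelsInRing(ndvi, polygons@rings[[k]])
    if (nrow(px) == 0L)
      warning("polygon ", k, " (", polygons@labels[k],
              ") contains no pixel centers inside the raster")
    hits[[k]] <- px
  }
  ## cell -> set of classes claiming it
  cellId <- function(px) (px[, "col"] - 1L) * nr + px[, "row"]
  claims <- data.frame(
    cell = unlist(lapply(hits, cellId)),
    class = rep(polygons@labels, vapply(hits, nrow, integer(1))),
    stringsAsFactors = FALSE)
  empty <- data.frame(class = character(0), ndvi = numeric(0),
                      bbst = numeric(0), row = integer(0), col = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(claims)) {
    attr(empty, "excluded_conflicts") <- 0L
    return(empty)
  }
  claims <- unique(claims)                      # same-class overlap dedup
  nclass <- tapply(claims$class, claims$cell, function(x) length(unique(x)))
  conflicted <- as.numeric(names(nclass)[nclass > 1L])
  if (length(conflicted))
    message(length(conflicted),
            " pixel(s) claimed by polygons of different classes excluded")
  claims <- claims[!claims$cell %in% conflicted, , drop = FALSE]
  row <- ((claims$cell - 1L) %% nr) + 1L
  col <- ((claims$cell - 1L) %/% nr) + 1L
  v <- ndvi@values[cbind(row, col)]
  t <- bbst@values[cbind(row, col)]
  ok <- !is.na(v) & !is.na(t)
  out <- data.frame(class = claims$class[ok], ndvi = v[ok], bbst = t[ok],
                    row = row[ok], col = col[ok], stringsAsFactors = FALSE)
  out <- out[order(out$class, out$col, out$row), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded_conflicts") <- length(conflicted)
  out
}

#' Per-polygon mean of a raster
#'
#' @param grid any \linkS4class{RasterGrid}.
#' @param polygons a \linkS4class{TrainingPolygonSet}.
#' @return data.frame with columns polygon (index), class, mean, n_pixels;
#'   polygons with zero valid pixels get NA mean, n_pixels 0 and a warning.
#' @export
polygonMeans <- function(grid, polygons) {
  out <- data.frame(polygon = seq_along(polygons@labels),
                    class = polygons@labels, mean = NA_real_,
                    n_pixels = 0L, stringsAsFactors = FALSE)
  for (k in seq_along(polygons@labels)) {
    px <- .pixelsInRing(grid, polygons@rings[[k]])
    vals <- grid@values[px]
    vals <- vals[!is.na(vals)]
    out$n_pixels[k] <- length(vals)
    if (length(vals)) out$mean[k] <- mean(vals)
    else warning("polygon ", k, " has no valid pixels; mean is NA")
  }
  out
}

.intervalOverlap <- function(a, b) {
  inter <- min(a[2], b[2]) - max(a[1], b[1])
  if (inter <= 0) return(0)
  shorter <- min(a[2] - a[1], b[2] - b[1])
  if (shorter <= 0) return(1)          # degenerate interval inside the other
  min(1, inter / shorter)
}

#' Per-class NDVI/BBST ranges and pairwise overlap
#'
#' Summarizes the separability of the classes in the NDVI-by-temperature
#' feature plane: per-class min, max and mean of each covariate, and for
#' each class pair the interval-overlap fraction (intersection length over
#' the length of the shorter interval, in [0, 1]) for NDVI and for BBST.
#' Classes with no samples are absent from the output, not zero-filled.
#'
#' @param samples pixel sample table (columns class, ndvi, bbst).
#' @return List with elements \code{stats} (data.frame: class, covariate,
#'   min, mean, max, n) and \code{overlap} (data.frame: class_a, class_b,
#'   ndvi_overlap, bbst_overlap).
#' @export
separabilitySummary <- function(samples) {
  classes <- intersect(coverClasses(), unique(samples$class))
  if (!length(classes)) stop("no samples for any cover class")
  stats <- do.call(rbind, lapply(classes, function(cl) {
    s <- samples[samples$class == cl, ]
    do.call(rbind, lapply(c("ndvi", "bbst"), function(v)
      data.frame(class = cl, covariate = v, min = min(s[[v]]),
                 mean = mean(s[[v]]), max = max(s[[v]]), n = nrow(s),
                 stringsAsFactors = FALSE)))
  }))
  pairs <- if (length(classes) > 1L) utils::combn(classes, 2) else
    matrix(character(0), 2, 0)
  overlap <- do.call(rbind, c(list(
    data.frame(class_a = character(0), class_b = character(0),
               ndvi_overlap = numeric(0), bbst_overlap = numeric(0),
               stringsAsFactors = FALSE)),
    lapply(seq_len(ncol(pairs)), function(j) {
      a <- samples[samples$class == pairs[1, j], ]
      b <- samples[samples$class == pairs[2, j], ]
      data.frame(class_a = pairs[1, j], class_b = pairs[2, j],
                 ndvi_overlap = .intervalOverlap(range(a$ndvi), range(b$ndvi)),
                 bbst_overlap = .intervalOverlap(range(a$bbst), range(b$bbst)),
                 stringsAsFactors = FALSE)
    })))
  rownames(stats) <- rownames(overlap) <- NULL
  list(stats = stats, overlap = overlap)
}
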