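#' Construct a RasterGrid
#'
#' @param values numeric matrix, row 1 = northernmost row; NA = nodata.
#' @param xll,yll map coordinates of the lower-left grid corner.
#' @param cellsize cell edge length in map units.
#' @param class one of "RasterGrid", "NdviGrid", "RadianceGrid",
#'   "TemperatureGrid", "ClassGrid".
#' @param unit temperature unit, used only for TemperatureGrid.
#' @return A validated object of the requested class.
#' @export
#' @examples
#' g <- rasterGrid(matrix(runif(12), 3, 4), xll = 5e5, yll = 85e5)
#' dim(g)
rasterGrid <- function(values, xll = 0, yll = 0, cellsize = 30,
                       class = "RasterGrid", unit = "kelvin") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (class == "TemperatureGrid")
    new(class, values = values, xll = xll, yll = yll, cellsize = cellsize,
        unit = unit)
  else
    new(class, values = values, xll = xll, yll = yll, cellsize = cellsize)
}

#' @describeIn rasterGrid Raster cell values as a matrix.
#' @param x a RasterGrid.
#' @export
gridValues <- function(x) x@values

#' @describeIn rasterGrid Georeferencing as a named list
#'   (xll, yll, cellsize, rows, cols).
#' @export
gridGeoref <- function(x) {
  list(xll = x@xll, yll = x@yll, cellsize = x@cellsize,
       rows = nrow(x@values), cols = ncol(x@values))
}

#' @export
setMethod("dim", "RasterGrid", function(x) dim(x@values))

setMethod("show", "RasterGrid", function(object) {
  v <- object@values
  cat(sprintf("%s: %d x %d cells, cellsize %g, origin (%g, %g)\n",
              class(object), nrow(v), ncol(v), object@cellsize,
              object@xll, object@yll))
  ok <- !is.na(v)
  if (any(ok))
    cat(sprintf("  values: [%.4g, %.4g], %d nodata\n",
                min(v[ok]), max(v[ok]), sum(!ok)))
  else cat("  all nodata\n")
  invisible(NULL)
})

#' Map coordinates of pixel centers
#'
#' Row 1 is the northernmost row, so the y coordinate decreases with the
#' row index.
#'
#' @param grid a RasterGrid.
#' @param rows,cols integer vectors of pixel indices (recycled pairwise).
#' @return A two-column matrix of (x, y) center coordinates.
#' @export
pixelCenters <- function(grid, rows, cols) {
  n <- nrow(grid@values)
  cbind(x = grid@xll + (cols - 0.5) * grid@cellsize,
        y = grid@yll + (n - rows + 0.5) * grid@cellsize)
}

#' @describeIn rasterGrid Check that two grids are co-registered (same
#'   dimensions and georeferencing); errors otherwise.
#' @param y a second RasterGrid.
#' @export
checkCoregistered <- function(x, y) {
  if (!identical(dim(x@values), dim(y@values)))
    stop("rasters are not co-registered: dimensions differ (",
         paste(dim(x@values), collapse = "x"), " vs ",
         paste(dim(y@values), collapse = "x"), ")")
  if (abs(x@xll - y@xll) > 1e-6 || abs(x@yll - y@yll) > 1e-6 ||
      abs(x@cellsize - y@cellsize) > 1e-9)
    stop("rasters are not co-registered: georeferencing differs")
  invisible(TRUE)
}

#' Construct calibration constants
#'
#' @param lmin,lmax spectral radiance scaled to qcalmin/qcalmax
#'   (W m-2 sr-1 um-1).
#' @param qcalmin,qcalmax minimum/maximum quantized calibrated DN.
#' @param k1,k2 prelaunch thermal calibration constants (radiance units
#'   and kelvin respectively).
#' @return A \linkS4class{CalibrationConstants} object.
#' @export
#' @examples
#' calibrationConstants(0.1, 22, 1, 65535, 774.8853, 1321.0789)
calibrationConstants <- function(lmin, lmax, qcalmin, qcalmax, k1, k2) {
  new("CalibrationConstants", lmin = lmin, lmax = lmax, qcalmin = qcalmin,
      qcalmax = qcalmax, k1 = k1, k2 = k2)
}

setMethod("show", "CalibrationConstants", function(object) {
  cat(sprintf(paste0("CalibrationConstants: L [%g, %g], QCAL [%g, %g], ",
                     "K1 = %g, K2 = %g K\n"),
              object@lmin, object@lmax, object@qcalmin, object@qcalmax,
              object@k1, object@k2))
  invisible(NULL)
})

#' Construct a training polygon set
#'
#' @param labels character vector of cover-class labels.
#' @param rings list of two-column (x, y) vertex matrices (open rings).
#' @param provenance free-text origin tag.
#' @return A \linkS4class{TrainingPolygonSet}.
#' @export
trainingPolygons <- function(labels, rings, provenance = "unspecified") {
  new("TrainingPolygonSet", labels = as.character(labels), rings = rings,
      provenance = provenance)
}

setMethod("show", "TrainingPolygonSet", function(object) {
  cat(sprintf("TrainingPolygonSet: %d polygons (%s)\n",
              length(object@labels), object@provenance))
  print(table(factor(object@labels, levels = coverClasses())))
  invisible(NULL)
})

setMethod("show", "Scene", function(object) {
  cat(sprintf("Scene: %d x %d pixels, cellsize %g m (red, nir, thermal DN)\n",
              nrow(object@red@values), ncol(object@red@values),
              object@red@cellsize))
  invisible(NULL)
})

#' @describeIn rasterGrid Extract one band of a Scene as its RasterGrid.
#' @param scene a \linkS4class{Scene}.
#' @param band "red", "nir" or "thermal".
#' @export
sceneBand <- function(scene, band = c("red", "nir", "thermal")) {
  band <- match.arg(band)
  slot(scene, band)
}
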