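#' @import methods
NULL

#' Land-cover legend
#'
#' Integer codes used in classified rasters: 0 is unclassified, the three
#' savanna structural classes follow.
#'
#' @return Named integer vector mapping class labels to raster codes.
#' @export
#' @examples
#' classLegend()
classLegend <- function() {
  c(unclassified = 0L, grassland = 1L, shrubland = 2L, woodland = 3L)
}

#' The three savanna cover classes, in increasing woody-cover order.
#' @return Character vector \code{c("grassland", "shrubland", "woodland")}.
#' @export
coverClasses <- function() c("grassland", "shrubland", "woodland")

## ---------------------------------------------------------------------------
## RasterGrid and subclasses
## ---------------------------------------------------------------------------

#' RasterGrid: a single-band north-up raster
#'
#' A minimal georeferenced raster: a numeric matrix (row 1 = northernmost
#' row) with a square cell size and the coordinates of the lower-left
#' corner. Nodata cells are \code{NA}. Only north-up, axis-aligned grids
#' are supported; this keeps pixel-center geometry exact in tests.
#'
#' @slot values numeric matrix; \code{NA} marks nodata.
#' @slot xll,yll numeric scalars, map coordinates of the lower-left corner
#'   of the grid (not of a cell center).
#' @slot cellsize positive numeric scalar, cell edge length in map units
#'   (meters for the 30 m scenes emulated here).
#' @export
setClass("RasterGrid",
  representation(values = "matrix", xll = "numeric", yll = "numeric",
                 cellsize = "numeric"),
  prototype(values = matrix(numeric(0), 0, 0), xll = 0, yll = 0,
            cellsize = 30))

setValidity("RasterGrid", function(object) {
  if (!is.numeric(object@values) && !is.logical(object@values))
    return("values must be a numeric matrix")
  if (length(object@cellsize) != 1L || !is.finite(object@cellsize) ||
      object@cellsize <= 0)
    return("cellsize must be a positive scalar")
  if (length(object@xll) != 1L || length(object@yll) != 1L)
    return("xll and yll must be scalars")
  TRUE
})

#' @rdname RasterGrid-class
#' @slot unit "kelvin" or "celsius".
#' @export
setClass("TemperatureGrid", contains = "RasterGrid",
  representation(unit = "character"), prototype(unit = "kelvin"))

setValidity("TemperatureGrid", function(object) {
  if (!object@unit %in% c("kelvin", "celsius"))
    return("unit must be 'kelvin' or 'celsius'")
  v <- object@values[!is.na(object@values)]
  if (object@unit == "kelvin" && length(v) && any(v <= 0))
    return("kelvin temperatures must be positive")
  TRUE
})

#' @rdname RasterGrid-class
#' @export
setClass("RadianceGrid", contains = "RasterGrid")

setValidity("RadianceGrid", function(object) {
  v <- object@values[!is.na(object@values)]
  if (length(v) && any(v <= 0))
    return("all unmasked radiance values must be positive")
  TRUE
})

#' @rdname RasterGrid-class
#' @export
setClass("NdviGrid", contains = "RasterGrid")

setValidity("NdviGrid", function(object) {
  v <- object@values[!is.na(object@values)]
  if (length(v) && (min(v) < -1 - 1e-9 || max(v) > 1 + 1e-9))
    return("NDVI values must lie in [-1, 1]")
  TRUE
})

#' @rdname RasterGrid-class
#' @export
setClass("ClassGrid", contains = "RasterGrid")

setValidity("ClassGrid", function(object) {
  v <- object@values[!is.na(object@values)]
  if (length(v) && !all(v %in% classLegend()))
    return("class codes must be drawn from classLegend()")
  TRUE
})

#' ClassZoneMap: a coarse class raster derived by majority aggregation
#'
#' @slot aggregationFactor integer, number of fine cells per coarse cell edge.
#' @slot purityThreshold fraction of valid fine pixels the modal class must
#'   reach for a coarse cell to be labelled; cells below it are masked.
#' @export
setClass("ClassZoneMap", contains = "ClassGrid",
  representation(aggregationFactor = "integer", purityThreshold = "numeric"),
  prototype(aggregationFactor = 1L, purityThreshold = 0.75))

## ---------------------------------------------------------------------------
## Calibration, scene, polygons
## ---------------------------------------------------------------------------

#' CalibrationConstants: thermal-band radiometric calibration
#'
#' The rescaling constants that map quantized digital numbers (DN) to
#' spectral radiance, and the two prelaunch Planck constants that map
#' radiance to brightness temperature. These are sensor metadata and have
#' no defaults; the synthetic scene generator supplies self-consistent
#' values.
#'
#' @slot lmin,lmax spectral radiance (W m-2 sr-1 um-1) at qcalmin/qcalmax.
#' @slot qcalmin,qcalmax minimum and maximum quantized calibrated DN.
#' @slot k1 prelaunch calibration constant, radiance units.
#' @slot k2 prelaunch calibration constant, kelvin.
#' @export
setClass("CalibrationConstants",
  representation(lmin = "numeric", lmax = "numeric", qcalmin = "numeric",
                 qcalmax = "numeric", k1 = "numeric", k2 = "numeric"))

setValidity("CalibrationConstants", function(object) {
  for (s in c("lmin", "lmax", "qcalmin", "qcalmax", "k1", "k2"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      return(sprintf("%s must be a finite scalar", s))
  if (object@qcalmax <= object@qcalmin) return("qcalmax must exceed qcalmin")
  if (object@lmax <= object@lmin) return("lmax must exceed lmin")
  if (object@k1 <= 0 || object@k2 <= 0) return("k1 and k2 must be positive")
  TRUE
})

#' Scene: co-registered red, NIR and thermal bands
#'
#' @slot red,nir reflectance-like bands as \linkS4class{RasterGrid}.
#' @slot thermal thermal-band digital numbers as \linkS4class{RasterGrid}.
#' @slot calibration \linkS4class{CalibrationConstants} for the thermal band.
#' @export
setClass("Scene",
  representation(red = "RasterGrid", nir = "RasterGrid",
                 thermal = "RasterGrid", calibration = "CalibrationConstants"))

setValidity("Scene", function(object) {
  d <- dim(object@red@values)
  if (!identical(d, dim(object@nir@values)) ||
      !identical(d, dim(object@thermal@values)))
    return("red, nir and thermal bands must share dimensions")
  TRUE
})

#' TrainingPolygonSet: labelled field polygons
#'
#' Simple (non-self-intersecting) rings in map coordinates, each carrying
#' one cover-class label; the unit of ground truthing for classifier
#' training and accuracy assessment.
#'
#' @slot labels character vector of class labels, one per polygon.
#' @slot rings list of two-column (x, y) matrices, open rings (first vertex
#'   not repeated).
#' @slot provenance free-text origin tag ("synthetic", "field", ...).
#' @export
setClass("TrainingPolygonSet",
  representation(labels = "character", rings = "list",
                 provenance = "character"),
  prototype(provenance = "unspecified"))

setValidity("TrainingPolygonSet", function(object) {
  if (length(object@labels) != length(object@rings))
    return("labels and rings must have equal length")
  if (length(object@labels) && !all(object@labels %in% coverClasses()))
    return("labels must be drawn from coverClasses()")
  ok <- vapply(object@rings, function(r)
    is.matrix(r) && ncol(r) == 2L && nrow(r) >= 3L, logical(1))
  if (!all(ok)) return("each ring must be a 2-column matrix with >= 3 vertices")
  TRUE
})

## ---------------------------------------------------------------------------
## Rules, error matrix, synthetic configs
## ---------------------------------------------------------------------------

#' RuleSet: coupled NDVI-by-temperature box rules
#'
#' One rule per class: an NDVI condition and a BBST condition, each an
#' interval or one-sided bound with per-bound inclusivity, plus a
#' precedence order. Classification tests classes in precedence order and
#' assigns the first class whose two conditions both hold; pixels matching
#' no rule stay unclassified.
#'
#' @slot rules data.frame with columns class, ndvi_min, ndvi_max, bbst_min,
#'   bbst_max (\code{-Inf}/\code{Inf} for absent bounds) and logical
#'   *_incl inclusivity columns for each finite bound.
#' @slot precedence character vector ordering the classes for first-match
#'   assignment.
#' @export
setClass("RuleSet",
  representation(rules = "data.frame", precedence = "character"))

setValidity("RuleSet", function(object) {
  r <- object@rules
  need <- c("class", "ndvi_min", "ndvi_max", "ndvi_min_incl", "ndvi_max_incl",
            "bbst_min", "bbst_max", "bbst_min_incl", "bbst_max_incl")
  if (!all(need %in% names(r))) return("rules data.frame is missing columns")
  if (anyDuplicated(object@precedence))
    return("each class must appear exactly once in precedence")
  if (!setequal(object@precedence, r$class))
    return("precedence must list exactly the ruled classes")
  ## degenerate (point) intervals are allowed: quantile induction on a
  ## point mass legitimately produces lower == upper
  if (any(r$ndvi_min > r$ndvi_max) || any(r$bbst_min > r$bbst_max))
    return("each condition needs lower <= upper where both bounds are present")
  TRUE
})

#' ErrorMatrix: mapped-versus-reference class counts
#'
#' Rows are the mapped (predicted) class, columns the reference class, in
#' the conventional woodland, shrubland, grassland order. Unclassified
#' predictions at reference sites are tallied separately and excluded from
#' the 3x3 table.
#'
#' @slot counts 3x3 nonnegative integer matrix with class dimnames.
#' @slot unclassified integer count of reference sites the map left
#'   unclassified.
#' @export
setClass("ErrorMatrix",
  representation(counts = "matrix", unclassified = "integer"),
  prototype(unclassified = 0L))

setValidity("ErrorMatrix", function(object) {
  m <- object@counts
  if (!all(dim(m) == c(3L, 3L))) return("counts must be 3x3")
  if (any(m < 0)) return("counts must be nonnegative")
  if (sum(m) + object@unclassified <= 0) return("grand total must be positive")
  if (is.null(dimnames(m))) return("counts must carry class dimnames")
  TRUE
})

#' ClassDistribution: a class-conditional (NDVI, BBST) generating box
#'
#' @slot label cover class.
#' @slot ndviRange length-2 numeric, closed NDVI interval within [-1, 1].
#' @slot bbstRange length-2 numeric, closed temperature interval in Celsius.
#' @slot family "uniform" or "truncated-normal" (mean at the interval
#'   midpoint, sd a quarter of its width, truncated to the interval).
#' @export
setClass("ClassDistribution",
  representation(label = "character", ndviRange = "numeric",
                 bbstRange = "numeric", family = "character"),
  prototype(family = "uniform"))

setValidity("ClassDistribution", function(object) {
  if (!object@label %in% coverClasses()) return("unknown class label")
  if (length(object@ndviRange) != 2L || length(object@bbstRange) != 2L)
    return("ndviRange and bbstRange must have length 2")
  if (object@ndviRange[1] > object@ndviRange[2] ||
      object@bbstRange[1] > object@bbstRange[2])
    return("interval lower bound must not exceed upper bound")
  if (object@ndviRange[1] < -1 || object@ndviRange[2] > 1)
    return("ndviRange must lie within [-1, 1]")
  if (!object@family %in% c("uniform", "truncated-normal"))
    return("family must be 'uniform' or 'truncated-normal'")
  TRUE
})

#' SceneConfig: synthetic fine-scene geometry and mixing
#'
#' @slot rows,cols pixel counts.
#' @slot cellsize cell edge in meters (default 30, emulating Landsat-like
#'   imagery).
#' @slot classFractions named simplex weights over the three cover classes.
#' @slot patchScale correlation length of the class mosaic, in pixels.
#' @slot brightnessSum s = NIR + red used to invert NDVI into band values.
#' @slot calibration thermal calibration used to encode temperatures as DN.
#' @slot quantizeDN round thermal DN to integers (emulates sensor
#'   quantization; off by default so radiometric round trips are exact).
#' @slot polygonsPerClass,polygonSize training-polygon sampling: number of
#'   axis-aligned square polygons per class and their edge length in pixels
#'   (>= 3, emulating the 90 m by 90 m minimum field-sample size).
#' @slot seed integer RNG seed.
#' @export
setClass("SceneConfig",
  representation(rows = "integer", cols = "integer", cellsize = "numeric",
                 classFractions = "numeric", patchScale = "numeric",
                 brightnessSum = "numeric", calibration = "CalibrationConstants",
                 quantizeDN = "logical", polygonsPerClass = "integer",
                 polygonSize = "integer", seed = "integer"))

setValidity("SceneConfig", function(object) {
  if (object@rows <= 0L || object@cols <= 0L)
    return("rows and cols must be positive")
  f <- object@classFractions
  if (!setequal(names(f), coverClasses()))
    return("classFractions must be named by the three cover classes")
  if (any(f < 0) || abs(sum(f) - 1) > 1e-9)
    return("classFractions must be nonnegative and sum to 1 (tol 1e-9)")
  if (object@patchScale <= 0) return("patchScale must be positive")
  if (object@brightnessSum <= 0 || object@brightnessSum > 2)
    return("brightnessSum must be in (0, 2]")
  if (object@polygonSize < 3L)
    return("polygonSize must be >= 3 pixels")
  TRUE
})

#' CoarseSeriesConfig: synthetic coarse NDVI stack parameters
#'
#' Emulates a 16-day maximum-NDVI composite product already reduced to
#' seasonal values: for each coarse cell, season and year, the value is the
#' class-seasonal baseline plus a linear yearly trend plus Gaussian noise.
#'
#' @slot aggregationFactor fine cells per coarse cell edge (default 8, i.e.
#'   240 m zones over a 30 m map, approximating a 250 m product).
#' @slot years integer vector of calendar years (default 2000:2016).
#' @slot baselines 3x4 numeric matrix of per-class per-season mean NDVI,
#'   rows named by class, columns MAM/JJA/SON/DJF; woodland must exceed
#'   shrubland which must exceed grassland in every season.
#' @slot trendPerYear named numeric, per-class NDVI change per year.
#' @slot noiseSD Gaussian noise standard deviation (NDVI units).
#' @slot seed integer RNG seed.
#' @export
setClass("CoarseSeriesConfig",
  representation(aggregationFactor = "integer", years = "integer",
                 baselines = "matrix", trendPerYear = "numeric",
                 noiseSD = "numeric", seed = "integer"))

setValidity("CoarseSeriesConfig", function(object) {
  if (object@aggregationFactor < 1L) return("aggregationFactor must be >= 1")
  if (length(object@years) < 1L) return("year range must be non-empty")
  if (object@noiseSD < 0) return("noiseSD must be nonnegative")
  b <- object@baselines
  if (!identical(sort(rownames(b)), sort(coverClasses())) ||
      !identical(colnames(b), seasonNames()))
    return("baselines must be a class-by-season matrix (MAM/JJA/SON/DJF)")
  if (!all(b["woodland", ] > b["shrubland", ]) ||
      !all(b["shrubland", ] > b["grassland", ]))
    return("baselines must order woodland > shrubland > grassland per season")
  if (!setequal(names(object@trendPerYear), coverClasses()))
    return("trendPerYear must be named by the three cover classes")
  TRUE
})

#' SeasonalStack: per-season per-year coarse NDVI rasters
#'
#' @slot rasters list of numeric matrices, one per (year, season) layer.
#' @slot year,season integer/character vectors indexing the layers.
#' @slot xll,yll,cellsize georeferencing shared by all layers.
#' @export
setClass("SeasonalStack",
  representation(rasters = "list", year = "integer", season = "character",
                 xll = "numeric", yll = "numeric", cellsize = "numeric"),
  prototype(xll = 0, yll = 0, cellsize = 240))

setValidity("SeasonalStack", function(object) {
  n <- length(object@rasters)
  if (length(object@year) != n || length(object@season) != n)
    return("year and season must index every raster layer")
  if (n && !all(object@season %in% seasonNames()))
    return("seasons must be MAM, JJA, SON or DJF")
  if (n > 1L) {
    d <- dim(object@rasters[[1L]])
    if (!all(vapply(object@rasters, function(m) identical(dim(m), d),
                    logical(1))))
      return("all layers must share dimensions")
  }
  TRUE
})

#' Meteorological season names in calendar order.
#' @return \code{c("MAM", "JJA", "SON", "DJF")}.
#' @export
seasonNames <- function() c("MAM", "JJA", "SON", "DJF")
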