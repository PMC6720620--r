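#' Write a raster as an ESRI ASCII Grid
#'
#' Plain-text Arc/Info ASCII Grid (.asc): a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of
#' values, north row first. Only north-up square-cell grids exist in this
#' package, which is exactly what the format encodes.
#'
#' @param grid a \linkS4class{RasterGrid} (or subclass).
#' @param path output path.
#' @param nodata numeric sentinel written for NA cells.
#' @return \code{path}, invisibly.
#' @export
writeAsciiGrid <- function(grid, path, nodata = -9999) {
  v <- grid@values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(v)), sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", grid@xll),
           sprintf("yllcorner %.10g", grid@yll),
           sprintf("cellsize %.10g", grid@cellsize),
           sprintf("NODATA_value %.10g", nodata))
  body <- apply(v, 1L, function(r)
    paste(formatC(r, format = "g", digits = 15), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII Grid raster
#'
#' @param path path to a readable .asc file.
#' @param class target grid class (default "RasterGrid").
#' @param unit temperature unit when \code{class} is "TemperatureGrid".
#' @return A \linkS4class{RasterGrid} (or requested subclass) with the
#'   NODATA sentinel mapped to NA.
#' @export
readAsciiGrid <- function(path, class = "RasterGrid", unit = "kelvin") {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 7L) stop("not an ASCII grid (truncated header): ", path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2L) stop("malformed ASCII grid header in ", path)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header is missing fields in ", path)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body size does not match header in ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  rasterGrid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
             class = class, unit = unit)
}

#' Write training polygons as GeoJSON
#'
#' A FeatureCollection of Polygon features with the class label in a
#' configurable property (default "class"). Rings are closed on output
#' per the GeoJSON spec.
#'
#' @param polygons a \linkS4class{TrainingPolygonSet}.
#' @param path output path.
#' @param property name of the class property.
#' @return \code{path}, invisibly.
#' @export
writePolygonsGeoJSON <- function(polygons, path, property = "class") {
  features <- lapply(seq_along(polygons@labels), function(k) {
    ring <- polygons@rings[[k]]
    closed <- rbind(ring, ring[1L, , drop = FALSE])
    props <- list(polygons@labels[k])
    names(props) <- property
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(closed)),
                           function(i) as.numeric(closed[i, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read training polygons from GeoJSON
#'
#' Accepts Polygon features (outer ring only; holes are not supported)
#' with a class-label property.
#'
#' @param path path to a GeoJSON FeatureCollection.
#' @param property name of the class property (default "class").
#' @param provenance origin tag for the returned set.
#' @return A \linkS4class{TrainingPolygonSet}.
#' @export
readPolygonsGeoJSON <- function(path, property = "class",
                                provenance = "file") {
  if (!file.exists(path)) stop("polygon file not found: ", path)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  labels <- character(0); rings <- list()
  for (f in gj$features) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("unsupported geometry type: ", f$geometry$type)
    lab <- f$properties[[property]]
    if (is.null(lab)) stop("feature lacks property '", property, "'")
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) as.numeric(unlist(p))))
    ## drop the closing vertex if present
    if (nrow(ring) > 1L && all(ring[1L, ] == ring[nrow(ring), ]))
      ring <- ring[-nrow(ring), , drop = FALSE]
    labels <- c(labels, lab)
    rings[[length(rings) + 1L]] <- ring
  }
  trainingPolygons(labels, rings, provenance = provenance)
}

#' Write a seasonal stack as per-layer ASCII grids plus a CSV manifest
#'
#' @param stack a \linkS4class{SeasonalStack}.
#' @param dir output directory (created if needed).
#' @param prefix layer filename prefix.
#' @return Path of the manifest CSV (columns path, year, season), invisibly.
#' @export
writeSeasonalStack <- function(stack, dir, prefix = "ndvi") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(stack@rasters))
  for (l in seq_along(stack@rasters)) {
    paths[l] <- file.path(dir, sprintf("%s_%d_%s.asc", prefix,
                                       stack@year[l], stack@season[l]))
    writeAsciiGrid(rasterGrid(stack@rasters[[l]], stack@xll, stack@yll,
                              stack@cellsize), paths[l])
  }
  manifest <- file.path(dir, paste0(prefix, "_manifest.csv"))
  utils::write.csv(data.frame(path = basename(paths), year = stack@year,
                              season = stack@season),
                   manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a seasonal stack from a CSV manifest
#'
#' @param manifest CSV with columns path, year, season; layer paths are
#'   resolved relative to the manifest's directory.
#' @return A \linkS4class{SeasonalStack}.
#' @export
readSeasonalStack <- function(manifest) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  dir <- dirname(manifest)
  grids <- lapply(file.path(dir, tab$path), readAsciiGrid)
  g <- grids[[1L]]
  new("SeasonalStack", rasters = lapply(grids, gridValues),
      year = as.integer(tab$year), season = tab$season,
      xll = g@xll, yll = g@yll, cellsize = g@cellsize)
}
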