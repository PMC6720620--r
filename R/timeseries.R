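#' Aggregate a fine class map to coarse class zones
#'
#' Bridges the fine classification to a coarse NDVI product: each coarse
#' cell takes its modal fine class if that class's share of the cell's
#' valid fine pixels reaches the purity threshold, and is masked
#' otherwise. Unclassified (code 0) and nodata fine pixels count as
#' invalid; a cell with no valid pixel is masked. Requiring a clear
#' majority makes each zone's coarse NDVI attributable to one cover class.
#'
#' @param map a fine \linkS4class{ClassGrid}.
#' @param factor fine cells per coarse cell edge (>= 1); the map is padded
#'   and masked if its dimensions are not divisible.
#' @param purityThreshold required modal-class share, in (0.5, 1].
#' @return A \linkS4class{ClassZoneMap}.
#' @export
#' @examples
#' m <- rasterGrid(matrix(3L, 16, 16), class = "ClassGrid")
#' aggregateClassMap(m, 8)
aggregateClassMap <- function(map, factor, purityThreshold = 0.75) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  if (factor > nrow(map@values) || factor > ncol(map@values))
    stop("aggregation factor exceeds raster dimensions")
  if (purityThreshold <= 0.5 || purityThreshold > 1)
    stop("purityThreshold must be in (0.5, 1]")
  v <- map@values
  cr <- ceiling(nrow(v) / factor); cc <- ceiling(ncol(v) / factor)
  padded <- matrix(NA_real_, cr * factor, cc * factor)
  padded[seq_len(nrow(v)), seq_len(ncol(v))] <- v
  out <- matrix(NA_integer_, cr, cc)
  for (i in seq_len(cr)) for (j in seq_len(cc)) {
    block <- padded[((i - 1L) * factor + 1L):(i * factor),
                    ((j - 1L) * factor + 1L):(j * factor)]
    valid <- block[!is.na(block) & block != 0]
    if (!length(valid)) next
    tab <- tabulate(valid, nbins = 3L)
    if (max(tab) / length(valid) >= purityThreshold)
      out[i, j] <- which.max(tab)
  }
  new("ClassZoneMap", values = out, xll = map@xll, yll = map@yll,
      cellsize = map@cellsize * factor, aggregationFactor = factor,
      purityThreshold = purityThreshold)
}

## Season and season-year of a date: MAM/JJA/SON by calendar months,
## December assigned to the DJF of the following January/February.
.seasonOfMonth <- function(month) {
  c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA",
    "JJA", "JJA", "SON", "SON", "SON", "DJF")[month]
}

.seasonYear <- function(year, month) ifelse(month == 12L, year + 1L, year)

#' Reduce dated NDVI composites to seasonal means
#'
#' Averages a stack of dated (16-day style) composite rasters into one
#' layer per season per year. Seasons partition the months as MAM, JJA,
#' SON and DJF; December belongs to the DJF labelled by the following
#' January/February. Per pixel, the seasonal value is the mean over the
#' composites whose dates fall in that season-year, ignoring nodata;
#' pixels with no valid composite are masked.
#'
#' @param composites list of numeric matrices, all of one shape.
#' @param dates vector of \code{Date}s, one per composite.
#' @param xll,yll,cellsize georeferencing carried into the output stack.
#' @return A \linkS4class{SeasonalStack}.
#' @export
seasonalMeanStack <- function(composites, dates, xll = 0, yll = 0,
                              cellsize = 240) {
  if (!length(composites)) stop("empty composite stack")
  if (length(composites) != length(dates))
    stop("need one date per composite")
  dates <- as.Date(dates)
  month <- as.integer(format(dates, "%m"))
  year <- as.integer(format(dates, "%Y"))
  season <- .seasonOfMonth(month)
  syear <- .seasonYear(year, month)
  key <- paste(syear, season)
  keys <- unique(key[order(syear, match(season, seasonNames()))])
  layers <- lapply(keys, function(k) {
    members <- composites[key == k]
    sumM <- Reduce(`+`, lapply(members, function(m) ifelse(is.na(m), 0, m)))
    cnt <- Reduce(`+`, lapply(members, function(m) !is.na(m) + 0))
    out <- sumM / cnt
    out[cnt == 0] <- NA_real_
    out
  })
  parts <- strsplit(keys, " ")
  new("SeasonalStack", rasters = layers,
      year = vapply(parts, function(p) as.integer(p[1]), integer(1)),
      season = vapply(parts, `[`, character(1), 2),
      xll = xll, yll = yll, cellsize = cellsize)
}

#' Per-class seasonal mean NDVI series from class zones
#'
#' Zonal statistics bridging scales: for every class, season and year, the
#' mean of the seasonal raster over that class's unmasked zone cells.
#' Classes with no zones are absent from the output rather than
#' zero-filled.
#'
#' @param stack a \linkS4class{SeasonalStack}.
#' @param zones a \linkS4class{ClassZoneMap} co-registered with the stack
#'   layers.
#' @return data.frame with columns class, season, year, mean_ndvi; one row
#'   per (class, season, year).
#' @export
zonalClassSeries <- function(stack, zones) {
  if (!length(stack@rasters)) stop("empty seasonal stack")
  if (!identical(dim(stack@rasters[[1L]]), dim(zones@values)))
    stop("zones and stack layers are not co-registered")
  present <- coverClasses()[classLegend()[coverClasses()] %in%
                              zones@values[!is.na(zones@values)]]
  if (!length(present)) stop("no overlap between zones and rasters")
  rows <- list()
  for (l in seq_along(stack@rasters)) {
    m <- stack@rasters[[l]]
    for (cl in present) {
      sel <- !is.na(zones@values) & zones@values == classLegend()[[cl]]
      vals <- m[sel]
      vals <- vals[!is.na(vals)]
      if (!length(vals)) next
      rows[[length(rows) + 1L]] <-
        data.frame(class = cl, season = stack@season[l],
                   year = stack@year[l], mean_ndvi = mean(vals),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ordinary least-squares trend of a series against year
#'
#' Fits \code{value ~ year} by least squares and reports the slope per
#' year, the intercept, and the two-sided p-value for a zero slope under
#' the standard normal-error linear model.
#'
#' @param year numeric vector of time points (at least 3 distinct).
#' @param value numeric response.
#' @return List with elements slope, intercept, p_value.
#' @export
#' @examples
#' linearTrend(2000:2016, 0.6 - 0.004 * (0:16))
linearTrend <- function(year, value) {
  ok <- !is.na(year) & !is.na(value)
  year <- year[ok]; value <- value[ok]
  if (length(year) < 3L) stop("trend needs at least 3 time points")
  if (length(unique(year)) < 2L) stop("constant time axis")
  fit <- stats::lm(value ~ year)
  cf <- stats::coef(fit)
  ## constant series fit perfectly; the p-value is then meaningless but the
  ## slope (0) is still the right answer, so silence the perfect-fit warning
  sm <- suppressWarnings(summary(fit))$coefficients
  p <- if (nrow(sm) >= 2L && !is.nan(sm["year", 4])) sm["year", 4] else NA_real_
  list(slope = unname(cf["year"]), intercept = unname(cf["(Intercept)"]),
       p_value = unname(p))
}

#' Per-class trends of a seasonal series
#'
#' For each class, regresses mean NDVI on year with season as an additive
#' factor (so the seasonal cycle does not bias the slope) and reports the
#' yearly slope and its two-sided p-value.
#'
#' @param series data.frame as returned by \code{\link{zonalClassSeries}}.
#' @return data.frame with columns class, slope_per_year, p_value.
#' @export
seasonalSeriesTrends <- function(series) {
  out <- do.call(rbind, lapply(sort(unique(series$class)), function(cl) {
    s <- series[series$class == cl, ]
    fit <- if (length(unique(s$season)) > 1L)
      stats::lm(mean_ndvi ~ year + factor(season), data = s)
    else stats::lm(mean_ndvi ~ year, data = s)
    sm <- summary(fit)$coefficients
    data.frame(class = cl, slope_per_year = unname(stats::coef(fit)["year"]),
               p_value = unname(sm["year", 4]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Water-year precipitation totals and anomalies
#'
#' Sums monthly precipitation over water years running from 1 October of
#' the preceding calendar year through 30 September, labelling each water
#' year by its ending (September) year. Water years with any of their 12
#' months missing are excluded with a warning. The anomaly is each total
#' minus the mean over all complete water-year totals.
#'
#' @param precip data.frame with columns year, month, precip_mm
#'   (nonnegative monthly totals).
#' @param startMonth first month of the water year (default 10, October).
#' @return data.frame with columns water_year, total_mm, anomaly_mm.
#' @export
#' @examples
#' p <- generatePrecipSeries(2000, 2003, rep(941 / 12, 12), 0, 0, seed = 1)
#' waterYearTotals(p)
waterYearTotals <- function(precip, startMonth = 10L) {
  if (anyDuplicated(precip[c("year", "month")]))
    stop("duplicate (year, month) rows in precipitation table")
  if (any(precip$precip_mm < 0)) stop("monthly totals must be nonnegative")
  wy <- ifelse(precip$month >= startMonth, precip$year + 1L, precip$year)
  counts <- tapply(precip$month, wy, length)
  complete <- names(counts)[counts == 12L]
  if (length(complete) < length(counts))
    warning(length(counts) - length(complete),
            " incomplete water year(s) excluded")
  keep <- wy %in% as.integer(complete)
  totals <- tapply(precip$precip_mm[keep], wy[keep], sum)
  out <- data.frame(water_year = as.integer(names(totals)),
                    total_mm = as.numeric(totals))
  out <- out[order(out$water_year), ]
  out$anomaly_mm <- out$total_mm - mean(out$total_mm)
  rownames(out) <- NULL
  out
}
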