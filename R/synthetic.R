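#' Thermal calibration used by the synthetic generator
#'
#' Self-consistent Landsat-8-like thermal rescaling and Planck constants
#' (16-bit DN range, K1/K2 of a typical 10.9 um thermal band). Real
#' calibration constants live in image metadata and are required inputs to
#' the radiometric chain; the generator supplies this set so synthetic DN
#' decode back to the drawn temperatures.
#'
#' @return A \linkS4class{CalibrationConstants} object.
#' @export
syntheticCalibration <- function() {
  calibrationConstants(lmin = 0.1, lmax = 22.0, qcalmin = 1, qcalmax = 65535,
                       k1 = 774.8853, k2 = 1321.0789)
}

#' Construct a class-conditional generating distribution
#'
#' @param label cover class.
#' @param ndviRange closed NDVI interval within [-1, 1].
#' @param bbstRange closed temperature interval, Celsius.
#' @param family "uniform" or "truncated-normal".
#' @return A \linkS4class{ClassDistribution}.
#' @export
classDistribution <- function(label, ndviRange, bbstRange,
                              family = "uniform") {
  new("ClassDistribution", label = label, ndviRange = as.numeric(ndviRange),
      bbstRange = as.numeric(bbstRange), family = family)
}

#' Default class-conditional (NDVI, BBST) distributions
#'
#' Uniform boxes over the wet-season per-class ranges observed in
#' field-training pixels of a southern-African savanna: woodland is
#' greenest and coolest (NDVI 0.40-0.68, 32.5-36.4 degC), grassland
#' sparsest and hottest (0.18-0.38, 38.6-41.3 degC), shrubland in between
#' and overlapping both neighbours (0.28-0.51, 36.7-39.4 degC). Woodland
#' is disjoint from grassland on both covariates; shrubland overlaps each
#' neighbour, which is exactly the separability structure the coupled
#' rule classifier exploits.
#'
#' @return Named list of three \linkS4class{ClassDistribution} objects.
#' @export
defaultClassDistributions <- function() {
  list(
    grassland = classDistribution("grassland", c(0.18, 0.38), c(38.6, 41.3)),
    shrubland = classDistribution("shrubland", c(0.28, 0.51), c(36.7, 39.4)),
    woodland  = classDistribution("woodland",  c(0.40, 0.68), c(32.5, 36.4)))
}

#' Construct a synthetic scene configuration
#'
#' @param rows,cols pixel counts (default 256 x 256).
#' @param cellsize cell edge in meters (default 30).
#' @param classFractions named simplex weights over grassland, shrubland,
#'   woodland; defaults to the wet-season mapped landscape shares
#'   (22.87/35.93/41.20%).
#' @param patchScale mosaic correlation length in pixels (default 8).
#' @param brightnessSum s = NIR + red used when inverting NDVI (default
#'   0.6).
#' @param calibration thermal calibration (default
#'   \code{\link{syntheticCalibration}}).
#' @param quantizeDN round thermal DN to integers (default FALSE).
#' @param polygonsPerClass,polygonSize training polygons sampled per class
#'   and their square edge in pixels (defaults 6 and 5; minimum size 3,
#'   the 90 m field-sampling floor at 30 m pixels).
#' @param seed integer RNG seed.
#' @param xll,yll map origin of the lower-left corner (UTM-like defaults).
#' @return A \linkS4class{SceneConfig}.
#' @export
sceneConfig <- function(rows = 256L, cols = 256L, cellsize = 30,
                        classFractions = c(grassland = 0.2287,
                                           shrubland = 0.3593,
                                           woodland = 0.4120),
                        patchScale = 8, brightnessSum = 0.6,
                        calibration = syntheticCalibration(),
                        quantizeDN = FALSE, polygonsPerClass = 6L,
                        polygonSize = 5L, seed = 1L,
                        xll = 5e5, yll = 85e5) {
  cfg <- new("SceneConfig", rows = as.integer(rows), cols = as.integer(cols),
             cellsize = cellsize,
             classFractions = classFractions[coverClasses()],
             patchScale = patchScale, brightnessSum = brightnessSum,
             calibration = calibration, quantizeDN = quantizeDN,
             polygonsPerClass = as.integer(polygonsPerClass),
             polygonSize = as.integer(polygonSize), seed = as.integer(seed))
  attr(cfg, "xll") <- xll; attr(cfg, "yll") <- yll
  cfg
}

## Separable Gaussian smoothing of a matrix by dense band matrices.
.gaussSmooth <- function(m, sigma) {
  k <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    w <- exp(-0.5 * (d / sigma)^2)
    w / rowSums(w)
  }
  k(nrow(m)) %*% m %*% t(k(ncol(m)))
}

## Patchy class mosaic: smooth a Gaussian white-noise field to the patch
## scale, then assign classes by field rank so the realized class counts
## match the requested fractions exactly (up to integer rounding).
## Grassland occupies the lowest field values, woodland the highest.
.classMosaic <- function(rows, cols, fractions, patchScale) {
  field <- .gaussSmooth(matrix(stats::rnorm(rows * cols), rows, cols),
                        patchScale)
  n <- rows * cols
  counts <- round(n * fractions)
  counts[3] <- n - counts[1] - counts[2]
  if (counts[3] < 0) {  # rounding overshoot; take it from the largest class
    i <- which.max(counts[1:2]); counts[i] <- counts[i] + counts[3]
    counts[3] <- 0
  }
  classOfRank <- rep.int(1:3, counts)
  cl <- matrix(classOfRank[rank(field, ties.method = "first")], rows, cols)
  cl
}

.drawFromDistribution <- function(n, range, family) {
  if (range[1] == range[2]) return(rep(range[1], n))
  if (family == "uniform") return(stats::runif(n, range[1], range[2]))
  mu <- mean(range); sd <- (range[2] - range[1]) / 4
  p <- stats::runif(n, stats::pnorm(range[1], mu, sd),
                    stats::pnorm(range[2], mu, sd))
  stats::qnorm(p, mu, sd)
}

## Sample non-overlapping pure-class square polygons from the truth mosaic.
.samplePolygons <- function(truth, grid, perClass, size, classes) {
  used <- matrix(FALSE, nrow(truth), ncol(truth))
  labels <- character(0); rings <- list()
  nr <- nrow(truth); nc <- ncol(truth)
  for (cl in classes) {
    code <- classLegend()[[cl]]
    found <- 0L
    for (k in seq(size, 3L)) {
      tries <- 0L
      while (found < perClass && tries < 20000L) {
        tries <- tries + 1L
        r0 <- sample.int(nr - k + 1L, 1L); c0 <- sample.int(nc - k + 1L, 1L)
        blockR <- r0:(r0 + k - 1L); blockC <- c0:(c0 + k - 1L)
        if (all(truth[blockR, blockC] == code) &&
            !any(used[blockR, blockC])) {
          used[blockR, blockC] <- TRUE
          found <- found + 1L
          x0 <- grid@xll + (c0 - 1L) * grid@cellsize
          x1 <- grid@xll + (c0 + k - 1L) * grid@cellsize
          y1 <- grid@yll + (nr - r0 + 1L) * grid@cellsize
          y0 <- grid@yll + (nr - r0 - k + 1L) * grid@cellsize
          rings[[length(rings) + 1L]] <-
            cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
          labels <- c(labels, cl)
        }
      }
      if (found >= perClass) break
    }
    if (found < 3L)
      stop("could not place 3 pure training polygons for class '", cl,
           "'; increase scene size or patchScale")
  }
  trainingPolygons(labels, rings, provenance = "synthetic")
}

#' Generate a synthetic fine-resolution scene
#'
#' Builds a patchy three-class mosaic (a Gaussian random field smoothed to
#' the configured patch scale and thresholded at the quantiles implied by
#' the class fractions), draws each pixel's NDVI and BBST from its class's
#' generating box, and encodes them as bands: red and NIR solve
#' \code{NIR = s(1+v)/2}, \code{red = s(1-v)/2} for drawn NDVI v and
#' brightness sum s, and the thermal band stores the digital number whose
#' radiometric decoding returns the drawn temperature. Also samples
#' non-overlapping pure-class square training polygons (at least 3 per
#' present class).
#'
#' @param config a \linkS4class{SceneConfig}.
#' @param distributions named list of three \linkS4class{ClassDistribution}
#'   objects covering the classes exactly once.
#' @return List with elements \code{scene} (\linkS4class{Scene}),
#'   \code{truth} (\linkS4class{ClassGrid}) and \code{polygons}
#'   (\linkS4class{TrainingPolygonSet}).
#' @export
#' @examples
#' out <- generateScene(sceneConfig(rows = 64, cols = 64, seed = 7))
#' table(gridValues(out$truth))
generateScene <- function(config, distributions = defaultClassDistributions()) {
  validObject(config)
  if (!setequal(names(distributions), coverClasses()))
    stop("distributions must cover the three classes exactly once")
  for (d in distributions) validObject(d)
  set.seed(config@seed)
  xll <- attr(config, "xll") %||% 5e5
  yll <- attr(config, "yll") %||% 85e5
  truth <- .classMosaic(config@rows, config@cols,
                        config@classFractions[coverClasses()],
                        config@patchScale)
  v <- matrix(NA_real_, config@rows, config@cols)
  t_c <- matrix(NA_real_, config@rows, config@cols)
  for (cl in coverClasses()) {
    sel <- truth == classLegend()[[cl]]
    n <- sum(sel)
    if (n == 0L) next
    d <- distributions[[cl]]
    v[sel] <- .drawFromDistribution(n, d@ndviRange, d@family)
    t_c[sel] <- .drawFromDistribution(n, d@bbstRange, d@family)
  }
  s <- config@brightnessSum
  nir <- s * (1 + v) / 2
  red <- s * (1 - v) / 2
  dn <- temperatureToDN(t_c, config@calibration, quantize = config@quantizeDN)
  mk <- function(m, cls = "RasterGrid")
    rasterGrid(m, xll, yll, config@cellsize, class = cls)
  truthGrid <- mk(truth, "ClassGrid")
  polygons <- .samplePolygons(truth, truthGrid, config@polygonsPerClass,
                              config@polygonSize,
                              coverClasses()[config@classFractions > 0])
  list(scene = new("Scene", red = mk(red), nir = mk(nir), thermal = mk(dn),
                   calibration = config@calibration),
       truth = truthGrid, polygons = polygons)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a coarse NDVI series configuration
#'
#' Defaults emulate a 2000-2016 run of seasonal means of a 16-day
#' maximum-NDVI product over this landscape: woodland greenest in every
#' season, grassland sparsest, a wet-season (DJF/MAM) peak and dry-season
#' (JJA) trough, and mild downward trends steepest in grassland.
#'
#' @param aggregationFactor fine pixels per coarse cell edge (default 8).
#' @param years calendar years (default 2000:2016).
#' @param baselines 3x4 class-by-season mean NDVI matrix.
#' @param trendPerYear named per-class NDVI change per year.
#' @param noiseSD Gaussian noise sd in NDVI units (default 0.01).
#' @param seed integer RNG seed.
#' @return A \linkS4class{CoarseSeriesConfig}.
#' @export
coarseSeriesConfig <- function(aggregationFactor = 8L, years = 2000:2016,
                               baselines = defaultSeasonalBaselines(),
                               trendPerYear = c(grassland = -0.004,
                                                shrubland = -0.002,
                                                woodland = -0.001),
                               noiseSD = 0.01, seed = 1L) {
  new("CoarseSeriesConfig", aggregationFactor = as.integer(aggregationFactor),
      years = as.integer(years), baselines = baselines,
      trendPerYear = trendPerYear, noiseSD = noiseSD, seed = as.integer(seed))
}

#' @rdname coarseSeriesConfig
#' @export
defaultSeasonalBaselines <- function() {
  b <- rbind(grassland = c(0.40, 0.22, 0.28, 0.45),
             shrubland = c(0.50, 0.32, 0.38, 0.55),
             woodland  = c(0.65, 0.45, 0.50, 0.70))
  colnames(b) <- seasonNames()
  b
}

## Modal fine class per coarse block; unclassified (0) and NA are invalid.
.blockModalClass <- function(values, factor) {
  nr <- nrow(values); nc <- ncol(values)
  cr <- ceiling(nr / factor); cc <- ceiling(nc / factor)
  padded <- matrix(NA_real_, cr * factor, cc * factor)
  padded[seq_len(nr), seq_len(nc)] <- values
  out <- matrix(NA_integer_, cr, cc)
  for (i in seq_len(cr)) for (j in seq_len(cc)) {
    block <- padded[((i - 1L) * factor + 1L):(i * factor),
                    ((j - 1L) * factor + 1L):(j * factor)]
    valid <- block[!is.na(block) & block != 0]
    if (!length(valid)) next
    tab <- tabulate(valid, nbins = 3L)
    out[i, j] <- which.max(tab)
  }
  out
}

#' Generate a synthetic coarse seasonal NDVI stack
#'
#' For each coarse cell, season and year, the value is the seasonal
#' baseline of the cell's majority fine class, plus the class trend times
#' the year offset, plus Gaussian noise, clipped to [-1, 1]. Coarse cells
#' with no valid fine pixels are masked in every layer. Deterministic
#' under a fixed seed.
#'
#' @param config a \linkS4class{CoarseSeriesConfig}.
#' @param truth fine-resolution true \linkS4class{ClassGrid} (padded and
#'   masked if its dimensions are not divisible by the aggregation factor).
#' @return A \linkS4class{SeasonalStack}.
#' @export
generateCoarseNdviSeries <- function(config, truth) {
  validObject(config)
  set.seed(config@seed)
  f <- config@aggregationFactor
  zones <- .blockModalClass(truth@values, f)
  y0 <- config@years[1]
  layers <- list(); yearIdx <- integer(0); seasonIdx <- character(0)
  for (yr in config@years) for (sn in seasonNames()) {
    m <- matrix(NA_real_, nrow(zones), ncol(zones))
    for (cl in coverClasses()) {
      sel <- !is.na(zones) & zones == classLegend()[[cl]]
      n <- sum(sel)
      if (!n) next
      mu <- config@baselines[cl, sn] + config@trendPerYear[[cl]] * (yr - y0)
      m[sel] <- mu + if (config@noiseSD > 0)
        stats::rnorm(n, 0, config@noiseSD) else 0
    }
    m[!is.na(m)] <- pmin(1, pmax(-1, m[!is.na(m)]))
    layers[[length(layers) + 1L]] <- m
    yearIdx <- c(yearIdx, yr); seasonIdx <- c(seasonIdx, sn)
  }
  new("SeasonalStack", rasters = layers, year = yearIdx, season = seasonIdx,
      xll = truth@xll, yll = truth@yll, cellsize = truth@cellsize * f)
}

#' Generate a synthetic monthly precipitation series
#'
#' Monthly totals are the calendar-month mean plus one twelfth of the
#' water-year trend times the water-year index, plus Gaussian noise;
#' negative draws truncate to zero. The noise standard deviation for a
#' month scales with that month's mean (\code{noiseSD} is the sd of an
#' average-wetness month), so near-zero dry-season months stay near zero
#' and truncation does not bias annual totals. Rows cover October of
#' \code{startYear - 1} through September of \code{endYear}, so every
#' water year from \code{startYear} to \code{endYear} is complete. The
#' default monthly means follow the strong November-April wet season of
#' an eastern-Zambian savanna and sum to 981 mm, which with the default
#' -5 mm/yr trend gives a 2000-2016 water-year mean of 941 mm.
#'
#' @param startYear,endYear first and last water year (labelled by their
#'   ending September).
#' @param monthlyMeans 12 nonnegative calendar-month means, mm
#'   (January..December).
#' @param trendPerYear water-year total trend, mm per year (signed).
#' @param noiseSD monthly Gaussian noise sd, mm.
#' @param seed integer RNG seed.
#' @return data.frame with columns year, month, precip_mm.
#' @export
generatePrecipSeries <- function(startYear = 2000L, endYear = 2016L,
                                 monthlyMeans = defaultMonthlyPrecip(),
                                 trendPerYear = -5, noiseSD = 25,
                                 seed = 1L) {
  if (endYear < startYear) stop("endYear must be >= startYear")
  if (length(monthlyMeans) != 12L || any(monthlyMeans < 0))
    stop("monthlyMeans must be 12 nonnegative values")
  set.seed(as.integer(seed))
  months <- seq.Date(as.Date(sprintf("%d-10-01", startYear - 1L)),
                     as.Date(sprintf("%d-09-01", endYear)), by = "month")
  year <- as.integer(format(months, "%Y"))
  month <- as.integer(format(months, "%m"))
  wy <- ifelse(month >= 10L, year + 1L, year)
  sdm <- if (mean(monthlyMeans) > 0)
    noiseSD * monthlyMeans[month] / mean(monthlyMeans) else 0
  mm <- monthlyMeans[month] + trendPerYear * (wy - startYear) / 12 +
    if (noiseSD > 0) stats::rnorm(length(month), 0, 1) * sdm else 0
  data.frame(year = year, month = month, precip_mm = pmax(0, mm))
}

#' @rdname generatePrecipSeries
#' @export
defaultMonthlyPrecip <- function() {
  c(200, 170, 125, 50, 8, 2, 1, 1, 3, 16, 140, 265)
}
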