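test_that("class-map aggregation applies the majority-with-purity rule", {
  pure <- rasterGrid(matrix(3L, 16, 16), class = "ClassGrid")
  z <- aggregateClassMap(pure, 8)
  expect_true(all(gridValues(z) == 3L))
  expect_equal(z@cellsize, 30 * 8)
  # 2x2 block split 1,1,2,2 at threshold 0.75 -> masked
  tie <- rasterGrid(matrix(c(1L, 1L, 2L, 2L), 2, 2), class = "ClassGrid")
  expect_true(is.na(gridValues(aggregateClassMap(tie, 2, 0.75))[1]))
  # 8x8 block with 60 woodland + 4 grassland: share 0.9375 >= 0.75
  m <- matrix(3L, 8, 8); m[1, 1:4] <- 1L
  mixed <- rasterGrid(m, class = "ClassGrid")
  expect_equal(gridValues(aggregateClassMap(mixed, 8, 0.75))[1], 3L)
  # unclassified pixels are invalid, not votes
  m2 <- matrix(0L, 8, 8); m2[1:2, 1:2] <- 2L
  expect_equal(gridValues(aggregateClassMap(rasterGrid(m2,
                                                       class = "ClassGrid"),
                                            8, 0.75))[1], 2L)
  expect_error(aggregateClassMap(pure, 32), "exceeds")
  expect_error(aggregateClassMap(pure, 2, 0.5), "purityThreshold")
})

test_that("factor-1 aggregation returns the input wherever it is classified", {
  fx <- localSceneFixture()
  cm <- applyRules(fx$ndvi, fx$bbst, referenceRuleSet())
  z <- aggregateClassMap(cm, 1, 1)
  v <- gridValues(cm); zv <- gridValues(z)
  classified <- !is.na(v) & v != 0L
  expect_equal(zv[classified], v[classified])
  expect_true(all(is.na(zv[!classified])))
})

test_that("seasonal means pool dated composites by season-year", {
  m <- function(x) matrix(x, 2, 2)
  stack <- seasonalMeanStack(list(m(0.2), m(0.4), m(0.6)),
                             as.Date(c("2001-03-10", "2001-04-05",
                                       "2001-05-20")))
  expect_equal(length(stack@rasters), 1L)
  expect_equal(stack@season, "MAM")
  expect_equal(stack@rasters[[1]][1, 1], 0.4)
  # December belongs to the following year's DJF
  djf <- seasonalMeanStack(list(m(0.5), m(0.7)),
                           as.Date(c("2001-12-20", "2002-01-10")))
  expect_equal(djf@year, 2002L)
  expect_equal(djf@rasters[[1]][1, 1], 0.6)
  # singleton season equals its composite; constant stays constant
  one <- seasonalMeanStack(list(m(0.5)), as.Date("2003-07-01"))
  expect_equal(one@rasters[[1]], m(0.5))
  # nodata composites are ignored per pixel
  withNA <- m(0.3); withNA[1, 1] <- NA
  s2 <- seasonalMeanStack(list(withNA, m(0.5)),
                          as.Date(c("2003-06-01", "2003-07-01")))
  expect_equal(s2@rasters[[1]][1, 1], 0.5)
  expect_equal(s2@rasters[[1]][2, 2], 0.4)
  expect_error(seasonalMeanStack(list(), as.Date(character(0))), "empty")
})

test_that("zonal class series take per-class means and drop absent classes", {
  zones <- new("ClassZoneMap",
               values = matrix(c(1, 1, 3, 3), 2, 2), xll = 0, yll = 0,
               cellsize = 240, aggregationFactor = 8L, purityThreshold = 0.75)
  lay <- matrix(c(0.3, 0.3, 0.6, 0.6), 2, 2)
  stack <- new("SeasonalStack", rasters = list(lay), year = 2005L,
               season = "SON", xll = 0, yll = 0, cellsize = 240)
  ser <- zonalClassSeries(stack, zones)
  expect_equal(nrow(ser), 2L)
  expect_equal(ser$mean_ndvi[ser$class == "grassland"], 0.3)
  expect_equal(ser$mean_ndvi[ser$class == "woodland"], 0.6)
  expect_false("shrubland" %in% ser$class)
})

test_that("noiseless coarse series equal their closed-form line exactly", {
  truth <- rasterGrid(matrix(3L, 16, 16), class = "ClassGrid")
  cfg <- coarseSeriesConfig(aggregationFactor = 8L, years = 2000:2016,
                            noiseSD = 0, seed = 1)
  b <- defaultSeasonalBaselines()
  stack <- generateCoarseNdviSeries(cfg, truth)
  first <- stack@rasters[[1]]
  expect_true(all(first == b["woodland", "MAM"]))
  # woodland trend -0.001/yr default: custom check with -0.002 and 0.60
  b2 <- b; b2["woodland", ] <- 0.60; b2["shrubland", ] <- 0.35
  b2["grassland", ] <- 0.20
  cfg2 <- coarseSeriesConfig(aggregationFactor = 8L, years = 2000:2016,
                             baselines = b2,
                             trendPerYear = c(grassland = 0, shrubland = 0,
                                              woodland = -0.002),
                             noiseSD = 0, seed = 1)
  stack2 <- generateCoarseNdviSeries(cfg2, truth)
  last <- stack2@rasters[[which(stack2@year == 2016 &
                                  stack2@season == "MAM")]]
  expect_equal(last[1, 1], 0.568)      # 0.60 - 0.002 * 16
})

test_that("coarse series keep the woodland > shrubland > grassland ordering", {
  fx <- localSceneFixture()
  cfg <- coarseSeriesConfig(aggregationFactor = 8L, seed = 21)
  stack <- generateCoarseNdviSeries(cfg, fx$gen$truth)
  zones <- aggregateClassMap(fx$gen$truth, 8L, 0.75)
  ser <- zonalClassSeries(stack, zones)
  wide <- reshape(ser, idvar = c("season", "year"), timevar = "class",
                  direction = "wide")
  expect_true(all(wide$mean_ndvi.woodland > wide$mean_ndvi.shrubland))
  expect_true(all(wide$mean_ndvi.shrubland > wide$mean_ndvi.grassland))
})

test_that("series generation is seed-reproducible", {
  truth <- rasterGrid(matrix(rep(1:3, each = 32), 8, 12),
                      class = "ClassGrid")
  a <- generateCoarseNdviSeries(coarseSeriesConfig(seed = 5,
                                                   aggregationFactor = 4L),
                                truth)
  b <- generateCoarseNdviSeries(coarseSeriesConfig(seed = 5,
                                                   aggregationFactor = 4L),
                                truth)
  c <- generateCoarseNdviSeries(coarseSeriesConfig(seed = 6,
                                                   aggregationFactor = 4L),
                                truth)
  expect_identical(a@rasters, b@rasters)
  expect_false(identical(a@rasters, c@rasters))
})

test_that("OLS trends recover exact lines and simulated slopes", {
  out <- linearTrend(2000:2016, 0.2 + 0.01 * (2000:2016 - 2000))
  expect_equal(out$slope, 0.01, tolerance = 1e-10)
  expect_equal(out$intercept, 0.2 - 0.01 * 2000, tolerance = 1e-6)
  flat <- linearTrend(2000:2016, rep(0.4, 17))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_error(linearTrend(rep(2000, 5), 1:5), "constant time axis")
  expect_error(linearTrend(2000:2001, c(1, 2)), "3 time points")
  set.seed(9)
  y <- 0.4 - 0.004 * (0:16) + rnorm(17, 0, 0.01)
  est <- linearTrend(2000:2016, y)
  expect_lt(abs(est$slope - (-0.004)), 0.002)
})

test_that("per-class slope estimates are unbiased across seeds", {
  truth <- rasterGrid(matrix(rep(1:3, each = 48), 12, 12),
                      class = "ClassGrid")
  zones <- aggregateClassMap(truth, 4L, 0.75)
  trends <- c(grassland = -0.004, shrubland = -0.002, woodland = -0.001)
  est <- sapply(1:50, function(s) {
    cfg <- coarseSeriesConfig(aggregationFactor = 4L, seed = s,
                              trendPerYear = trends)
    ser <- zonalClassSeries(generateCoarseNdviSeries(cfg, truth), zones)
    tr <- seasonalSeriesTrends(ser)
    setNames(tr$slope_per_year, tr$class)[names(trends)]
  })
  relErr <- abs(rowMeans(est) - trends) / abs(trends)
  expect_true(all(relErr < 0.10))
})

test_that("water-year bookkeeping sums October through September", {
  p <- generatePrecipSeries(2000, 2016, rep(941 / 12, 12), 0, 0, seed = 1)
  wy <- waterYearTotals(p)
  expect_equal(nrow(wy), 17L)
  expect_equal(wy$total_mm, rep(941, 17), tolerance = 1e-9)
  expect_equal(wy$anomaly_mm, rep(0, 17), tolerance = 1e-9)
  # mass conservation over complete water years
  expect_equal(sum(wy$total_mm), sum(p$precip_mm), tolerance = 1e-9)
  # all-zero input
  p0 <- generatePrecipSeries(2000, 2005, rep(0, 12), 0, 10, seed = 1)
  expect_true(all(waterYearTotals(p0)$total_mm == 0))
  # linear decline: 17 water years at -5 mm/yr span 80 mm
  pd <- generatePrecipSeries(2000, 2016, rep(80, 12), -5, 0, seed = 1)
  wyd <- waterYearTotals(pd)
  expect_equal(wyd$total_mm[1] - wyd$total_mm[17], 80, tolerance = 1e-9)
})

test_that("incomplete years are excluded and duplicates rejected", {
  p <- generatePrecipSeries(2000, 2002, rep(10, 12), 0, 0, seed = 1)
  broken <- p[!(p$year == 2001 & p$month == 3), ]
  expect_warning(wy <- waterYearTotals(broken), "incomplete")
  expect_false(2001 %in% wy$water_year)
  expect_true(all(c(2000, 2002) %in% wy$water_year))
  expect_error(waterYearTotals(rbind(p, p[1, ])), "duplicate")
  expect_error(generatePrecipSeries(2010, 2005), "endYear")
  expect_error(generatePrecipSeries(2000, 2005, rep(-1, 12)), "nonnegative")
})
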