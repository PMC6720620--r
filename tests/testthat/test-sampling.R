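mkGrids <- function(vals_ndvi, vals_bbst = vals_ndvi * 0 + 35) {
  list(ndvi = rasterGrid(vals_ndvi, xll = 0, yll = 0, cellsize = 30,
                         class = "NdviGrid"),
       bbst = rasterGrid(vals_bbst, xll = 0, yll = 0, cellsize = 30,
                         class = "TemperatureGrid", unit = "celsius"))
}

test_that("a 3x3-pixel polygon yields exactly nine rows", {
  g <- mkGrids(matrix(runif(100, 0, 0.5), 10))
  ring <- rectRing(g$ndvi, r0 = 4, r1 = 6, c0 = 2, c1 = 4)
  px <- extractPixels(g$ndvi, g$bbst,
                      trainingPolygons("woodland", list(ring)))
  expect_equal(nrow(px), 9L)
  expect_true(all(px$class == "woodland"))
  expect_setequal(px$row, 4:6)
  expect_setequal(px$col, 2:4)
})

test_that("masked pixels and out-of-raster polygons contribute nothing", {
  v <- matrix(runif(64, 0, 0.5), 8)
  v[3:5, 3:5] <- NA
  g <- mkGrids(v)
  ringMasked <- rectRing(g$ndvi, 3, 5, 3, 5)
  expect_warning(px <- extractPixels(g$ndvi, g$bbst,
                                     trainingPolygons("grassland",
                                                      list(ringMasked))),
                 NA)  # pixels exist; they are masked, not absent
  expect_equal(nrow(px), 0L)
  ringOutside <- cbind(x = c(1e5, 2e5, 2e5, 1e5), y = c(1e5, 1e5, 2e5, 2e5))
  expect_warning(px2 <- extractPixels(g$ndvi, g$bbst,
                                      trainingPolygons("grassland",
                                                       list(ringOutside))),
                 "no pixel centers")
  expect_equal(nrow(px2), 0L)
})

test_that("overlap handling deduplicates same-class and excludes cross-class", {
  g <- mkGrids(matrix(runif(100, 0, 0.5), 10))
  r1 <- rectRing(g$ndvi, 2, 4, 2, 4)
  r2 <- rectRing(g$ndvi, 3, 5, 3, 5)   # overlaps r1 in a 2x2 block
  same <- extractPixels(g$ndvi, g$bbst,
                        trainingPolygons(c("woodland", "woodland"),
                                         list(r1, r2)))
  expect_equal(nrow(same), 9L + 9L - 4L)
  expect_message(
    cross <- extractPixels(g$ndvi, g$bbst,
                           trainingPolygons(c("woodland", "grassland"),
                                            list(r1, r2))),
    "different classes")
  expect_equal(nrow(cross), 9L + 9L - 2L * 4L)
  expect_equal(attr(cross, "excluded_conflicts"), 4L)
})

test_that("pixel membership agrees with an independent point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  set.seed(31)
  g <- mkGrids(matrix(runif(48 * 48, 0, 0.5), 48))
  # an irregular convex-ish pentagon in map coordinates
  ring <- cbind(x = c(100, 1100, 1350, 700, 150),
                y = c(200, 100, 900, 1300, 800))
  px <- extractPixels(g$ndvi, g$bbst, trainingPolygons("shrubland",
                                                       list(ring)))
  idx <- expand.grid(row = 1:48, col = 1:48)
  ctr <- pixelCenters(g$ndvi, idx$row, idx$col)
  oracle <- mgcv::in.out(rbind(ring, ring[1, ]), ctr)
  expect_equal(nrow(px), sum(oracle))
  got <- paste(px$row, px$col)
  want <- paste(idx$row[oracle], idx$col[oracle])
  expect_setequal(got, want)
})

test_that("polygon means reduce to the contained-pixel means", {
  v <- matrix(0.3, 6, 6)
  g <- mkGrids(v)
  ring <- rectRing(g$ndvi, 2, 4, 2, 4)
  pm <- polygonMeans(g$ndvi, trainingPolygons("woodland", list(ring)))
  expect_equal(pm$mean, 0.3)
  expect_equal(pm$n_pixels, 9L)
  # two-point mean
  v2 <- matrix(c(0.2, 0.4), 1)
  g2 <- mkGrids(v2)
  ring2 <- rectRing(g2$ndvi, 1, 1, 1, 2)
  pm2 <- polygonMeans(g2$ndvi, trainingPolygons("grassland", list(ring2)))
  expect_equal(pm2$mean, 0.3)
  # all-masked polygon is flagged, not silently averaged
  v3 <- matrix(NA_real_, 4, 4)
  g3 <- mkGrids(v3)
  expect_warning(pm3 <- polygonMeans(g3$ndvi,
                                     trainingPolygons("grassland",
                                                      list(rectRing(g3$ndvi,
                                                                    1, 3, 1, 3)))),
                 "no valid pixels")
  expect_true(is.na(pm3$mean))
})

test_that("synthetic woodland polygon means fall in the expected NDVI band", {
  fx <- localSceneFixture()
  pm <- polygonMeans(fx$ndvi, fx$gen$polygons)
  wood <- pm$mean[pm$class == "woodland"]
  expect_true(all(wood >= 0.40 & wood <= 0.68))
})

test_that("separability summary reports ranges and interval overlaps", {
  s <- data.frame(class = rep(c("grassland", "woodland"), each = 4),
                  ndvi = c(0.1, 0.2, 0.3, 0.4, 0.1, 0.2, 0.3, 0.4),
                  bbst = c(30, 31, 32, 33, 30, 31, 32, 33))
  out <- separabilitySummary(s)
  expect_equal(out$overlap$ndvi_overlap, 1)   # identical samples
  expect_equal(out$overlap$bbst_overlap, 1)
  s2 <- s; s2$ndvi[s2$class == "woodland"] <- s2$ndvi[s2$class == "woodland"] + 1
  expect_equal(separabilitySummary(s2)$overlap$ndvi_overlap, 0)  # disjoint
  # absent classes are dropped, not zero-filled
  expect_false("shrubland" %in% separabilitySummary(s)$stats$class)
})

test_that("synthetic scene reproduces the wet-season separability structure", {
  fx <- localSceneFixture()
  out <- separabilitySummary(fx$samples)
  ov <- out$overlap
  gw <- ov[ov$class_a == "grassland" & ov$class_b == "woodland", ]
  expect_equal(gw$ndvi_overlap, 0)
  expect_equal(gw$bbst_overlap, 0)
  gs <- ov[ov$class_a == "grassland" & ov$class_b == "shrubland", ]
  sw <- ov[ov$class_a == "shrubland" & ov$class_b == "woodland", ]
  expect_gt(gs$ndvi_overlap, 0); expect_gt(gs$bbst_overlap, 0)
  expect_gt(sw$ndvi_overlap, 0)
  # every woodland pixel is cooler than every grassland pixel
  expect_lt(max(fx$samples$bbst[fx$samples$class == "woodland"]),
            min(fx$samples$bbst[fx$samples$class == "grassland"]))
})

test_that("half-pixel polygon translation only moves boundary pixels", {
  g <- mkGrids(matrix(runif(400, 0, 0.5), 20))
  ring <- rectRing(g$ndvi, 5, 9, 4, 8)           # 5x5 block
  shift <- ring; shift[, 1] <- shift[, 1] + 15   # half a 30 m pixel in x
  a <- extractPixels(g$ndvi, g$bbst, trainingPolygons("woodland", list(ring)))
  b <- extractPixels(g$ndvi, g$bbst, trainingPolygons("woodland", list(shift)))
  # 5 rows x 5 cols: a half-pixel shift can change membership only along
  # one 5-pixel column boundary
  expect_lte(abs(nrow(a) - nrow(b)), 5L)
})
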