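# Shared fixtures built in code at test time.

# Table of published assessment counts (rows mapped, cols reference;
# woodland, shrubland, grassland order).
rbcCounts <- function() rbind(c(23L, 8L, 1L), c(6L, 25L, 3L), c(0L, 0L, 21L))
svmCounts <- function() rbind(c(18L, 13L, 1L), c(19L, 11L, 4L), c(9L, 11L, 1L))

# One medium synthetic scene reused by several files (generation is the
# expensive step); fully decoded to NDVI/BBST and training pixels.
localSceneFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sceneConfig(rows = 128L, cols = 128L, seed = 2024L)
      gen <- generateScene(cfg)
      cal <- gen$scene@calibration
      ndvi <- computeNDVI(gen$scene@nir, gen$scene@red)
      bbst <- radianceToBBST(dnToRadiance(gen$scene@thermal, cal), cal,
                             unit = "celsius")
      samples <- extractPixels(ndvi, bbst, gen$polygons)
      cache <<- list(config = cfg, gen = gen, ndvi = ndvi, bbst = bbst,
                     samples = samples)
    }
    cache
  }
})

# Scalar per-pixel rule evaluator written independently of applyRules:
# plain if/else over the reference thresholds, first match in precedence.
scalarRuleOracle <- function(ndvi, bbst, rules) {
  r <- rules@rules
  legend <- classLegend()
  if (is.na(ndvi) || is.na(bbst)) return(NA_integer_)
  for (cl in rules@precedence) {
    i <- which(r$class == cl)
    okLo <- function(x, lo, incl) !is.finite(lo) || (if (incl) x >= lo else x > lo)
    okHi <- function(x, hi, incl) !is.finite(hi) || (if (incl) x <= hi else x < hi)
    if (okLo(ndvi, r$ndvi_min[i], r$ndvi_min_incl[i]) &&
        okHi(ndvi, r$ndvi_max[i], r$ndvi_max_incl[i]) &&
        okLo(bbst, r$bbst_min[i], r$bbst_min_incl[i]) &&
        okHi(bbst, r$bbst_max[i], r$bbst_max_incl[i]))
      return(legend[[cl]])
  }
  0L
}

# Axis-aligned rectangle ring in map coordinates from pixel block indices.
rectRing <- function(grid, r0, r1, c0, c1) {
  g <- gridGeoref(grid)
  x0 <- g$xll + (c0 - 1) * g$cellsize
  x1 <- g$xll + c1 * g$cellsize
  y1 <- g$yll + (g$rows - r0 + 1) * g$cellsize
  y0 <- g$yll + (g$rows - r1) * g$cellsize
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}
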