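test_that("the reference rule set carries the published thresholds exactly", {
  rules <- referenceRuleSet()
  r <- rules@rules
  wood <- r[r$class == "woodland", ]
  expect_identical(wood$ndvi_min, 0.41); expect_false(wood$ndvi_min_incl)
  expect_identical(wood$bbst_max, 36.5); expect_false(wood$bbst_max_incl)
  grass <- r[r$class == "grassland", ]
  expect_identical(grass$ndvi_max, 0.36); expect_false(grass$ndvi_max_incl)
  expect_identical(grass$bbst_min, 38.6); expect_false(grass$bbst_min_incl)
  shrub <- r[r$class == "shrubland", ]
  expect_identical(c(shrub$ndvi_min, shrub$ndvi_max), c(0.28, 0.51))
  expect_identical(c(shrub$bbst_min, shrub$bbst_max), c(36.7, 39.3))
  expect_true(all(shrub$ndvi_min_incl, shrub$ndvi_max_incl,
                  shrub$bbst_min_incl, shrub$bbst_max_incl))
  expect_identical(rules@precedence, c("woodland", "grassland", "shrubland"))
})

test_that("rule-set serialization round-trips bit-exactly", {
  rules <- referenceRuleSet()
  path <- withr::local_tempfile(fileext = ".json")
  writeRuleSet(rules, path)
  back <- readRuleSet(path)
  expect_identical(back@rules, rules@rules)
  expect_identical(back@precedence, rules@precedence)
})

test_that("classification honors inequalities, precedence and the gap", {
  rules <- referenceRuleSet()
  nd <- rasterGrid(matrix(c(0.55, 0.30, 0.39, 0.45, NA, 0.41), 1),
                   class = "NdviGrid")
  bt <- rasterGrid(matrix(c(34.0, 39.0, 36.6, 38.0, 35, 34.0), 1),
                   class = "TemperatureGrid", unit = "celsius")
  got <- gridValues(applyRules(nd, bt, rules))
  expect_equal(got[1], 3)        # woodland box
  expect_equal(got[2], 1)        # grass and shrub both hold; grass precedes
  expect_equal(got[3], 0)        # inter-rule gap -> unclassified
  expect_equal(got[4], 2)        # only shrub conditions hold
  expect_true(is.na(got[5]))     # nodata propagates
  expect_equal(got[6], 0)        # NDVI exactly 0.41 fails the strict bound
})

test_that("strict and inclusive bounds behave differently at the boundary", {
  rules <- referenceRuleSet()
  expect_false(ruleMatches(rules, "woodland", 0.41, 34))   # strict >
  expect_true(ruleMatches(rules, "shrubland", 0.28, 37))   # inclusive >=
  expect_true(ruleMatches(rules, "shrubland", 0.51, 39.3)) # inclusive <=
  expect_false(ruleMatches(rules, "grassland", 0.36, 39))  # strict <
})

test_that("classification is idempotent and matches the scalar oracle", {
  fx <- localSceneFixture()
  rules <- referenceRuleSet()
  sub <- function(g, cls) rasterGrid(gridValues(g)[1:32, 1:32],
                                     class = cls,
                                     unit = "celsius")
  nd <- sub(fx$ndvi, "NdviGrid"); bt <- sub(fx$bbst, "TemperatureGrid")
  m1 <- applyRules(nd, bt, rules)
  m2 <- applyRules(nd, bt, rules)
  expect_identical(gridValues(m1), gridValues(m2))
  oracle <- matrix(mapply(scalarRuleOracle, gridValues(nd), gridValues(bt),
                          MoreArgs = list(rules = rules)), 32, 32)
  storage.mode(oracle) <- "double"
  expect_identical(gridValues(m1), oracle)
})

test_that("precedence is configurable and changes overlap assignment", {
  rules <- referenceRuleSet()
  flipped <- ruleSet(rules@rules$class,
                     rules@rules$ndvi_min, rules@rules$ndvi_max,
                     rules@rules$bbst_min, rules@rules$bbst_max,
                     rules@rules$ndvi_min_incl, rules@rules$ndvi_max_incl,
                     rules@rules$bbst_min_incl, rules@rules$bbst_max_incl,
                     precedence = c("shrubland", "grassland", "woodland"))
  nd <- rasterGrid(matrix(0.30), class = "NdviGrid")
  bt <- rasterGrid(matrix(39.0), class = "TemperatureGrid", unit = "celsius")
  expect_equal(gridValues(applyRules(nd, bt, rules))[1], 1)     # grassland
  expect_equal(gridValues(applyRules(nd, bt, flipped))[1], 2)   # shrubland
})

test_that("quantile induction recovers generating intervals and point masses", {
  pt <- data.frame(class = rep(coverClasses(), each = 12),
                   ndvi = rep(c(0.2, 0.35, 0.55), each = 12),
                   bbst = rep(c(40, 38, 34), each = 12))
  r0 <- induceRules(pt, 0, 1)@rules
  expect_equal(r0$ndvi_min, r0$ndvi_max)     # degenerate interval
  set.seed(77)
  n <- 10000
  u <- data.frame(class = "woodland", ndvi = runif(n, 0.40, 0.68),
                  bbst = runif(n, 32.5, 36.4))
  u <- rbind(u, data.frame(class = "grassland", ndvi = runif(n, 0.18, 0.38),
                           bbst = runif(n, 38.6, 41.3)),
             data.frame(class = "shrubland", ndvi = runif(n, 0.28, 0.51),
                        bbst = runif(n, 36.7, 39.4)))
  full <- induceRules(u, 0, 1)@rules
  wood <- full[full$class == "woodland", ]
  expect_equal(c(wood$ndvi_min, wood$ndvi_max), c(0.40, 0.68),
               tolerance = 0.005)
  expect_true(wood$bbst_min >= 32.4 && wood$bbst_max <= 36.5)
  expect_error(induceRules(u[1:5, ], 0, 1), "10 samples")
  expect_error(induceRules(u, 0.9, 0.1))
})

test_that("rules induced on scene training pixels recover the true classes", {
  fx <- localSceneFixture()
  induced <- induceRules(fx$samples, 0, 1)
  # in-sample recall with untrimmed boxes is total
  expect_true(all(ruleRecall(fx$samples, induced) == 1))
  cm <- applyRules(fx$ndvi, fx$bbst, induced)
  truth <- gridValues(fx$gen$truth); got <- gridValues(cm)
  # woodland and grassland generating boxes are disjoint from the others'
  for (cl in c("woodland", "grassland")) {
    code <- classLegend()[[cl]]
    expect_gte(mean(got[truth == code] == code), 0.90)
  }
})

test_that("trimmed-quantile boxes keep at least 92% own-class recall", {
  fx <- localSceneFixture()
  induced <- induceRules(fx$samples, 0.02, 0.98)
  expect_true(all(ruleRecall(fx$samples, induced) >= 0.92))
})

test_that("class proportions renormalize and catch degenerate maps", {
  m <- rasterGrid(matrix(3L, 4, 4), class = "ClassGrid")
  expect_equal(unname(classProportions(m)["woodland"]), 100)
  eq <- rasterGrid(matrix(rep(1:3, 27), 9, 9), class = "ClassGrid")
  expect_equal(unname(classProportions(eq)), rep(100 / 3, 3))
  withU <- rasterGrid(matrix(c(0L, 1L, 2L, 3L), 2), class = "ClassGrid")
  expect_equal(sum(classProportions(withU, includeUnclassified = TRUE)), 100)
  expect_equal(unname(classProportions(withU,
                                       includeUnclassified = TRUE)[1]), 25)
  allNA <- rasterGrid(matrix(NA_real_, 2, 2), class = "ClassGrid")
  expect_error(classProportions(allNA), "no unmasked")
})
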