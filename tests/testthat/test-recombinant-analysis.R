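test_that("flanking-marker configurations map to the classification truth table", {
  expect_identical(classifyRecombinant("present", "present"), "CO")
  expect_identical(classifyRecombinant("absent", "present"),
                   "NCO_recipient_606N")
  expect_identical(classifyRecombinant("present", "absent"),
                   "NCO_recipient_609N")
  expect_identical(classifyRecombinant("absent", "absent"), "anomalous")
  expect_message(cls <- classifyRecombinant(c("present", NA), c(NA, "absent")),
                 "unclassified")
  expect_identical(cls, c("unclassified", "unclassified"))
})

test_that("converted sites are read off the genotype relative to the recipient", {
  map <- ryMap()
  st <- stateMatrix(map)
  # NCO with ry609N recipient, conversion of the three sites around +3506
  g <- st[, "ry609N"]
  g[c("3506", "3511", "3610")] <- st[c("3506", "3511", "3610"), "ry606N"]
  cs <- convertedSites(g, map, "ry609N")
  expect_identical(cs$converted, c(3506L, 3511L, 3610L))
  expect_false(cs$discontinuous)
  expect_true(cs$complete)
  # minimal conversion at the selected site only
  g2 <- st[, "ry606N"]; g2["-468"] <- "G"
  cs2 <- convertedSites(g2, map, "ry606N")
  expect_identical(cs2$converted, -468L)
  # discontinuous tracts are reported, not dropped
  g3 <- st[, "ry609N"]
  g3[c("3506", "3735")] <- st[c("3506", "3735"), "ry606N"]
  cs3 <- convertedSites(g3, map, "ry609N")
  expect_identical(cs3$converted, c(3506L, 3735L))
  expect_true(cs3$discontinuous)
  # unsequenced sites are unobserved, third states are an error
  g4 <- g2; g4["355"] <- NA; g4["239"] <- "X"
  expect_error(convertedSites(g4, map, "ry606N"), "239")
  g4["239"] <- st["239", "ry606N"]
  cs4 <- convertedSites(g4, map, "ry606N")
  expect_identical(cs4$unobserved, 355L)
  expect_false(cs4$complete)
})

test_that("tract length estimates follow the midpoint arithmetic", {
  map <- ryMap()
  te <- tractLengths(c(3506, 3511, 3610), map, "ry609N")
  expect_equal(minBp(te), 104)
  expect_equal(midBp(te), 240.5)
  expect_equal(maxBp(te), 376)
  expect_identical(te@leftBound, 3358L)
  expect_identical(te@rightBound, 3735L)
  # single converted site, bounds across the missing zero of the coordinate
  # system (sites -332, -323, -320 unsequenced)
  te2 <- tractLengths(-468, map, "ry606N",
                      observed = setdiff(sitePositions(map),
                                         c(-332, -323, -320)))
  expect_equal(minBp(te2), 0)
  expect_equal(midBp(te2), 299.5)
  expect_equal(maxBp(te2), 598)
  expect_identical(c(te2@leftBound, te2@rightBound), c(-527L, 73L))
  expect_false(te2@complete)
  # with full genotyping the nearest unconverted neighbor is -332
  te3 <- tractLengths(-468, map, "ry606N")
  expect_identical(c(te3@leftBound, te3@rightBound), c(-527L, -332L))
  expect_equal(maxBp(te3), coteToAssembly(-332) - coteToAssembly(-527) - 1)
  # conversion spanning every site on one side is censored at the map edge
  right609 <- sitePositions(map)[sitePositions(map) >= 3506 &
    stateMatrix(map)[, "ry606N"] != stateMatrix(map)[, "ry609N"]]
  te4 <- tractLengths(right609, map, "ry609N")
  expect_true(te4@rightCensored)
  expect_false(te4@leftCensored)
  expect_identical(te4@rightBound, 6998L)
  expect_error(tractLengths(c(3506, 1200), map, "ry609N"), "1200")
})

test_that("tract summaries report mean and standard error of the mean", {
  s <- summarizeTracts(c(100, 200, 300))
  expect_equal(s$mean, 200)
  expect_equal(s$sem, 100 / sqrt(3), tolerance = 1e-12)
  expect_equal(s$n, 3L)
  s1 <- summarizeTracts(444)
  expect_equal(s1$mean, 444)
  expect_true(is.na(s1$sem))
  s0 <- summarizeTracts(c(50, 50, 50, 50))
  expect_equal(s0$sem, 0)
  expect_error(summarizeTracts(numeric()), "no tract")
})

test_that("ordering min <= mid <= max holds across simulated screens", {
  map <- ryMap()
  cfg <- simConfig(3e4, 1, pCO = 0.3, seed = 31)
  sim <- simulateExperiment(cfg, map)
  analyzed <- analyzeRecords(sim$records, map)
  got <- analyzed[!is.na(analyzed$tract_min_bp), ]
  expect_gt(nrow(got), 100)
  expect_true(all(got$tract_min_bp <= got$tract_mid_bp &
                  got$tract_mid_bp <= got$tract_max_bp))
})

test_that("every selectable noncrossover genotype contains its own mutant site converted", {
  map <- ryMap()
  sim <- simulateExperiment(simConfig(2e4, 1, pCO = 0, seed = 13), map)
  analyzed <- analyzeRecords(sim$records, map)
  nco <- analyzed[grepl("^NCO", analyzed$classification), ]
  sel606 <- nco$recipient == "ry606N"
  conv <- strsplit(nco$converted, ",")
  hasOwn <- mapply(function(cv, r606) {
    if (r606) "-468" %in% cv && !"3506" %in% cv
    else "3506" %in% cv && !"-468" %in% cv
  }, conv, sel606)
  expect_true(all(hasOwn))
})

test_that("per-location summaries aggregate counts, rates and tract means", {
  map <- ryMap()
  sim <- simulateExperiment(simConfig(5e4, 1, pCO = 0.4, seed = 21,
                                      locationLabel = "6E"), map)
  analyzed <- analyzeRecords(sim$records, map)
  sumy <- summarizeByLocation(analyzed, c("6E" = 5e4))
  expect_identical(sumy$co + sumy$nco + sumy$anomalous + sumy$unclassified,
                   nrow(analyzed))
  expect_equal(sumy$co_rate, sumy$co / 5e4)
  expect_true(sumy$tract_n <= sumy$nco)
  expect_true(sumy$tract_mean_bp > 0)
})
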