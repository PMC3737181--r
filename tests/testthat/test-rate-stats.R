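test_that("event rates reproduce the screen arithmetic and flag empty screens", {
  expect_equal(signif(eventRate(112, 3710000)$rate, 2), 3.0e-5)
  expect_equal(signif(eventRate(10, 943000)$rate, 2), 1.1e-5)
  r0 <- eventRate(0, 1285800)
  expect_equal(r0$rate, 0)
  expect_true(r0$noEvents)
  expect_error(eventRate(5, 0), "positive")
})

test_that("per-thousand tables pair events with rounded thousands of progeny", {
  tab <- perThousandTable(112, 3710000, 6, 943000)
  expect_identical(unname(tab), matrix(c(112L, 3710L, 6L, 943L), 2,
                                       byrow = TRUE))
  # half-up rounding: 903,500 progeny count as 904 thousand
  expect_identical(perThousandTable(10, 903500, 1, 1000)[1, 2], 904L)
  expect_identical(unname(perThousandTable(0, 1000, 0, 1000)),
                   matrix(c(0L, 1L, 0L, 1L), 2, byrow = TRUE))
  expect_error(perThousandTable(5, 2000, 1, 1000), "exceed")
})

test_that("the exact test matches closed-form enumeration and the stats oracle", {
  # full enumeration over k in {0, 1, 2} hypergeometric outcomes
  expect_equal(pValue(fisherTwoSided(matrix(c(2, 8, 0, 10), 2, byrow = TRUE))),
               0.473684210526, tolerance = 1e-10)
  # degenerate margin
  expect_equal(pValue(fisherTwoSided(matrix(c(0, 10, 0, 10), 2,
                                            byrow = TRUE))), 1.0)
  # expectation-conforming table has p = 1
  expect_equal(pValue(fisherTwoSided(matrix(c(5, 5, 5, 5), 2))), 1.0)
  # agreement with stats::fisher.test across random tables, small and large
  set.seed(7)
  for (i in 1:40) {
    tab <- matrix(rpois(4, lambda = sample(c(3, 40, 900), 1)), 2)
    if (sum(tab) == 0) next
    expect_equal(pValue(fisherTwoSided(tab)),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-8)
  }
  expect_error(fisherTwoSided(matrix(c(-1, 2, 3, 4), 2)), "nonnegative")
})

test_that("the two-sided p-value is symmetric in rows, columns and transposition", {
  set.seed(11)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 15), 2)
    if (sum(tab) == 0) next
    p <- pValue(fisherTwoSided(tab))
    expect_equal(pValue(fisherTwoSided(tab[2:1, ])), p, tolerance = 1e-12)
    expect_equal(pValue(fisherTwoSided(tab[, 2:1])), p, tolerance = 1e-12)
    expect_equal(pValue(fisherTwoSided(t(tab))), p, tolerance = 1e-12)
  }
})

test_that("selection-corrected map units and per-Mb normalisation", {
  expect_equal(mapUnits(6, 943000), 0.0012725, tolerance = 1e-4)
  expect_equal(mapUnits(0, 1e6), 0)
  expect_equal(mapUnits(10, 903500), 0.0022136, tolerance = 1e-4)
  expect_equal(round(mapUnitsPerMb(mapUnits(6, 943000), 3974), 2), 0.32)
  expect_equal(round(mapUnitsPerMb(mapUnits(10, 903500), 3974), 2), 0.56)
  expect_equal(round(regionalRate(2.4, 1.75), 2), 1.37)
  expect_equal(round(regionalRate(1.1, 2.2), 2), 0.50)
  expect_equal(regionalRate(5, 1.6), 3.125)
  expect_equal(regionalRate(0, 1.0), 0)
  expect_error(mapUnitsPerMb(1, 0), "positive")
  expect_error(regionalRate(1, -2), "positive")
})

test_that("location comparisons assemble rates, ratios and exact tests", {
  counts <- ryCounts()
  cmp <- compareLocations(counts, "86E")
  expect_identical(nrow(cmp$tests), 8L)
  co6 <- cmp$tests[cmp$tests$location == "6E" & cmp$tests$class == "CO", ]
  expect_lt(co6$p_value, 0.0001)
  co20 <- cmp$tests[cmp$tests$location == "20C" & cmp$tests$class == "CO", ]
  expect_equal(signif(co20$p_value, 2), 0.0010)
  expect_true(all(cmp$rates$co_no_events[cmp$rates$location %in%
                                           c("2A", "102D")]))
  # single-row input: empty comparison set
  one <- counts[counts$location == "86E", ]
  expect_identical(nrow(compareLocations(one, "86E")$tests), 0L)
  expect_error(compareLocations(counts, "nowhere"), "not found")
  expect_error(compareLocations(rbind(counts, counts[1, ]), "86E"),
               "duplicate")
})

test_that("simulated crossover screens recover the configured map distance", {
  map <- ryMap()
  # short tracts and a window inside the selected interval keep every
  # crossover exchange between the selected sites, so the recombinant
  # fraction equals the event rate
  cfg <- simConfig(5e5, 1.2e-4, pCO = 1, meanTractBp = 100,
                   dsbWindow = c(500L, 2500L), seed = 17)
  sim <- simulateExperiment(cfg, map)
  co <- unname(sim$trueCounts["selected_co"])
  cm <- mapUnits(co, cfg@nProgeny, recoveryFactor = 2)
  target <- 100 * cfg@eventRate
  mcse <- 100 * 2 * sqrt(cfg@nProgeny * cfg@eventRate / 2) / cfg@nProgeny
  expect_lt(abs(cm - target), 3 * mcse)
})
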