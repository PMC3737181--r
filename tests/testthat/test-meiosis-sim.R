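test_that("event draws respect the resolution probability and the seed", {
  map <- ryMap()
  cfgNCO <- simConfig(1e5, 6e-5, pCO = 0, seed = 1)
  set.seed(1)
  outcomes <- replicate(200, drawEvent(cfgNCO, map)@outcome)
  expect_true(all(outcomes == "NCO"))
  cfg <- simConfig(1e5, 6e-5, pCO = 0.5, seed = 1)
  set.seed(99); e1 <- drawEvent(cfg, map)
  set.seed(99); e2 <- drawEvent(cfg, map)
  expect_equal(e1, e2)
  expect_true(e1@dsbPosition >= e1@tract[1] && e1@dsbPosition <= e1@tract[2])
})

test_that("tract lengths follow the two-sided geometric model", {
  map <- ryMap()
  cfg <- simConfig(1e5, 6e-5, meanTractBp = 800, seed = 1)
  set.seed(5)
  ev <- ryrec:::.drawEvents(cfg, map, 1e5)
  len <- ev$rightAsm - ev$leftAsm
  se <- sd(len) / sqrt(length(len))
  expect_lt(abs(mean(len) - 800), 3 * se)
  # initiation sites are uniform on the window and inside every tract
  expect_true(all(ev$dsbAsm >= ev$leftAsm & ev$dsbAsm <= ev$rightAsm))
  w <- coteToAssembly(c(-3149, 6998))
  expect_true(all(ev$dsbAsm >= w[1] & ev$dsbAsm <= w[2]))
  expect_lt(abs(mean(ev$dsbAsm) - mean(w)), 4 * sd(ev$dsbAsm) / sqrt(1e5))
})

test_that("noncrossover conversion substitutes donor states inside the tract only", {
  map <- ryMap()
  h606 <- haplotype(map, "ry606N")
  h609 <- haplotype(map, "ry609N")
  ev <- new("RecombinationEvent", recipient = "ry606N",
            dsbPosition = -200L, tract = c(-500L, 100L), outcome = "NCO",
            exchangePoint = NA_integer_)
  g <- applyEvent(ev, list(h606, h609), map)
  inside <- c("-468", "-332", "-323", "-320", "73")
  expect_identical(unname(g@states[inside]), unname(h609@states[inside]))
  outside <- setdiff(names(g@states), inside)
  expect_identical(g@states[outside], h606@states[outside])
  expect_true(isFunctional(g, map))
  # a tract containing no informative site leaves the recipient unchanged
  ev0 <- new("RecombinationEvent", recipient = "ry606N",
             dsbPosition = 5000L, tract = c(4400L, 5500L), outcome = "NCO",
             exchangePoint = NA_integer_)
  g0 <- applyEvent(ev0, list(h606, h609), map)
  expect_identical(unname(g0@states), unname(h606@states))
  # conversion is non-reciprocal: donor information is never altered
  expect_identical(h609, haplotype(map, "ry609N"))
})

test_that("a crossover between the selected sites yields exactly one selectable product", {
  map <- ryMap()
  parents <- list(haplotype(map, "ry606N"), haplotype(map, "ry609N"))
  set.seed(3)
  for (exch in c("left", "right")) {
    ev <- new("RecombinationEvent", recipient = "ry609N",
              dsbPosition = 1500L, tract = c(1200L, 1800L), outcome = "CO",
              exchangePoint = if (exch == "left") 1200L else 1800L)
    funs <- replicate(60, isFunctional(applyEvent(ev, parents, map), map))
    # both reciprocal products appear; exactly one of the two is functional
    expect_setequal(unique(funs), c(TRUE, FALSE))
  }
})

test_that("tracts reaching beyond the map span are truncated with a warning", {
  map <- ryMap()
  parents <- list(haplotype(map, "ry606N"), haplotype(map, "ry609N"))
  ev <- new("RecombinationEvent", recipient = "ry606N",
            dsbPosition = 6900L, tract = c(6000L, 9000L), outcome = "NCO",
            exchangePoint = NA_integer_)
  expect_warning(g <- applyEvent(ev, parents, map), "truncat")
  expect_identical(unname(g@states["6998"]), "G")  # still converted
})

test_that("simulated screens are reproducible and selection-sound", {
  map <- ryMap()
  cfg <- simConfig(2e5, 6e-5, seed = 11, locationLabel = "6E")
  s1 <- simulateExperiment(cfg, map)
  s2 <- simulateExperiment(cfg, map)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$totalProgeny, 2e5)
  # every selected gamete is wild type at both selected positions
  expect_true(all(s1$records[["-468"]] == "G" & s1$records[["3506"]] == "G"))
  # no events, no selected recombinants (parental gametes are nonfunctional)
  s0 <- simulateExperiment(simConfig(5e4, 0, seed = 1), map)
  expect_identical(nrow(s0$records), 0L)
  expect_identical(unname(s0$trueCounts["events"]), 0L)
})

test_that("selected crossover counts match the analytic expectation", {
  map <- ryMap()
  cfg <- simConfig(1e6, 6e-5, pCO = 1, meanTractBp = 800,
                   dsbWindow = c(-3149L, 6998L), seed = 2024)
  sim <- simulateExperiment(cfg, map)
  expected <- cfg@nProgeny * cfg@eventRate *
    pSelectedCO(map, c(-3149, 6998), 800)
  observed <- unname(sim$trueCounts["selected_co"])
  expect_lt(abs(observed - expected), 3 * sqrt(expected))
})

test_that("half of crossover products are recovered when exchanges sit between the selected sites", {
  map <- ryMap()
  # narrow window and short tracts keep every exchange inside the selected
  # interval and away from the selected sites themselves
  cfg <- simConfig(4e3, 1, pCO = 1, meanTractBp = 100,
                   dsbWindow = c(500L, 2500L), seed = 8)
  sim <- simulateExperiment(cfg, map)
  frac <- unname(sim$trueCounts["selected"]) / unname(sim$trueCounts["events"])
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 4e3))
})

test_that("progeny estimation from untreated bottles follows the tray arithmetic", {
  expect_equal(estimateProgeny(500, 25, 1, "treated_only"), 12000)
  expect_equal(estimateProgeny(0, 25, 4, "treated_only"), 0)
  expect_equal(estimateProgeny(500, 25, 1, "all"), 12500)
  expect_error(estimateProgeny(500, 1, 1), "at least 2")
  # emulation inside a simulated screen lands near the true total
  map <- ryMap()
  cfg <- simConfig(6e4, 0, seed = 4, trays = 10L)
  sim <- simulateExperiment(cfg, map)
  expect_lt(abs(sim$progenyEstimate / (6e4 * 24 / 25) - 1), 0.15)
})

test_that("configuration files are validated", {
  tf <- tempfile(fileext = ".yaml")
  writeLines(c("n_progeny: 1000", "event_rate: 0.001", "seed: 3",
               "bogus_key: 1"), tf)
  expect_error(readSimConfig(tf), "bogus_key")
  writeLines(c("n_progeny: 1000", "event_rate: 2", "seed: 3"), tf)
  expect_error(readSimConfig(tf), "eventRate")
  cfg <- readSimConfig(system.file("extdata", "example_sim.yaml",
                                   package = "ryrec"))
  expect_s4_class(cfg, "SimConfig")
  expect_equal(cfg@eventRate, 6e-5)
  expect_equal(cfg@dsbWindow, c(-3149L, 6998L))
})
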