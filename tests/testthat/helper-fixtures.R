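# shared fixtures and independent oracles

ryMap <- function() {
  loadMarkerMap(system.file("extdata", "table1_marker_map.tsv",
                            package = "ryrec"))
}

ryCounts <- function() {
  readLocationCounts(system.file("extdata", "table2_counts.tsv",
                                 package = "ryrec"))
}

ryIntervals <- function() {
  readIntervals(system.file("extdata", "fig4_intervals.tsv",
                            package = "ryrec"))
}

# independent brute-force two-sided Fisher p: enumerate every table with the
# observed margins, probability from binomial coefficients, sum of point
# probabilities <= observed (same 1e-7 relative tie rule as the tested code)
bruteFisherP <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  k <- max(0L, c1 - r2):min(r1, c1)
  pk <- choose(r1, k) * choose(r2, c1 - k) / choose(r1 + r2, c1)
  pobs <- pk[k == tab[1, 1]]
  min(1, sum(pk[pk <= pobs * (1 + 1e-7)]))
}

# analytic probability that a crossover event yields a selectable (ry+)
# transmitted gamete: the functional reciprocal product exists iff the
# relevant tract end falls between the two selected sites (right end for a
# ry606N recipient, left end for ry609N), and it is transmitted with
# probability 1/2. DSB uniform on the window, one-sided geometric tails.
pSelectedCO <- function(map, windowCote, meanTractBp) {
  sel <- sort(coteToAssembly(selectedPositions(map)))
  a <- sel[1]; b <- sel[2]
  d <- coteToAssembly(windowCote[1]):coteToAssembly(windowCote[2])
  p <- 1 / (meanTractBp / 2 + 1)
  pRight <- mean(pgeom(b - 1 - d, p) - pgeom(a - 1 - d, p))
  pLeft <- mean(pgeom(d - a - 1, p) - pgeom(d - b - 1, p))
  0.5 * (pRight + pLeft) / 2
}
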