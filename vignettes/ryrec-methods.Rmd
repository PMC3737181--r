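---
title: "Methods: models, estimators and the meiosis simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and the meiosis simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ryrec)
```

# The experimental system

`ryrec` models a classical fine-structure recombination assay.  Two
transgenic copies of the *Drosophila melanogaster* *rosy* (*ry*) gene, each
inactivated by a different point mutation, are placed at allelic positions
on homologous chromosomes in a *ry* mutant background.  The transgene
alleles, `ry606N` and `ry609N`, differ at 25 sequence heterologies across
roughly 10 kb.  Meiotic recombination between the two defective copies can
reconstitute a functional `ry+` gene; because *rosy* encodes xanthine
dehydrogenase, `ry+` progeny are recovered by purine selection, which kills
all non-recombinant offspring.  Each surviving fly is a single recombinant
chromatid whose genotype across the heterologies can be read out.

Two heterologies are *selected sites*: the inactivating lesion of each
allele (`-468` in `ry606N`, `+3506` in `ry609N`).  A selected chromatid must
carry the functional state at both.  Two further heterologies are *flanking
markers* — restriction-site polymorphisms outside the selected interval
(a KpnI site at `-3149`, absent from `ry606N`, and an AgeI site at `+6998`,
absent from `ry609N`) — that classify each recombinant:

| KpnI | AgeI | Class |
|------|------|-------|
| present | present | crossover (CO) |
| absent  | present | noncrossover (NCO), recipient `ry606N` |
| present | absent  | noncrossover (NCO), recipient `ry609N` |
| absent  | absent  | anomalous |

A CO exchanges the flanks; an NCO is a local gene conversion that leaves
the flanks parental, and the converted ("recipient") chromosome is
identified by which parental flank combination survives.

# Coordinates

Positions use a transgene-local coordinate system in which position `+1`
corresponds to assembly coordinate 8,859,890 on chromosome arm 3R and
**position 0 does not exist**: `-1` immediately precedes `+1`.  All distance
arithmetic is therefore performed in assembly coordinates via
`coteToAssembly()` / `assemblyToCote()`:

```{r}
coteToAssembly(c(-1, 1))          # adjacent base pairs
coteToAssembly(3506) - coteToAssembly(-468) + 1   # selected-interval span
```

The packaged marker map carries all 25 heterologies with their states on
each allele and their roles:

```{r}
map <- loadMarkerMap(system.file("extdata", "table1_marker_map.tsv",
                                 package = "ryrec"))
map
selectedPositions(map); flankingPositions(map)
```

The selected interval spans `selectedSpanBp(map)` =
`r selectedSpanBp(map)` bp (inclusive of both selected sites); this is the
physical denominator used when expressing transgene map distances per Mb.

# Conversion tract estimation

For an NCO, the converted sites are the heterologies at which the recipient
chromatid carries the donor state (`convertedSites()`).  Marker density
limits resolution, so `tractLengths()` reports three nested estimates from
the outermost converted sites $c_1 \le c_2$ and the nearest *observed*
unconverted neighbours $u_L < c_1$, $u_R > c_2$ (all in assembly
coordinates):

* **minimum**: $c_2 - c_1$ — the tract certainly covers this,
* **maximum**: $u_R - u_L - 1$ — the tract cannot exceed this,
* **midpoint**: $\frac{c_2 + u_R}{2} - \frac{c_1 + u_L}{2}$ — the expected
  length if each tract end is uniform on its bracketing interval.

```{r}
te <- tractLengths(c(3506, 3511, 3610), map, "ry609N")
te
```

When some heterologies were not genotyped, the `observed` argument restricts
the neighbour search to sequenced sites, widening the bounds honestly:

```{r}
tractLengths(-468, map, "ry606N",
             observed = setdiff(sitePositions(map), c(-332, -323, -320)))
```

Tracts converting every marker to one end of the map are flagged as
censored (`leftCensored` / `rightCensored`); discontinuous conversion is
flagged rather than silently split.

# Rates, map units and exact tests

`eventRate()` is events per progeny scored.  Because purine selection kills
the non-recombinant siblings, only half of each meiosis' products are
recoverable in expectation, so genetic distance applies a recovery factor
of 2:

$$ \text{cM} = 100 \times 2 \times \frac{\text{CO}}{\text{progeny}} $$

`mapUnitsPerMb()` divides by the physical span in Mb, and `regionalRate()`
does the same for conventional marker intervals, allowing the transgene
interval to be compared with region-scale crossover rates:

```{r}
mapUnitsPerMb(mapUnits(6, 943000), selectedSpanBp(map))
regionalRate(2.4, 1.75)   # cM over Mb for a flanking-marker interval
```

Rates between genomic locations are compared with a two-sided Fisher exact
test on a 2×2 table pairing event counts with progeny counts **in
thousands** (rounded half-up); with screens of $10^6$ progeny and event
counts of order 10, tables of raw progeny counts are numerically
unnecessary and the per-thousand convention matches how such screens are
conventionally tabulated.  `fisherTwoSided()` computes the exact
hypergeometric two-sided p-value (point probabilities at most that of the
observed table, with a relative tolerance of $10^{-7}$ for ties) in log
space; it agrees with `stats::fisher.test()` and with brute-force
enumeration (see the test suite).

```{r}
counts <- readLocationCounts(system.file("extdata", "table2_counts.tsv",
                                         package = "ryrec"))
cmp <- compareLocations(counts, baseline = "86E")
cmp$tests
```

# The meiosis simulator

`simulateExperiment()` is a forward generator of fully labelled synthetic
screens, used to validate the analysis chain against a known truth.  Its
model, chosen for mechanistic transparency rather than biological
completeness:

1. Each transmitted chromatid independently experiences a recombination
   event at the selected locus with probability `eventRate` (so the
   per-screen event count is binomial; chromatids without events can never
   survive selection and are not materialised).
2. An event initiates at a double-strand break drawn uniformly on
   `dsbWindow` (default: the full marker span).
3. The conversion tract extends from the break by two independent
   geometric lengths with mean `meanTractBp / 2` each, giving a mean total
   tract of `meanTractBp`; the recipient chromatid is chosen uniformly.
4. With probability `pCO` the event resolves as a CO, with the exchange
   point placed at a uniformly chosen tract end and one of the two
   reciprocal products transmitted at random; otherwise it resolves as an
   NCO that substitutes donor states inside the tract only
   (conversion is non-reciprocal).
5. Purine selection keeps exactly the products that are functional at both
   selected sites; selected records carry the observable genotype plus the
   true outcome, recipient and tract for validation.

Defaults (`eventRate = 6e-5`, `pCO = 0.5`, `meanTractBp = 800`) are of the
magnitude the analysis functions are designed for: screens of $10^5$ to a
few $10^6$ progeny yielding tens to hundreds of selected recombinants, and
tract lengths comparable to the marker spacing so that censoring and
partial-conversion corner cases are exercised.  The simulator deliberately
omits chromatid interference, meiotic drive, mismatch-repair patchiness
(discontinuous tracts) and viability effects; it is an idealisation of the
selection assay, not of meiosis.

```{r}
cfg <- simConfig(nProgeny = 2e5, eventRate = 6e-5, pCO = 0.5,
                 meanTractBp = 800, seed = 7)
sim <- simulateExperiment(cfg, map)
sim$trueCounts
head(analyzeRecords(sim$records, map)[, 1:8])
```

`estimateProgeny()` emulates how screen sizes are estimated in practice:
progeny are counted in a small number of untreated bottles and scaled by
the bottles per tray.

## Calibration experiments

Two designed simulations tie the estimators to the generator (both are run
in the test suite):

* **Map-distance recovery.** With `pCO = 1`, short tracts
  (`meanTractBp = 100`) and `dsbWindow = c(500, 2500)` every exchange point
  falls strictly between the selected sites, so exactly one reciprocal
  product of every event is selectable and is transmitted with probability
  ½.  The recombinant fraction after the factor-2 recovery correction then
  equals `eventRate` exactly in expectation, and `mapUnits()` recovers
  `100 * eventRate` to within Monte-Carlo error.
* **Classifier fidelity.** Flanking-marker classification is exact for
  every CO and for every NCO whose tract does not reach a flanking marker;
  the only possible misclassification is co-conversion of a flank, which
  the simulation labels and the tests verify is the sole source of error.

# Numerical choices

* Distances are always computed in assembly coordinates; the missing
  position 0 makes local-coordinate subtraction off by one across the
  origin.
* `perThousandTable()` rounds progeny to thousands *half-up*
  (`floor(x + 0.5)`), not by `round()`, whose round-half-even rule would
  tabulate 903,500 progeny as 903 rather than 904 thousand.
* `fisherTwoSided()` accumulates hypergeometric point masses in log space
  so that tables with margins in the thousands do not underflow.
* Geometric tract halves use `rgeom(p = 1 / (meanTractBp/2 + 1))`, whose
  mean is exactly `meanTractBp / 2`.

# Session info

```{r}
sessionInfo()
```
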