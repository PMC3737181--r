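# ryrec

Crossover and noncrossover analysis of intragenic meiotic recombination
between heteroallelic *rosy* transgenes in *Drosophila melanogaster*.

## The scientific problem

Two transgenic copies of the *rosy* (*ry*) gene, each killed by a different
point mutation (`ry606N` at position −468, `ry609N` at position +3506), sit
at allelic positions on homologous chromosomes. Meiotic recombination
between them can reconstitute a functional `ry⁺` gene, and purine selection
recovers exactly those rare recombinant progeny — of order 10 per million.
Each survivor is a single recombinant chromatid genotyped across the 25
sequence heterologies that distinguish the two alleles.

Two restriction-site polymorphisms flanking the selected interval (KpnI at
−3149, absent from `ry606N`; AgeI at +6998, absent from `ry609N`) classify
each recombinant: both sites present means a **crossover** (CO, flanks
exchanged); one parental flank combination means a **noncrossover gene
conversion** (NCO) and identifies which chromosome was the conversion
recipient. From the co-converted heterologies the package estimates
conversion **tract lengths** as a (minimum, midpoint, maximum) triple:
with outermost converted sites c₁ ≤ c₂ and nearest observed unconverted
neighbours u_L, u_R (assembly coordinates),

```
min = c₂ − c₁     mid = (c₂ + u_R)/2 − (c₁ + u_L)/2     max = u_R − u_L − 1
```

Because selection discards the non-recombinant meiotic products, genetic
distance carries a recovery factor of 2:

```
cM = 100 × 2 × CO / progeny
```

normalised per Mb over the 3,974 bp selected interval for comparison with
region-scale crossover rates. Event rates between genomic insertion sites
are compared by a two-sided Fisher exact test on 2×2 tables of event counts
versus progeny in thousands.

Positions use a transgene-local coordinate system anchored at assembly
3R:8,859,890 with **no position 0**; all arithmetic is done in assembly
coordinates (`coteToAssembly()`).

A forward **meiosis simulator** (`simulateExperiment()`) generates fully
labelled synthetic screens — binomial event counts, uniform initiation,
two-sided geometric conversion tracts, CO resolution with probability
`pCO`, truthful purine selection — so every estimator can be validated
against a known ground truth. See the methods vignette
(`vignettes/ryrec-methods.Rmd`) for the model and its limitations.

## Worked example

```r
library(ryrec)
map <- loadMarkerMap(system.file("extdata", "table1_marker_map.tsv",
                                 package = "ryrec"))
map
#> MarkerMap with 25 polymorphic sites
#>   alleles: ry_plus, ry606N, ry609N
#>   span: -3149 .. 6998 (anchor 3R:8,859,890)
#>   selected: -468, 3506  flanking: -3149, 6998

## rate comparisons between insertion sites, against the 86E baseline
counts <- readLocationCounts(system.file("extdata", "table2_counts.tsv",
                                         package = "ryrec"))
cmp <- compareLocations(counts, "86E")
cmp$tests[1:4, c("location", "class", "n", "baseline_n", "p_value")]
#>   location class  n baseline_n      p_value
#> 1       6E    CO  6        112 6.083790e-06
#> 2       6E   NCO 10         53 5.266828e-01
#> 3      20C    CO 10        112 1.007001e-03
#> 4      20C   NCO  7         53 1.408112e-01

## conversion tract bounds for an NCO converting +3506, +3511, +3610
tractLengths(c(3506, 3511, 3610), map, "ry609N")
#> TractEstimate: min 104 / mid 240.5 / max 376 bp
#>   converted: 3506, 3511, 3610
#>   bounds: 3358 .. 3735

## a labelled synthetic screen, analysed blind and checked against truth
cfg <- simConfig(nProgeny = 2e5, eventRate = 6e-5, pCO = 0.5, seed = 7)
sim <- simulateExperiment(cfg, map)
sim$trueCounts
#>       events     selected  selected_co selected_nco
#>           21            6            5            1
table(analyzeRecords(sim$records, map)$classification)
#>                 CO NCO_recipient_606N
#>                  5                  1
```

A small command-line front end wrapping simulate / analyze / rates lives at
`inst/scripts/ryrec.R` (requires `optparse`).

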