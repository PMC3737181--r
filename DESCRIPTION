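Package: ryrec
Title: Crossover and Noncrossover Analysis of Intragenic Recombination
    at rosy Transgenes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of intragenic meiotic recombination assays between
    heteroallelic rosy (ry) transgenes in Drosophila melanogaster.
    Provides a marker-map model of the polymorphisms distinguishing the
    ry606N and ry609N transgenes, classification of purine-selected ry+
    recombinants into crossovers and noncrossover gene conversions from
    flanking restriction-site markers, midpoint estimation of gene
    conversion tract lengths from co-converted polymorphisms,
    recombination-rate and selection-corrected genetic map-distance
    computation, Fisher exact comparisons of event rates between genomic
    locations, and a forward simulator of meioses that generates fully
    labelled synthetic recombinant data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'markerMap.R'
    'simulate.R'
    'classify.R'
    'rates.R'
    'report.R'
    'ryrec-package.R'
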