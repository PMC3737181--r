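## Central S4 classes. Coordinates follow the rosy-locus ("Cote") convention:
## +1 lies inside an EcoRI site in the second exon (assembly 3R:8,859,890) and
## position zero does not exist, so all distance arithmetic is performed after
## conversion to 1-based assembly coordinates.

#' MarkerMap: ordered polymorphic sites distinguishing transgene haplotypes
#'
#' A \code{MarkerMap} holds the ordered polymorphic sites that distinguish the
#' transgene alleles carried by the two homologs of an intragenic
#' recombination assay, together with the sequence state of every allele at
#' every site, the role of each site (\code{selected}, \code{flanking} or
#' \code{silent}) and the genome-assembly coordinate of locus position +1.
#'
#' Site positions are signed rosy-locus coordinates (no position zero).
#' Exactly two sites are \code{selected} (the mutant positions the purine
#' selection acts on) and exactly two are \code{flanking} (the restriction-site
#' markers used to distinguish crossovers from noncrossovers); the flanking
#' sites must bracket the selected sites.
#'
#' @slot sites data.frame with columns \code{position} (signed integer),
#'   \code{role} and \code{note}, in strictly ascending position order.
#' @slot states character matrix, one row per site, one column per allele
#'   (column names are the allele labels); \code{"-"} denotes a deletion.
#' @slot anchor numeric(1), 1-based assembly coordinate of locus position +1.
#' @slot chrom character(1), assembly sequence name (informational).
#'
#' @seealso [loadMarkerMap()], [haplotype()], [heterologies()]
#' @export
setClass("MarkerMap",
  representation(
    sites  = "data.frame",
    states = "matrix",
    anchor = "numeric",
    chrom  = "character"
  )
)

setValidity("MarkerMap", function(object) {
  msg <- character()
  s <- object@sites
  if (nrow(s) == 0L) return("no sites")
  if (!all(c("position", "role", "note") %in% names(s)))
    msg <- c(msg, "sites must have columns position, role, note")
  else {
    pos <- s$position
    if (any(pos == 0L))
      msg <- c(msg, "position 0 does not exist in the locus coordinate system")
    if (anyDuplicated(pos))
      msg <- c(msg, sprintf("duplicate position: %s",
                            paste(unique(pos[duplicated(pos)]), collapse = ", ")))
    if (is.unsorted(pos, strictly = TRUE))
      msg <- c(msg, "positions must be strictly increasing")
    if (!all(s$role %in% c("selected", "flanking", "silent")))
      msg <- c(msg, "role must be one of selected, flanking, silent")
    nsel <- sum(s$role == "selected"); nfl <- sum(s$role == "flanking")
    if (nsel != 2L)
      msg <- c(msg, sprintf("need exactly 2 selected sites, found %d", nsel))
    if (nfl != 2L)
      msg <- c(msg, sprintf("need exactly 2 flanking sites, found %d", nfl))
    if (nsel == 2L && nfl == 2L) {
      sel <- range(pos[s$role == "selected"])
      fl  <- range(pos[s$role == "flanking"])
      if (!(fl[1] < sel[1] && fl[2] > sel[2]))
        msg <- c(msg, "flanking sites must bracket the selected sites")
    }
  }
  st <- object@states
  if (!is.character(st) || nrow(st) != nrow(s))
    msg <- c(msg, "states must be a character matrix with one row per site")
  else {
    if (is.null(colnames(st)) || ncol(st) < 2L)
      msg <- c(msg, "states needs at least two named allele columns")
    else {
      mono <- apply(st, 1L, function(x) length(unique(x)) < 2L)
      if (any(mono))
        msg <- c(msg, sprintf("site %s has no allelic difference",
                              paste(s$position[mono], collapse = ", ")))
    }
  }
  if (length(object@anchor) != 1L || !is.finite(object@anchor) ||
      object@anchor < 1)
    msg <- c(msg, "anchor must be a single positive assembly coordinate")
  if (length(msg)) msg else TRUE
})

#' Haplotype: the state of one allele at every site of a MarkerMap
#'
#' @slot label character(1) allele name.
#' @slot states named character vector, one state per map site (names are the
#'   site positions as written in the map).
#' @slot positions integer vector of the originating map's site positions,
#'   used to refuse comparisons between haplotypes from different maps.
#'
#' @seealso [haplotype()], [isFunctional()]
#' @export
setClass("Haplotype",
  representation(label = "character", states = "character",
                 positions = "integer")
)

setValidity("Haplotype", function(object) {
  if (length(object@label) != 1L) return("label must be a single string")
  if (length(object@states) != length(object@positions))
    return("states and positions differ in length")
  TRUE
})

#' SimConfig: parameters of a simulated intragenic recombination screen
#'
#' Describes one simulated purine-selection experiment: progeny screened,
#' per-chromatid probability of a recombination event at the transgene, the
#' crossover/noncrossover resolution probability, the conversion-tract model
#' (two-sided geometric around the initiating double-strand break), the
#' interval over which initiation sites are drawn, and the selection recovery
#' factor (2: only the ry+ half of crossover products survives selection).
#'
#' @slot nProgeny numeric(1), progeny (transmitted chromatids) screened.
#' @slot eventRate numeric(1) in [0,1], probability a transmitted chromatid
#'   carries a recombination event at the transgene.
#' @slot pCO numeric(1) in [0,1], probability an event resolves as crossover.
#' @slot meanTractBp numeric(1) > 0, mean total conversion tract length (bp).
#' @slot dsbWindow integer(2), locus-coordinate interval from which the
#'   initiation site is drawn uniformly; must lie within the marker-map span.
#' @slot locationLabel character(1), genomic location tag (e.g. "6E").
#' @slot seed integer(1), seed governing all randomness of the run.
#' @slot selectionRecovery numeric(1) > 0, factor relating total to recovered
#'   crossovers (default 2).
#' @slot bottlesPerTray integer(1) >= 2, bottles per tray for the
#'   progeny-count estimation emulation.
#' @slot trays integer(1), number of trays for the emulation (NA to skip).
#'
#' @seealso [simConfig()], [simulateExperiment()]
#' @export
setClass("SimConfig",
  representation(
    nProgeny = "numeric", eventRate = "numeric", pCO = "numeric",
    meanTractBp = "numeric", dsbWindow = "integer",
    locationLabel = "character", seed = "integer",
    selectionRecovery = "numeric", bottlesPerTray = "integer",
    trays = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  chk1 <- function(x, nm) if (length(x) != 1L || is.na(x))
    sprintf("%s must be a single non-missing value", nm) else NULL
  msg <- c(msg, chk1(object@nProgeny, "nProgeny"),
           chk1(object@eventRate, "eventRate"), chk1(object@pCO, "pCO"),
           chk1(object@meanTractBp, "meanTractBp"))
  if (length(msg) == 0L) {
    if (object@nProgeny < 0 || object@nProgeny != round(object@nProgeny))
      msg <- c(msg, "nProgeny must be a nonnegative integer")
    if (object@eventRate < 0 || object@eventRate > 1)
      msg <- c(msg, "eventRate must be in [0, 1]")
    if (object@pCO < 0 || object@pCO > 1)
      msg <- c(msg, "pCO must be in [0, 1]")
    if (object@meanTractBp <= 0)
      msg <- c(msg, "meanTractBp must be positive")
    if (length(object@dsbWindow) != 2L || any(object@dsbWindow == 0L) ||
        object@dsbWindow[1] > object@dsbWindow[2])
      msg <- c(msg, "dsbWindow must be two nonzero positions, left <= right")
    if (object@selectionRecovery <= 0)
      msg <- c(msg, "selectionRecovery must be positive")
    if (!is.na(object@bottlesPerTray) && object@bottlesPerTray < 2L)
      msg <- c(msg, "bottlesPerTray must be at least 2")
  }
  if (length(msg)) msg else TRUE
})

#' RecombinationEvent: one simulated double-strand-break repair event
#'
#' @slot recipient character(1), allele label of the broken (converted)
#'   chromatid.
#' @slot dsbPosition integer(1), locus coordinate of the initiation site.
#' @slot tract integer(2), closed locus-coordinate interval of the conversion
#'   tract (contains the initiation site).
#' @slot outcome character(1), \code{"CO"} or \code{"NCO"}.
#' @slot exchangePoint integer(1), locus coordinate of the crossover exchange
#'   (one of the tract ends); NA for noncrossovers.
#'
#' @seealso [drawEvent()], [applyEvent()]
#' @export
setClass("RecombinationEvent",
  representation(recipient = "character", dsbPosition = "integer",
                 tract = "integer", outcome = "character",
                 exchangePoint = "integer")
)

setValidity("RecombinationEvent", function(object) {
  msg <- character()
  if (!object@outcome %in% c("CO", "NCO"))
    msg <- c(msg, "outcome must be CO or NCO")
  if (length(object@tract) != 2L || object@tract[1] > object@tract[2])
    msg <- c(msg, "tract must be a closed interval [left, right]")
  else {
    if (object@dsbPosition < object@tract[1] ||
        object@dsbPosition > object@tract[2])
      msg <- c(msg, "dsbPosition must lie within the tract")
    if (object@outcome == "NCO" && !is.na(object@exchangePoint))
      msg <- c(msg, "noncrossovers have no exchange point")
    if (object@outcome == "CO" &&
        (is.na(object@exchangePoint) ||
         !object@exchangePoint %in% object@tract))
      msg <- c(msg, "crossover exchange point must be a tract end")
  }
  if (length(msg)) msg else TRUE
})

#' TractEstimate: minimum/midpoint/maximum gene conversion tract lengths
#'
#' Lengths (bp) are computed in assembly coordinates. \code{minBp} is the span
#' of the outermost converted sites (0 for a single converted site);
#' \code{midBp} is the midpoint estimate, halfway between each outermost
#' converted site and its nearest observed unconverted neighbor;
#' \code{maxBp} is the largest length compatible with the nearest unconverted
#' neighbors (exclusive of both). When no unconverted site exists on one side
#' the map boundary substitutes and the corresponding side is flagged
#' censored.
#'
#' @slot minBp,midBp,maxBp numeric(1), ordered min <= mid <= max.
#' @slot converted integer, converted site positions (locus coordinates).
#' @slot leftBound,rightBound integer(1), nearest observed unconverted
#'   positions (or map boundary when censored).
#' @slot leftCensored,rightCensored logical(1).
#' @slot discontinuous logical(1), TRUE when an observed unconverted site lies
#'   strictly between converted sites.
#' @slot complete logical(1), TRUE when every informative site was observed.
#'
#' @seealso [tractLengths()]
#' @export
setClass("TractEstimate",
  representation(minBp = "numeric", midBp = "numeric", maxBp = "numeric",
                 converted = "integer", leftBound = "integer",
                 rightBound = "integer", leftCensored = "logical",
                 rightCensored = "logical", discontinuous = "logical",
                 complete = "logical")
)

setValidity("TractEstimate", function(object) {
  if (length(object@converted) == 0L) return("converted must be non-empty")
  if (!(object@minBp <= object@midBp && object@midBp <= object@maxBp))
    return("tract lengths must satisfy min <= mid <= max")
  TRUE
})

#' FisherResult: a two-sided Fisher exact test on a 2x2 table
#'
#' @slot table 2x2 integer matrix of the tested counts.
#' @slot pTwoSided numeric(1) in (0, 1].
#' @slot method character(1), tag naming the two-sided rule used.
#'
#' @seealso [fisherTwoSided()]
#' @export
setClass("FisherResult",
  representation(table = "matrix", pTwoSided = "numeric",
                 method = "character")
)

setValidity("FisherResult", function(object) {
  if (!all(dim(object@table) == c(2L, 2L)))
    return("table must be 2x2")
  if (object@pTwoSided <= 0 || object@pTwoSided > 1 + 1e-12)
    return("p must lie in (0, 1]")
  TRUE
})
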