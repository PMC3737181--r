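#' @include classify.R
NULL

## Recombination rates, the per-thousand Fisher exact convention, and
## selection-corrected genetic map distances. Because purine selection
## recovers only the ry+ half of crossover products, map units carry a
## recovery factor of 2: cM = 100 * 2 * crossovers / progeny.

#' Recombination event rate per progeny
#'
#' @param count nonnegative event count(s).
#' @param progeny positive progeny total(s).
#' @return list with \code{rate} (= count/progeny) and \code{noEvents}
#'   (logical; zero-count rates are 0 and flagged, mirroring the "-" entries
#'   of screens that recovered nothing).
#' @examples
#' eventRate(112, 3710000)$rate   # 3.0e-5
#' eventRate(0, 1285800)
#' @export
eventRate <- function(count, progeny) {
  if (any(progeny <= 0)) stop("progeny must be positive")
  if (any(count < 0)) stop("count must be nonnegative")
  list(rate = count / progeny, noEvents = count == 0)
}

# round half away from zero (903.5 -> 904)
.roundHalfUp <- function(x) floor(x + 0.5)

#' Build the per-thousand 2x2 table for a Fisher exact rate comparison
#'
#' Rate comparisons between screens are tested on events against
#' thousands of progeny: each location contributes a row
#' \code{(events, round(progeny/1000))}, with half-up rounding of the
#' thousands (e.g. 112 crossovers from 3710 thousand progeny; 903,500 progeny
#' count as 904 thousand).
#'
#' @param count1,progeny1 events and progeny at the first location.
#' @param count2,progeny2 events and progeny at the second location.
#' @return 2x2 integer matrix, rows = locations,
#'   columns = (events, thousands of progeny).
#' @examples
#' perThousandTable(112, 3710000, 6, 943000)
#' @export
perThousandTable <- function(count1, progeny1, count2, progeny2) {
  if (any(c(count1, count2) < 0)) stop("counts must be nonnegative")
  if (any(c(progeny1, progeny2) <= 0)) stop("progeny must be positive")
  th <- .roundHalfUp(c(progeny1, progeny2) / 1000)
  if (count1 > th[1] || count2 > th[2])
    stop("events exceed the rounded thousands of progeny")
  matrix(as.integer(c(count1, th[1], count2, th[2])), nrow = 2L,
         byrow = TRUE,
         dimnames = list(location = c("1", "2"),
                         c("events", "thousands")))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact conditional test: with all margins fixed, the first cell follows a
#' hypergeometric distribution; the two-sided p-value is the sum of the
#' probabilities of every table (with the observed margins) whose point
#' probability does not exceed the observed table's, using a relative
#' tolerance of 1e-7 for ties. Probabilities are evaluated in log space so
#' large margins stay accurate.
#'
#' @param table 2x2 matrix of nonnegative integer counts, at least one
#'   positive.
#' @return a [FisherResult-class].
#' @examples
#' pValue(fisherTwoSided(perThousandTable(53, 3710000, 10, 943000)))  # 0.53
#' @export
fisherTwoSided <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0)) stop("table entries must be nonnegative")
  if (any(table != round(table))) stop("table entries must be integers")
  if (sum(table) == 0) stop("at least one entry must be positive")
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ]); c1 <- sum(table[, 1])
  k <- max(0L, c1 - r2):min(r1, c1)
  lp <- stats::dhyper(k, r1, r2, c1, log = TRUE)
  lobs <- stats::dhyper(table[1, 1], r1, r2, c1, log = TRUE)
  p <- min(1, sum(exp(lp[lp <= lobs + log1p(1e-7)])))
  methods::new("FisherResult", table = table, pTwoSided = p,
    method = "sum of point probabilities <= observed (rel. tol 1e-7)")
}

#' @describeIn FisherResult-class the two-sided p-value.
#' @param x a [FisherResult-class].
#' @export
setMethod("pValue", "FisherResult", function(x) x@pTwoSided)

setMethod("show", "FisherResult", function(object) {
  cat("Fisher exact test (two-sided): P =", format(object@pTwoSided, digits = 3),
      "\n")
  print(object@table)
})

#' Selection-corrected genetic map distance
#'
#' Only the ry+ half of crossover chromatids survives purine selection, so the
#' recombinant fraction is twice the recovered crossover frequency:
#' \code{cM = 100 * recoveryFactor * coCount / progeny}.
#'
#' @param coCount recovered crossovers.
#' @param progeny progeny screened (> 0).
#' @param recoveryFactor total/recovered crossover ratio (default 2).
#' @return map distance in centiMorgans.
#' @examples
#' mapUnits(6, 943000)   # 0.0012725 cM
#' @export
mapUnits <- function(coCount, progeny, recoveryFactor = 2) {
  if (any(progeny <= 0)) stop("progeny must be positive")
  if (recoveryFactor <= 0) stop("recoveryFactor must be positive")
  100 * recoveryFactor * coCount / progeny
}

#' Map units per megabase
#'
#' @param mapUnits genetic distance in centiMorgans.
#' @param intervalBp physical span of the assayed interval in bp (> 0); for
#'   intragenic screens this defaults to the span between the two selected
#'   sites (see [selectedSpanBp()]).
#' @return cM per Mb.
#' @examples
#' mapUnitsPerMb(mapUnits(6, 943000), 3974)   # 0.32
#' @export
mapUnitsPerMb <- function(mapUnits, intervalBp) {
  if (any(intervalBp <= 0)) stop("intervalBp must be positive")
  mapUnits / (intervalBp / 1e6)
}

#' Regional recombination rate from standard-map distances
#'
#' @param geneticMu genetic length of a region in map units (cM).
#' @param physicalMb physical length in Mb (> 0).
#' @return cM per Mb.
#' @examples
#' regionalRate(2.4, 1.75)   # 1.37
#' @export
regionalRate <- function(geneticMu, physicalMb) {
  if (any(physicalMb <= 0, na.rm = TRUE)) stop("physicalMb must be positive")
  geneticMu / physicalMb
}

#' Read a per-location counts table
#'
#' @param path TSV with columns \code{location}, \code{assembly_coord},
#'   \code{progeny}, \code{co}, \code{nco}.
#' @return data.frame.
#' @export
readLocationCounts <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  need <- c("location", "progeny", "co", "nco")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("counts table is missing columns: ", paste(miss, collapse = ", "))
  d
}

#' Read a regional-interval table
#'
#' @param path TSV with columns \code{label}, \code{location},
#'   \code{genetic_mu}, \code{physical_mb}. Regions without a standard-map
#'   genetic length carry \code{NA}.
#' @return data.frame with an added \code{mu_per_mb} column.
#' @export
readIntervals <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  need <- c("label", "genetic_mu", "physical_mb")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("intervals table is missing columns: ", paste(miss, collapse = ", "))
  d$mu_per_mb <- regionalRate(d$genetic_mu, d$physical_mb)
  d
}

#' Compare recombination rates across genomic locations
#'
#' For every non-baseline location and each event class (crossover,
#' noncrossover), builds the per-thousand 2x2 table against the baseline,
#' computes the two-sided Fisher exact p-value and the rate ratio. Also
#' returns per-location rates and selection-corrected map units per Mb.
#'
#' @param counts data.frame as read by [readLocationCounts()].
#' @param baseline location label of the reference row.
#' @param intervalBp physical span for per-Mb normalisation (default 3974 bp,
#'   the span between the two selected sites of the packaged map).
#' @param recoveryFactor selection recovery factor (default 2).
#' @return list with \code{rates} (per location: counts, rates, map units,
#'   cM/Mb, no-event flags) and \code{tests} (per non-baseline location and
#'   class: counts, rates, rate ratio, p-value).
#' @examples
#' counts <- readLocationCounts(system.file("extdata", "table2_counts.tsv",
#'                                          package = "ryrec"))
#' compareLocations(counts, "86E")$tests
#' @export
compareLocations <- function(counts, baseline, intervalBp = 3974,
                             recoveryFactor = 2) {
  if (anyDuplicated(counts$location))
    stop("duplicate location labels")
  if (!baseline %in% counts$location)
    stop("baseline location '", baseline, "' not found")
  mu <- mapUnits(counts$co, counts$progeny, recoveryFactor)
  rates <- data.frame(
    location = counts$location, progeny = counts$progeny,
    co = counts$co, co_rate = eventRate(counts$co, counts$progeny)$rate,
    co_no_events = counts$co == 0,
    nco = counts$nco, nco_rate = eventRate(counts$nco, counts$progeny)$rate,
    nco_no_events = counts$nco == 0,
    map_units = mu, mu_per_mb = mapUnitsPerMb(mu, intervalBp),
    stringsAsFactors = FALSE)
  b <- counts[counts$location == baseline, ]
  others <- counts[counts$location != baseline, , drop = FALSE]
  tests <- do.call(rbind, lapply(seq_len(nrow(others)), function(i) {
    o <- others[i, ]
    do.call(rbind, lapply(c("co", "nco"), function(cl) {
      tab <- perThousandTable(b[[cl]], b$progeny, o[[cl]], o$progeny)
      data.frame(location = o$location, class = toupper(cl),
                 baseline = baseline,
                 n = o[[cl]], progeny = o$progeny,
                 baseline_n = b[[cl]], baseline_progeny = b$progeny,
                 rate_ratio = (o[[cl]] / o$progeny) / (b[[cl]] / b$progeny),
                 p_value = pValue(fisherTwoSided(tab)),
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(tests))
    tests <- data.frame(location = character(), class = character(),
                        baseline = character(), n = integer(),
                        progeny = numeric(), baseline_n = integer(),
                        baseline_progeny = numeric(), rate_ratio = numeric(),
                        p_value = numeric(), stringsAsFactors = FALSE)
  list(rates = rates, tests = tests)
}
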