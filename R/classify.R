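#' @include simulate.R
NULL

## CO/NCO classification from flanking restriction-site markers, and gene
## conversion tract length estimation. The ry606N parent lacks the KpnI site
## (-3149) and keeps the AgeI site (+6998); ry609N keeps KpnI and lacks AgeI.
## A noncrossover retains its recipient's parental flank configuration; the
## unique selectable single-exchange crossover product carries both sites.

.CLASSES <- c("CO", "NCO_recipient_606N", "NCO_recipient_609N",
              "anomalous", "unclassified")

#' Classify selected recombinants from their flanking-marker states
#'
#' @param flankKpn,flankAge character vectors of \code{"present"} /
#'   \code{"absent"} (missing or \code{NA} gives \code{"unclassified"}).
#' @return character vector: \code{"CO"} (both present),
#'   \code{"NCO_recipient_606N"} (KpnI absent, AgeI present),
#'   \code{"NCO_recipient_609N"} (KpnI present, AgeI absent),
#'   \code{"anomalous"} (both absent, matching neither parental nor
#'   single-exchange configuration) or \code{"unclassified"}.
#' @examples
#' classifyRecombinant("present", "present")
#' classifyRecombinant(c("absent", "present"), c("present", "absent"))
#' @export
classifyRecombinant <- function(flankKpn, flankAge) {
  ok <- c("present", "absent")
  k <- ifelse(flankKpn %in% ok, flankKpn, NA)
  a <- ifelse(flankAge %in% ok, flankAge, NA)
  out <- rep("unclassified", length(k))
  out[k == "present" & a == "present"] <- "CO"
  out[k == "absent" & a == "present"] <- "NCO_recipient_606N"
  out[k == "present" & a == "absent"] <- "NCO_recipient_609N"
  out[k == "absent" & a == "absent"] <- "anomalous"
  out[is.na(k) | is.na(a)] <- "unclassified"
  if (any(out == "unclassified"))
    message(sum(out == "unclassified"),
            " record(s) with missing flank state left unclassified")
  out
}

# recipient allele label for an NCO classification, NA otherwise
.recipientOf <- function(classification) {
  ifelse(classification == "NCO_recipient_606N", "ry606N",
         ifelse(classification == "NCO_recipient_609N", "ry609N", NA))
}

#' Identify converted polymorphic sites in a noncrossover recombinant
#'
#' Over the sites at which the two parental alleles differ, a site is
#' converted when the observed state equals the donor's rather than the
#' recipient's. Unsequenced sites (\code{NA} or empty) are treated as
#' unobserved. A converted site separated from the rest of the tract by an
#' observed unconverted site marks the tract discontinuous; such records are
#' reported, not dropped.
#'
#' @param genotype named character vector (names are site positions as written
#'   in the map) of observed states; may cover only a subset of sites.
#' @param map a [MarkerMap-class].
#' @param recipient recipient allele label (\code{"ry606N"} or
#'   \code{"ry609N"}), known from the flank classification.
#' @return list with integer vectors \code{converted}, \code{unconverted},
#'   \code{unobserved} (ascending positions) and logicals
#'   \code{discontinuous}, \code{complete}.
#' @export
convertedSites <- function(genotype, map, recipient) {
  alleles <- colnames(map@states)
  if (!recipient %in% alleles) stop("unknown recipient '", recipient, "'")
  donor <- setdiff(setdiff(alleles, "ry_plus"), recipient)
  if (length(donor) != 1L) donor <- setdiff(alleles, recipient)[1]
  het <- map@states[, recipient] != map@states[, donor]
  pos <- map@sites$position[het]
  rSt <- map@states[het, recipient]
  dSt <- map@states[het, donor]
  obs <- genotype[as.character(pos)]
  obs[!is.na(obs) & obs == ""] <- NA
  unobserved <- pos[is.na(obs)]
  conv <- !is.na(obs) & obs == dSt
  unconv <- !is.na(obs) & obs == rSt
  bad <- !is.na(obs) & !conv & !unconv
  if (any(bad))
    stop("observed state matches neither parent at site(s): ",
         paste(pos[bad], collapse = ", "))
  converted <- pos[conv]
  unconverted <- pos[unconv]
  disc <- length(converted) >= 1L &&
    any(unconverted > min(converted) & unconverted < max(converted))
  list(converted = as.integer(converted),
       unconverted = as.integer(unconverted),
       unobserved = as.integer(unobserved),
       discontinuous = disc,
       complete = length(unobserved) == 0L)
}

#' Minimum, midpoint and maximum conversion tract lengths
#'
#' Working in assembly coordinates, let \code{c1}/\code{c2} be the outermost
#' converted sites and \code{uL}/\code{uR} the nearest observed unconverted
#' informative sites outside them (the flanking restriction-site markers count
#' as informative sites). Then \code{min = c2 - c1} (0 for a single converted
#' site), \code{mid = (c2 + uR)/2 - (c1 + uL)/2} (the midpoint between
#' converted sites and the nearest unconverted sites, possibly half-integral)
#' and \code{max = uR - uL - 1} (the largest tract fitting strictly between
#' the bounding unconverted sites). When no unconverted site exists on a side
#' the map boundary substitutes and that side is flagged censored.
#'
#' @param converted integer vector of converted positions (locus coordinates),
#'   non-empty; must be informative sites of the recipient/donor pair.
#' @param map a [MarkerMap-class].
#' @param recipient recipient allele label.
#' @param observed optional integer vector of positions actually genotyped;
#'   defaults to every informative site. Bounds use the nearest observed
#'   unconverted site, and the estimate is marked incomplete when sites were
#'   unobserved.
#' @return a [TractEstimate-class].
#' @examples
#' map <- loadMarkerMap(system.file("extdata", "table1_marker_map.tsv",
#'                                  package = "ryrec"))
#' tractLengths(c(3506, 3511, 3610), map, "ry609N")  # min 104, mid 240.5, max 376
#' @export
tractLengths <- function(converted, map, recipient, observed = NULL) {
  if (length(converted) == 0L) stop("converted must be non-empty")
  alleles <- colnames(map@states)
  donor <- setdiff(setdiff(alleles, "ry_plus"), recipient)
  if (length(donor) != 1L) donor <- setdiff(alleles, recipient)[1]
  het <- map@sites$position[map@states[, recipient] != map@states[, donor]]
  if (!all(converted %in% het))
    stop("converted position(s) not informative on the map: ",
         paste(setdiff(converted, het), collapse = ", "))
  if (is.null(observed)) observed <- het
  complete <- all(het %in% union(observed, converted))
  asm <- function(p) coteToAssembly(p, map@anchor)
  convAsm <- sort(asm(converted))
  c1 <- convAsm[1]; c2 <- convAsm[length(convAsm)]
  candidates <- asm(setdiff(intersect(het, observed), converted))
  spanAsm <- range(asm(map@sites$position))
  lc <- !any(candidates < c1)
  rc <- !any(candidates > c2)
  uL <- if (lc) spanAsm[1] else max(candidates[candidates < c1])
  uR <- if (rc) spanAsm[2] else min(candidates[candidates > c2])
  minBp <- c2 - c1
  midBp <- (c2 + uR) / 2 - (c1 + uL) / 2
  maxBp <- uR - uL - 1
  disc <- any(candidates > c1 & candidates < c2)
  methods::new("TractEstimate",
    minBp = as.numeric(minBp), midBp = as.numeric(midBp),
    maxBp = as.numeric(max(maxBp, midBp)),
    converted = as.integer(sort(converted)),
    leftBound = assemblyToCote(uL, map@anchor),
    rightBound = assemblyToCote(uR, map@anchor),
    leftCensored = lc, rightCensored = rc,
    discontinuous = disc, complete = complete)
}

#' @rdname TractEstimate-accessors
#' @name TractEstimate-accessors
#' @param x a [TractEstimate-class].
NULL

#' @describeIn TractEstimate-accessors minimum tract length (bp).
#' @export
setMethod("minBp", "TractEstimate", function(x) x@minBp)

#' @describeIn TractEstimate-accessors midpoint tract length estimate (bp).
#' @export
setMethod("midBp", "TractEstimate", function(x) x@midBp)

#' @describeIn TractEstimate-accessors maximum tract length (bp).
#' @export
setMethod("maxBp", "TractEstimate", function(x) x@maxBp)

setMethod("show", "TractEstimate", function(object) {
  cat(sprintf("TractEstimate: min %g / mid %g / max %g bp\n",
              object@minBp, object@midBp, object@maxBp))
  cat("  converted:", paste(object@converted, collapse = ", "), "\n")
  cat(sprintf("  bounds: %d .. %d%s%s%s%s\n", object@leftBound,
              object@rightBound,
              if (object@leftCensored) " [left-censored]" else "",
              if (object@rightCensored) " [right-censored]" else "",
              if (object@discontinuous) " [discontinuous]" else "",
              if (!object@complete) " [incomplete genotyping]" else ""))
})

#' Mean and standard error of tract length estimates
#'
#' @param estimates list of [TractEstimate-class] objects, or a numeric vector
#'   of lengths.
#' @param which which estimate to summarise: \code{"mid"} (default),
#'   \code{"min"} or \code{"max"}; ignored for numeric input.
#' @return list with \code{mean} (bp), \code{sem} (sample standard deviation /
#'   sqrt(n); \code{NA} for n = 1) and \code{n}.
#' @examples
#' summarizeTracts(c(100, 200, 300))
#' @export
summarizeTracts <- function(estimates, which = c("mid", "min", "max")) {
  which <- match.arg(which)
  v <- if (is.numeric(estimates)) estimates else {
    getter <- switch(which, mid = midBp, min = minBp, max = maxBp)
    vapply(estimates, getter, numeric(1))
  }
  if (length(v) == 0L) stop("no tract estimates to summarise")
  list(mean = mean(v),
       sem = if (length(v) == 1L) NA_real_ else
         stats::sd(v) / sqrt(length(v)),
       n = length(v))
}

#' Classify and measure every record of a recombinant table
#'
#' Applies [classifyRecombinant()] to each record, then, for noncrossovers,
#' [convertedSites()] and [tractLengths()]. Every input row appears exactly
#' once in the output; anomalous and unclassified records are retained with
#' missing tract fields.
#'
#' @param records data.frame in the layout written by [writeRecords()]
#'   (columns \code{id}, \code{location}, \code{flank_kpn}, \code{flank_age}
#'   and one column per marker position; further columns are ignored).
#' @param map a [MarkerMap-class].
#' @return data.frame with one row per record: \code{id}, \code{location},
#'   \code{classification}, \code{recipient}, \code{n_converted},
#'   \code{converted} (comma-separated positions), \code{tract_min_bp},
#'   \code{tract_mid_bp}, \code{tract_max_bp}, \code{left_bound},
#'   \code{right_bound}, \code{censored}, \code{discontinuous},
#'   \code{complete}.
#' @export
analyzeRecords <- function(records, map) {
  need <- c("id", "location", "flank_kpn", "flank_age")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records table is missing columns: ", paste(miss, collapse = ", "))
  sitesAvail <- intersect(as.character(map@sites$position), names(records))
  n <- nrow(records)
  cls <- if (n) suppressMessages(
    classifyRecombinant(records$flank_kpn, records$flank_age)) else character()
  out <- data.frame(
    id = records$id, location = records$location, classification = cls,
    recipient = .recipientOf(cls), n_converted = rep(NA_integer_, n),
    converted = rep(NA_character_, n), tract_min_bp = rep(NA_real_, n),
    tract_mid_bp = rep(NA_real_, n), tract_max_bp = rep(NA_real_, n),
    left_bound = rep(NA_integer_, n), right_bound = rep(NA_integer_, n),
    censored = rep(NA, n), discontinuous = rep(NA, n),
    complete = rep(NA, n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (is.na(out$recipient[i])) next
    g <- unlist(records[i, sitesAvail, drop = FALSE])
    cs <- convertedSites(g, map, out$recipient[i])
    out$n_converted[i] <- length(cs$converted)
    if (length(cs$converted) == 0L) next
    te <- tractLengths(cs$converted, map, out$recipient[i],
                       observed = setdiff(map@sites$position,
                                          cs$unobserved))
    out$converted[i] <- paste(cs$converted, collapse = ",")
    out$tract_min_bp[i] <- te@minBp
    out$tract_mid_bp[i] <- te@midBp
    out$tract_max_bp[i] <- te@maxBp
    out$left_bound[i] <- te@leftBound
    out$right_bound[i] <- te@rightBound
    out$censored[i] <- te@leftCensored || te@rightCensored
    out$discontinuous[i] <- cs$discontinuous
    out$complete[i] <- cs$complete
  }
  out
}

#' Per-location summary of an analyzed recombinant table
#'
#' Aggregates the output of [analyzeRecords()] into one row per genomic
#' location: progeny screened, crossover and noncrossover counts and rates,
#' and the mean +/- SEM midpoint tract length of uncensored noncrossovers.
#'
#' @param analyzed output of [analyzeRecords()].
#' @param progeny named numeric vector of progeny screened per location.
#' @return data.frame with columns \code{location}, \code{progeny}, \code{co},
#'   \code{co_rate}, \code{nco}, \code{nco_rate}, \code{tract_mean_bp},
#'   \code{tract_sem_bp}, \code{tract_n}, \code{anomalous},
#'   \code{unclassified}.
#' @export
summarizeByLocation <- function(analyzed, progeny) {
  locs <- unique(analyzed$location)
  rows <- lapply(locs, function(loc) {
    a <- analyzed[analyzed$location == loc, , drop = FALSE]
    p <- unname(progeny[loc])
    if (is.null(p) || is.na(p)) stop("no progeny total for location ", loc)
    nco <- a[grepl("^NCO", a$classification), , drop = FALSE]
    usable <- nco[!is.na(nco$tract_mid_bp) & !nco$censored, , drop = FALSE]
    ts <- if (nrow(usable)) summarizeTracts(usable$tract_mid_bp) else
      list(mean = NA_real_, sem = NA_real_, n = 0L)
    data.frame(location = loc, progeny = p,
               co = sum(a$classification == "CO"),
               co_rate = sum(a$classification == "CO") / p,
               nco = nrow(nco), nco_rate = nrow(nco) / p,
               tract_mean_bp = ts$mean, tract_sem_bp = ts$sem,
               tract_n = ts$n,
               anomalous = sum(a$classification == "anomalous"),
               unclassified = sum(a$classification == "unclassified"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
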