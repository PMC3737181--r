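#' @include markerMap.R
NULL

## Forward simulator of meioses in heteroallelic females. Each transmitted
## chromatid independently carries a recombination event with probability
## eventRate; the initiation (DSB) site is uniform on a window, the conversion
## tract extends left and right of it by independent geometric lengths (mean
## meanTractBp/2 each), the event resolves as CO with probability pCO, and a
## CO transmits one of its two reciprocal products uniformly. Purine selection
## keeps only gametes that are wild type at both selected positions.

#' Construct a simulation configuration
#'
#' @param nProgeny progeny (transmitted chromatids) to screen.
#' @param eventRate per-chromatid probability of a recombination event.
#' @param pCO probability an event resolves as a crossover.
#' @param meanTractBp mean total conversion tract length in bp.
#' @param dsbWindow length-2 vector of locus coordinates; initiation sites are
#'   uniform on this interval.
#' @param locationLabel genomic location tag carried into the output.
#' @param seed integer seed governing all randomness of a run.
#' @param selectionRecovery factor relating total to recovered crossovers
#'   (2: only the ry+ half of crossover products survives selection).
#' @param bottlesPerTray,trays tray layout for the progeny-count estimation
#'   emulation; \code{trays = NA} (default) skips the emulation.
#' @return a validated [SimConfig-class].
#' @examples
#' simConfig(nProgeny = 1e5, eventRate = 6e-5, seed = 1)
#' @export
simConfig <- function(nProgeny, eventRate, pCO = 0.5, meanTractBp = 800,
                      dsbWindow = c(-3149L, 6998L), locationLabel = "sim",
                      seed = 1L, selectionRecovery = 2,
                      bottlesPerTray = 25L, trays = NA_integer_) {
  cfg <- methods::new("SimConfig",
    nProgeny = as.numeric(nProgeny), eventRate = as.numeric(eventRate),
    pCO = as.numeric(pCO), meanTractBp = as.numeric(meanTractBp),
    dsbWindow = as.integer(dsbWindow), locationLabel = locationLabel,
    seed = as.integer(seed), selectionRecovery = as.numeric(selectionRecovery),
    bottlesPerTray = as.integer(bottlesPerTray), trays = as.integer(trays))
  methods::validObject(cfg)
  cfg
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [simConfig()] in snake_case
#' (\code{n_progeny}, \code{event_rate}, \code{p_co}, \code{mean_tract_bp},
#' \code{dsb_window}, \code{location_label}, \code{seed},
#' \code{selection_recovery}, \code{bottles_per_tray}, \code{trays}).
#'
#' @param path path to the YAML file.
#' @return a [SimConfig-class].
#' @export
readSimConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("n_progeny", "event_rate", "p_co", "mean_tract_bp", "dsb_window",
             "location_label", "seed", "selection_recovery",
             "bottles_per_tray", "trays")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("invalid config keys: ", paste(bad, collapse = ", "))
  miss <- setdiff(c("n_progeny", "event_rate", "seed"), names(y))
  if (length(miss))
    stop("config is missing required keys: ", paste(miss, collapse = ", "))
  get <- function(key, default) if (is.null(y[[key]])) default else y[[key]]
  trays <- get("trays", NA)
  if (is.character(trays)) trays <- suppressWarnings(as.integer(trays))
  simConfig(nProgeny = y$n_progeny, eventRate = y$event_rate,
            pCO = get("p_co", 0.5), meanTractBp = get("mean_tract_bp", 800),
            dsbWindow = unlist(get("dsb_window", c(-3149, 6998))),
            locationLabel = get("location_label", "sim"),
            seed = y$seed, selectionRecovery = get("selection_recovery", 2),
            bottlesPerTray = get("bottles_per_tray", 25),
            trays = if (is.na(trays)) NA_integer_ else trays)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", format(object@nProgeny, big.mark = ","), "progeny at",
      object@locationLabel, "\n")
  cat(sprintf("  event rate %.3g, P(CO) %.3g, mean tract %g bp, window [%d, %d], seed %d\n",
              object@eventRate, object@pCO, object@meanTractBp,
              object@dsbWindow[1], object@dsbWindow[2], object@seed))
})

# draw n events as a data.frame in assembly coordinates; uses the current RNG
# stream. Geometric one-sided tails with mean meanTractBp/2 each.
.drawEvents <- function(config, map, n) {
  wl <- coteToAssembly(config@dsbWindow[1], map@anchor)
  wr <- coteToAssembly(config@dsbWindow[2], map@anchor)
  span <- range(coteToAssembly(map@sites$position, map@anchor))
  if (wl < span[1] || wr > span[2])
    stop("dsbWindow must lie within the marker-map span")
  if (n == 0L)
    return(data.frame(recipient = character(), dsbAsm = numeric(),
                      leftAsm = numeric(), rightAsm = numeric(),
                      outcome = character(), exchEnd = character(),
                      transmitted = integer(), stringsAsFactors = FALSE))
  parents <- setdiff(colnames(map@states), "ry_plus")
  if (length(parents) != 2L)
    parents <- colnames(map@states)[seq_len(2L)]
  dsb <- wl + sample.int(wr - wl + 1L, n, replace = TRUE) - 1L
  pg <- 1 / (config@meanTractBp / 2 + 1)   # geometric with mean meanTractBp/2
  left <- dsb - stats::rgeom(n, pg)
  right <- dsb + stats::rgeom(n, pg)
  recipient <- parents[sample.int(2L, n, replace = TRUE)]
  outcome <- ifelse(stats::runif(n) < config@pCO, "CO", "NCO")
  exchEnd <- ifelse(outcome == "CO",
                    c("left", "right")[sample.int(2L, n, replace = TRUE)],
                    NA_character_)
  transmitted <- ifelse(outcome == "CO", sample.int(2L, n, replace = TRUE),
                        1L)
  data.frame(recipient = recipient, dsbAsm = dsb, leftAsm = left,
             rightAsm = right, outcome = outcome, exchEnd = exchEnd,
             transmitted = transmitted, stringsAsFactors = FALSE)
}

#' Draw one recombination event
#'
#' The initiation site is uniform on the configured window; the conversion
#' tract extends left and right of it by independent geometric lengths with
#' mean \code{meanTractBp/2} each; the recipient chromatid is chosen uniformly
#' from the two parental alleles; the event resolves as crossover with
#' probability \code{pCO}, in which case the exchange sits at a uniformly
#' chosen end of the tract. Uses (and advances) the current RNG stream, so a
#' fixed \code{set.seed()} gives identical draws.
#'
#' @param config a [SimConfig-class].
#' @param map a [MarkerMap-class]; the window must lie within its span.
#' @return a [RecombinationEvent-class] (coordinates in the locus system).
#' @examples
#' map <- loadMarkerMap(system.file("extdata", "table1_marker_map.tsv",
#'                                  package = "ryrec"))
#' set.seed(1)
#' drawEvent(simConfig(1e5, 6e-5, seed = 1), map)
#' @export
drawEvent <- function(config, map) {
  e <- .drawEvents(config, map, 1L)
  exch <- if (e$outcome == "CO") {
    as.integer(assemblyToCote(
      if (e$exchEnd == "left") e$leftAsm else e$rightAsm, map@anchor))
  } else NA_integer_
  methods::new("RecombinationEvent",
    recipient = e$recipient,
    dsbPosition = assemblyToCote(e$dsbAsm, map@anchor),
    tract = c(assemblyToCote(e$leftAsm, map@anchor),
              assemblyToCote(e$rightAsm, map@anchor)),
    outcome = e$outcome, exchangePoint = exch)
}

setMethod("show", "RecombinationEvent", function(object) {
  cat(sprintf("RecombinationEvent: %s on %s, DSB at %d, tract [%d, %d]%s\n",
              object@outcome, object@recipient, object@dsbPosition,
              object@tract[1], object@tract[2],
              if (object@outcome == "CO")
                sprintf(", exchange at %d", object@exchangePoint) else ""))
})

# vectorised event application: returns a character matrix (site x event) of
# transmitted gamete states. Events are given in assembly coordinates.
# NCO: recipient with donor states substituted at sites inside the tract.
# CO: conversion on the recipient plus reciprocal exchange at a tract end;
# the transmitted product (1 = repaired recipient, 2 = donor chromatid) has
# the donor state precisely on the exchange side:
#   exchange at right end: product 1 = donor at sites >= tract left,
#                          product 2 = donor at sites <= tract right;
#   exchange at left end:  product 1 = donor at sites <= tract right,
#                          product 2 = donor at sites >= tract left.
.applyEvents <- function(events, map) {
  nS <- nrow(map@sites)
  nE <- nrow(events)
  siteAsm <- coteToAssembly(map@sites$position, map@anchor)
  parents <- unique(events$recipient)
  donorOf <- function(r) {
    two <- setdiff(colnames(map@states), "ry_plus")
    if (length(two) != 2L) two <- colnames(map@states)[seq_len(2L)]
    ifelse(r == two[1], two[2], two[1])
  }
  Rm <- map@states[, events$recipient, drop = FALSE]
  Dm <- map@states[, donorOf(events$recipient), drop = FALSE]
  siteM <- matrix(siteAsm, nS, nE)
  leftM <- matrix(events$leftAsm, nS, nE, byrow = TRUE)
  rightM <- matrix(events$rightAsm, nS, nE, byrow = TRUE)
  inTract <- siteM >= leftM & siteM <= rightM
  geLeft <- siteM >= leftM
  leRight <- siteM <= rightM
  isCO <- events$outcome == "CO"
  takeGeLeft <- isCO & ((events$exchEnd == "right" & events$transmitted == 1L) |
                        (events$exchEnd == "left" & events$transmitted == 2L))
  takeLeRight <- isCO & !takeGeLeft
  donorMask <- inTract
  donorMask[, takeGeLeft] <- geLeft[, takeGeLeft]
  donorMask[, takeLeRight] <- leRight[, takeLeRight]
  G <- Rm
  G[donorMask] <- Dm[donorMask]
  rownames(G) <- as.character(map@sites$position)
  colnames(G) <- NULL
  G
}

#' Apply a recombination event to a pair of parental haplotypes
#'
#' For a noncrossover, the transmitted gamete equals the recipient with the
#' donor's states substituted at every polymorphic site inside the conversion
#' tract (conversion is non-reciprocal: the donor itself is unchanged). For a
#' crossover, conversion of the recipient is combined with a reciprocal
#' exchange at the event's exchange point (a tract end) and one of the two
#' reciprocal products is transmitted, chosen uniformly using the current RNG
#' stream.
#'
#' @param event a [RecombinationEvent-class]. A tract reaching beyond the
#'   marker-map span is truncated to the span with a warning (states outside
#'   the mapped sites are unobservable, so the gamete is unaffected).
#' @param parents list of two [Haplotype-class] objects; one must be the
#'   event's recipient.
#' @param map the [MarkerMap-class] the haplotypes are defined on.
#' @return a [Haplotype-class] for the transmitted gamete, labelled
#'   \code{"gamete"}.
#' @export
applyEvent <- function(event, parents, map) {
  stopifnot(methods::is(event, "RecombinationEvent"), length(parents) == 2L)
  labels <- vapply(parents, function(p) p@label, character(1))
  if (!event@recipient %in% labels)
    stop("event recipient '", event@recipient, "' is not among the parents")
  span <- range(map@sites$position)
  tract <- event@tract
  la <- coteToAssembly(tract[1], map@anchor)
  ra <- coteToAssembly(tract[2], map@anchor)
  spanAsm <- coteToAssembly(span, map@anchor)
  if (la < spanAsm[1] || ra > spanAsm[2]) {
    warning("event tract extends beyond the marker-map span; truncating")
    la <- max(la, spanAsm[1]); ra <- min(ra, spanAsm[2])
  }
  transmitted <- if (event@outcome == "CO") sample.int(2L, 1L) else 1L
  ev <- data.frame(recipient = event@recipient,
                   dsbAsm = coteToAssembly(event@dsbPosition, map@anchor),
                   leftAsm = la, rightAsm = ra, outcome = event@outcome,
                   exchEnd = if (event@outcome == "CO") {
                     if (event@exchangePoint == tract[1]) "left" else "right"
                   } else NA_character_,
                   transmitted = transmitted, stringsAsFactors = FALSE)
  G <- .applyEvents(ev, map)
  st <- G[, 1L]
  methods::new("Haplotype", label = "gamete", states = st,
               positions = as.integer(map@sites$position))
}

# functional (selectable) status of gamete state columns
.functionalStates <- function(G, map, wildtype = "ry_plus") {
  sel <- which(map@sites$role == "selected")
  wt <- map@states[sel, wildtype]
  G[sel[1], ] == wt[1] & G[sel[2], ] == wt[2]
}

#' Simulate a purine-selection intragenic recombination screen
#'
#' Draws \code{nProgeny} transmitted chromatids; each independently carries a
#' recombination event with probability \code{eventRate} (non-event chromatids
#' are parental and never survive selection, so only event chromatids are
#' materialised). Selection keeps gametes that are wild type at both selected
#' positions. Each selected record carries its generating event (outcome,
#' tract, recipient) as ground truth for oracle testing.
#'
#' @param config a [SimConfig-class]; \code{config@seed} seeds the run.
#' @param map a [MarkerMap-class].
#' @return a list with elements:
#'   \describe{
#'     \item{totalProgeny}{progeny screened (\code{nProgeny}).}
#'     \item{records}{data.frame of selected gametes: \code{id},
#'       \code{location}, \code{flank_kpn}/\code{flank_age}
#'       (\code{present}/\code{absent}), one column per polymorphic site
#'       holding the observed state, \code{true_outcome},
#'       \code{true_recipient}, \code{true_tract_left},
#'       \code{true_tract_right} (locus coordinates).}
#'     \item{trueCounts}{named vector: events drawn, selected, selected CO,
#'       selected NCO.}
#'     \item{progenyEstimate}{bottle-count estimate of progeny screened (only
#'       when \code{config@trays} is set; see [estimateProgeny()]).}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' map <- loadMarkerMap(system.file("extdata", "table1_marker_map.tsv",
#'                                  package = "ryrec"))
#' sim <- simulateExperiment(simConfig(2e5, 6e-5, seed = 7), map)
#' sim$trueCounts
#' @export
simulateExperiment <- function(config, map) {
  stopifnot(methods::is(config, "SimConfig"), methods::is(map, "MarkerMap"))
  set.seed(config@seed)
  nEvents <- stats::rbinom(1L, config@nProgeny, config@eventRate)
  events <- .drawEvents(config, map, nEvents)
  if (nEvents > 0L) {
    G <- .applyEvents(events, map)
    fun <- .functionalStates(G, map)
  } else {
    G <- matrix(character(), nrow(map@sites), 0L)
    fun <- logical()
  }
  keep <- which(fun)
  flk <- map@sites$role == "flanking"
  kpnRow <- which(flk)[1]; ageRow <- which(flk)[2]
  wtK <- map@states[kpnRow, "ry_plus"]; wtA <- map@states[ageRow, "ry_plus"]
  gsel <- G[, keep, drop = FALSE]
  siteCols <- as.data.frame(t(gsel), stringsAsFactors = FALSE)
  names(siteCols) <- as.character(map@sites$position)
  records <- data.frame(
    id = sprintf("%s_%05d", config@locationLabel, seq_along(keep)),
    location = rep(config@locationLabel, length(keep)),
    flank_kpn = ifelse(gsel[kpnRow, ] == wtK, "present", "absent"),
    flank_age = ifelse(gsel[ageRow, ] == wtA, "present", "absent"),
    siteCols,
    true_outcome = events$outcome[keep],
    true_recipient = events$recipient[keep],
    true_tract_left = assemblyToCote(events$leftAsm[keep], map@anchor),
    true_tract_right = assemblyToCote(events$rightAsm[keep], map@anchor),
    check.names = FALSE, stringsAsFactors = FALSE, row.names = NULL)
  est <- NA_real_
  if (!is.na(config@trays) && config@trays >= 1L) {
    nb <- config@trays * config@bottlesPerTray
    perBottle <- stats::rmultinom(1L, config@nProgeny, rep(1 / nb, nb))[, 1L]
    untreated <- vapply(seq_len(config@trays), function(tr) {
      bottles <- (tr - 1L) * config@bottlesPerTray +
        seq_len(config@bottlesPerTray)
      perBottle[sample(bottles, 1L)]
    }, numeric(1))
    est <- estimateProgeny(round(mean(untreated)), config@bottlesPerTray,
                           config@trays, "treated_only")
  }
  list(totalProgeny = config@nProgeny,
       records = records,
       trueCounts = c(events = nEvents, selected = length(keep),
                      selected_co = sum(events$outcome[keep] == "CO"),
                      selected_nco = sum(events$outcome[keep] == "NCO")),
       progenyEstimate = est,
       config = config)
}

#' Estimate total progeny screened from untreated-bottle counts
#'
#' Screens rear progeny in trays of bottles; all bottles but one randomly
#' chosen bottle per tray are treated with purine, and the untreated bottle is
#' counted to estimate the total screened. With
#' \code{mode = "treated_only"} the estimate covers the treated bottles only
#' (\code{count * (bottlesPerTray - 1) * trays}); with \code{mode = "all"} it
#' covers every bottle (\code{count * bottlesPerTray * trays}).
#'
#' @param untreatedBottleCount progeny counted in the untreated bottle
#'   (a per-tray average when several trays are used).
#' @param bottlesPerTray bottles per tray (>= 2).
#' @param trays number of trays.
#' @param mode \code{"treated_only"} or \code{"all"}.
#' @return numeric(1) estimated progeny.
#' @examples
#' estimateProgeny(500, 25, 1)            # 12,000
#' estimateProgeny(500, 25, 1, "all")     # 12,500
#' @export
estimateProgeny <- function(untreatedBottleCount, bottlesPerTray = 25L,
                            trays = 1L, mode = c("treated_only", "all")) {
  mode <- match.arg(mode)
  if (any(untreatedBottleCount < 0) || trays < 0)
    stop("counts must be nonnegative")
  if (bottlesPerTray < 2L)
    stop("bottlesPerTray must be at least 2")
  mult <- if (mode == "treated_only") bottlesPerTray - 1L else bottlesPerTray
  untreatedBottleCount * mult * trays
}

#' Write simulated recombinant records to a tab-separated file
#'
#' Prepends a commented header line recording the package version, seed and a
#' configuration checksum so runs are audit-reproducible.
#'
#' @param sim result of [simulateExperiment()].
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
writeRecords <- function(sim, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ryrec %s\tseed=%d\tconfig=%s",
                     as.character(utils::packageVersion("ryrec")),
                     sim$config@seed, .configHash(sim$config)), con)
  utils::write.table(sim$records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a recombinant-records table
#'
#' Reads the TSV format written by [writeRecords()] (comment lines starting
#' with \code{#} are skipped). Site columns keep their literal position names.
#'
#' @param path path to the records TSV.
#' @return data.frame of records.
#' @export
readRecords <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    colClasses = "character")
}

# order-insensitive checksum of the serialised configuration (base R only)
.configHash <- function(config) {
  s <- paste(config@nProgeny, config@eventRate, config@pCO,
             config@meanTractBp, paste(config@dsbWindow, collapse = ","),
             config@locationLabel, config@seed, config@selectionRecovery,
             sep = "|")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}
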