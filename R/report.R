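#' @include rates.R
NULL

.commentHeader <- function(seed, extra = "") {
  sprintf("# ryrec %s\tseed=%s%s",
          as.character(utils::packageVersion("ryrec")),
          as.character(seed), extra)
}

.writeTsv <- function(d, path, seed = NA, extra = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.commentHeader(seed, extra), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run a simulated screen from a configuration file
#'
#' Reads a YAML configuration (see [readSimConfig()]), simulates the screen,
#' and writes the selected recombinant records as TSV plus a run-summary JSON
#' (progeny screened, counts by true outcome, seed, configuration echo).
#' Deterministic for a given configuration.
#'
#' @param configPath YAML configuration file, or a [SimConfig-class].
#' @param mapPath marker-map TSV (default: the packaged map).
#' @param outRecords,outSummary output paths.
#' @return invisibly, the [simulateExperiment()] result.
#' @export
runSimulate <- function(configPath, mapPath = NULL,
                        outRecords = "records.tsv",
                        outSummary = "summary.json") {
  cfg <- if (methods::is(configPath, "SimConfig")) configPath else
    readSimConfig(configPath)
  map <- .loadDefaultMap(mapPath)
  sim <- simulateExperiment(cfg, map)
  writeRecords(sim, outRecords)
  summary <- list(
    total_progeny = sim$totalProgeny,
    events = unname(sim$trueCounts["events"]),
    selected = unname(sim$trueCounts["selected"]),
    selected_co = unname(sim$trueCounts["selected_co"]),
    selected_nco = unname(sim$trueCounts["selected_nco"]),
    progeny_estimate = if (is.na(sim$progenyEstimate)) NULL else
      sim$progenyEstimate,
    seed = cfg@seed,
    config = list(n_progeny = cfg@nProgeny, event_rate = cfg@eventRate,
                  p_co = cfg@pCO, mean_tract_bp = cfg@meanTractBp,
                  dsb_window = cfg@dsbWindow,
                  location_label = cfg@locationLabel,
                  selection_recovery = cfg@selectionRecovery,
                  hash = .configHash(cfg)))
  jsonlite::write_json(summary, outSummary, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(sim)
}

.loadDefaultMap <- function(mapPath) {
  if (methods::is(mapPath, "MarkerMap")) return(mapPath)
  if (is.null(mapPath))
    mapPath <- system.file("extdata", "table1_marker_map.tsv",
                           package = "ryrec")
  loadMarkerMap(mapPath)
}

#' Classify a recombinant table and summarise it per location
#'
#' Runs [analyzeRecords()] on a records TSV and writes the per-record
#' classification/tract table; when progeny totals are supplied, also writes a
#' per-location summary (counts, rates, tract mean +/- SEM).
#'
#' @param recordsPath records TSV (format of [writeRecords()]), or a
#'   data.frame.
#' @param mapPath marker-map TSV or [MarkerMap-class] (default: packaged map).
#' @param outRecords output path for the per-record table.
#' @param outSummary output path for the per-location summary (only written
#'   when \code{progeny} is given).
#' @param progeny named numeric vector of progeny screened per location.
#' @param seed seed to echo into output headers.
#' @return invisibly, list with \code{records} and (possibly NULL)
#'   \code{summary} data.frames.
#' @export
runAnalyze <- function(recordsPath, mapPath = NULL,
                       outRecords = "analyzed.tsv",
                       outSummary = "location_summary.tsv",
                       progeny = NULL, seed = NA) {
  records <- if (is.data.frame(recordsPath)) recordsPath else
    readRecords(recordsPath)
  map <- .loadDefaultMap(mapPath)
  analyzed <- analyzeRecords(records, map)
  .writeTsv(analyzed, outRecords, seed)
  summary <- NULL
  if (!is.null(progeny)) {
    summary <- summarizeByLocation(analyzed, progeny)
    .writeTsv(summary, outSummary, seed)
  }
  invisible(list(records = analyzed, summary = summary))
}

#' Rate, map-unit and Fisher-exact comparison report
#'
#' From a per-location counts table and (optionally) a regional-interval
#' table, writes per-location rates with selection-corrected map units per Mb,
#' Fisher exact comparisons of each location against a baseline, and regional
#' cM/Mb values, and prints a human-readable summary.
#'
#' @param countsPath counts TSV (see [readLocationCounts()]) or data.frame;
#'   NULL to report regional intervals only.
#' @param intervalsPath intervals TSV (see [readIntervals()]) or data.frame;
#'   NULL to skip.
#' @param baseline baseline location label (required with counts).
#' @param outDir output directory for \code{rates.tsv}, \code{tests.tsv},
#'   \code{regional.tsv}.
#' @param intervalBp physical span for per-Mb normalisation.
#' @param quiet suppress the printed table.
#' @return invisibly, list with \code{rates}, \code{tests}, \code{regional}.
#' @export
runRates <- function(countsPath = NULL, intervalsPath = NULL, baseline = NULL,
                     outDir = ".", intervalBp = 3974, quiet = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rates <- tests <- regional <- NULL
  if (!is.null(countsPath)) {
    counts <- if (is.data.frame(countsPath)) countsPath else
      readLocationCounts(countsPath)
    if (is.null(baseline)) stop("a baseline location is required")
    cmp <- compareLocations(counts, baseline, intervalBp)
    rates <- cmp$rates; tests <- cmp$tests
    .writeTsv(rates, file.path(outDir, "rates.tsv"))
    .writeTsv(tests, file.path(outDir, "tests.tsv"))
  }
  if (!is.null(intervalsPath)) {
    regional <- if (is.data.frame(intervalsPath)) intervalsPath else
      readIntervals(intervalsPath)
    .writeTsv(regional, file.path(outDir, "regional.tsv"))
  }
  if (!quiet) {
    if (!is.null(rates)) {
      cat("Per-location rates (recovery-corrected map units over",
          intervalBp, "bp):\n")
      print(rates, digits = 3)
      cat("\nFisher exact comparisons vs", baseline,
          "(events per 1000 progeny):\n")
      print(tests, digits = 3)
    }
    if (!is.null(regional)) {
      cat("\nRegional standard-map rates:\n")
      print(regional, digits = 3)
    }
  }
  invisible(list(rates = rates, tests = tests, regional = regional))
}
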