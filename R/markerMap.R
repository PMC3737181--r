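#' @include AllGenerics.R
NULL

# default assembly coordinate of locus position +1 (3R, release 5.44)
.RY_ANCHOR <- 8859890
.RY_CHROM <- "3R"

#' Convert locus coordinates to assembly coordinates
#'
#' The locus coordinate system has no position zero: +1 is the first base of
#' the anchoring EcoRI site and -1 the base immediately upstream. Positive
#' positions map to \code{anchor + position - 1}, negative positions to
#' \code{anchor + position}, so -1 and +1 are adjacent assembly bases.
#'
#' @param position integer vector of nonzero signed locus coordinates.
#' @param anchor assembly coordinate of position +1
#'   (default 8,859,890, 3R release 5.44).
#' @return numeric vector of 1-based assembly coordinates.
#' @examples
#' coteToAssembly(c(1, -1, 3506))
#' @export
coteToAssembly <- function(position, anchor = .RY_ANCHOR) {
  if (any(position == 0, na.rm = TRUE))
    stop("position 0 does not exist in the locus coordinate system")
  ifelse(position > 0, anchor + position - 1, anchor + position)
}

#' Convert assembly coordinates back to locus coordinates
#'
#' Inverse of [coteToAssembly()].
#'
#' @param coord numeric vector of 1-based assembly coordinates.
#' @inheritParams coteToAssembly
#' @return integer vector of signed locus coordinates (never zero).
#' @export
assemblyToCote <- function(coord, anchor = .RY_ANCHOR) {
  as.integer(ifelse(coord >= anchor, coord - anchor + 1, coord - anchor))
}

#' Read a transgene marker map from a tab-separated file
#'
#' The file must carry a header line with columns \code{position} (signed
#' integer, no zero), one state column per allele (by default \code{ry_plus},
#' \code{ry606N}, \code{ry609N}; \code{"-"} denotes a deletion), \code{role}
#' (\code{selected}, \code{flanking} or \code{silent}) and \code{note}.
#' Rows are sorted by position regardless of file order.
#'
#' @param path path to the TSV file.
#' @param alleles character vector of allele column names expected in the file.
#' @param anchor assembly coordinate of locus position +1.
#' @param chrom assembly sequence name.
#' @return a validated [MarkerMap-class].
#' @examples
#' map <- loadMarkerMap(system.file("extdata", "table1_marker_map.tsv",
#'                                  package = "ryrec"))
#' map
#' @export
loadMarkerMap <- function(path,
                          alleles = c("ry_plus", "ry606N", "ry609N"),
                          anchor = .RY_ANCHOR, chrom = .RY_CHROM) {
  d <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                         colClasses = "character")
  if (nrow(d) == 0L) stop("no sites in marker map file '", path, "'")
  need <- c("position", alleles, "role", "note")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("marker map file is missing columns: ", paste(miss, collapse = ", "))
  pos <- suppressWarnings(as.integer(gsub("^\\+", "", d$position)))
  if (any(is.na(pos)))
    stop("non-integer position in row(s): ",
         paste(which(is.na(pos)), collapse = ", "))
  if (any(pos == 0L))
    stop("position 0 (row ", paste(which(pos == 0L), collapse = ", "),
         ") does not exist in the locus coordinate system")
  dup <- unique(pos[duplicated(pos)])
  if (length(dup))
    stop("duplicate position: ", paste(dup, collapse = ", "))
  o <- order(pos)
  st <- as.matrix(d[o, alleles, drop = FALSE])
  rownames(st) <- NULL
  map <- methods::new("MarkerMap",
    sites = data.frame(position = pos[o], role = d$role[o], note = d$note[o],
                       stringsAsFactors = FALSE),
    states = st, anchor = anchor, chrom = chrom)
  methods::validObject(map)
  map
}

#' Write a marker map to a tab-separated file
#'
#' Produces a file that [loadMarkerMap()] reads back into an identical map.
#'
#' @param map a [MarkerMap-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeMarkerMap <- function(map, path) {
  d <- data.frame(position = map@sites$position, map@states,
                  role = map@sites$role, note = map@sites$note,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn MarkerMap-accessors signed locus positions, ascending.
#' @export
setMethod("sitePositions", "MarkerMap", function(x) x@sites$position)

#' Accessors for MarkerMap components
#'
#' @param x a [MarkerMap-class].
#' @name MarkerMap-accessors
NULL

#' @describeIn MarkerMap-accessors site roles.
#' @export
setMethod("siteRoles", "MarkerMap", function(x) x@sites$role)

#' @describeIn MarkerMap-accessors free-text site annotations.
#' @export
setMethod("siteNotes", "MarkerMap", function(x) x@sites$note)

#' @describeIn MarkerMap-accessors allele labels.
#' @export
setMethod("alleleNames", "MarkerMap", function(x) colnames(x@states))

#' @describeIn MarkerMap-accessors character matrix of states (site x allele).
#' @export
setMethod("stateMatrix", "MarkerMap", function(x) {
  st <- x@states
  rownames(st) <- as.character(x@sites$position)
  st
})

#' @describeIn MarkerMap-accessors assembly coordinate of position +1.
#' @export
setMethod("assemblyAnchor", "MarkerMap", function(x) x@anchor)

#' @describeIn MarkerMap-accessors positions of the two selected sites.
#' @export
setMethod("selectedPositions", "MarkerMap",
          function(x) x@sites$position[x@sites$role == "selected"])

#' @describeIn MarkerMap-accessors positions of the two flanking sites.
#' @export
setMethod("flankingPositions", "MarkerMap",
          function(x) x@sites$position[x@sites$role == "flanking"])

#' @describeIn MarkerMap-accessors number of polymorphic sites.
#' @export
setMethod("length", "MarkerMap", function(x) nrow(x@sites))

setMethod("show", "MarkerMap", function(object) {
  cat("MarkerMap with", nrow(object@sites), "polymorphic sites\n")
  cat("  alleles:", paste(colnames(object@states), collapse = ", "), "\n")
  cat("  span:", object@sites$position[1], "..",
      object@sites$position[nrow(object@sites)],
      sprintf("(anchor %s:%s)", object@chrom,
              format(object@anchor, big.mark = ",")), "\n")
  cat("  selected:", paste(selectedPositions(object), collapse = ", "),
      " flanking:", paste(flankingPositions(object), collapse = ", "), "\n")
})

#' Extract one allele's haplotype from a marker map
#'
#' @param map a [MarkerMap-class].
#' @param label allele name; must be one of \code{alleleNames(map)}.
#' @return a [Haplotype-class] with one state per map site.
#' @examples
#' map <- loadMarkerMap(system.file("extdata", "table1_marker_map.tsv",
#'                                  package = "ryrec"))
#' isFunctional(haplotype(map, "ry_plus"), map)
#' @export
haplotype <- function(map, label) {
  stopifnot(methods::is(map, "MarkerMap"))
  if (!label %in% colnames(map@states))
    stop("unknown allele '", label, "'; map has: ",
         paste(colnames(map@states), collapse = ", "))
  st <- map@states[, label]
  names(st) <- as.character(map@sites$position)
  methods::new("Haplotype", label = label, states = st,
               positions = as.integer(map@sites$position))
}

setMethod("show", "Haplotype", function(object) {
  cat("Haplotype", object@label, "over", length(object@states), "sites\n")
})

#' @rdname heterologies
#' @export
setMethod("heterologies", signature("Haplotype", "Haplotype", "MarkerMap"),
  function(h1, h2, map) {
    if (!identical(h1@positions, h2@positions) ||
        !identical(h1@positions, as.integer(map@sites$position)))
      stop("haplotypes are not defined on the same marker map")
    diffs <- h1@states != h2@states
    out <- data.frame(position = map@sites$position[diffs],
                      role = map@sites$role[diffs],
                      note = map@sites$note[diffs],
                      stringsAsFactors = FALSE)
    out[[h1@label]] <- unname(h1@states[diffs])
    out[[h2@label]] <- unname(h2@states[diffs])
    out
  })

#' Positions at which two alleles of a map differ
#'
#' Convenience wrapper around [heterologies()] taking allele labels.
#'
#' @param map a [MarkerMap-class].
#' @param a1,a2 allele labels.
#' @return integer vector of positions, ascending.
#' @export
heterologyPositions <- function(map, a1, a2) {
  heterologies(haplotype(map, a1), haplotype(map, a2), map)$position
}

#' @rdname isFunctional
#' @export
setMethod("isFunctional", signature("Haplotype", "MarkerMap"),
  function(h, map, wildtype = "ry_plus") {
    if (!identical(h@positions, as.integer(map@sites$position)))
      stop("haplotype is not defined on this marker map")
    sel <- map@sites$role == "selected"
    if (sum(sel) != 2L) stop("map must contain both selected sites")
    wt <- map@states[sel, wildtype]
    all(unname(h@states[sel]) == wt)
  })

# inclusive physical span (bp) between the two selected sites, in assembly
# coordinates; the default normalisation interval for map units per Mb
.selectedSpanBp <- function(map) {
  sel <- coteToAssembly(selectedPositions(map), map@anchor)
  diff(range(sel)) + 1
}

#' Physical span between the selected sites of a map
#'
#' Inclusive base-pair distance between the two selected (mutant) positions in
#' assembly coordinates; used as the default physical interval when
#' normalising intragenic map units per megabase.
#'
#' @param map a [MarkerMap-class].
#' @return numeric(1), span in bp (3974 on the packaged map).
#' @export
selectedSpanBp <- function(map) .selectedSpanBp(map)
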