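#' @include AllClasses.R
NULL

#' @rdname MarkerMap-accessors
#' @export
setGeneric("sitePositions", function(x) standardGeneric("sitePositions"))

#' @rdname MarkerMap-accessors
#' @export
setGeneric("siteRoles", function(x) standardGeneric("siteRoles"))

#' @rdname MarkerMap-accessors
#' @export
setGeneric("siteNotes", function(x) standardGeneric("siteNotes"))

#' @rdname MarkerMap-accessors
#' @export
setGeneric("alleleNames", function(x) standardGeneric("alleleNames"))

#' @rdname MarkerMap-accessors
#' @export
setGeneric("stateMatrix", function(x) standardGeneric("stateMatrix"))

#' @rdname MarkerMap-accessors
#' @export
setGeneric("assemblyAnchor", function(x) standardGeneric("assemblyAnchor"))

#' @rdname MarkerMap-accessors
#' @export
setGeneric("selectedPositions", function(x) standardGeneric("selectedPositions"))

#' @rdname MarkerMap-accessors
#' @export
setGeneric("flankingPositions", function(x) standardGeneric("flankingPositions"))

#' Compare two haplotypes over a marker map
#'
#' @param h1,h2 [Haplotype-class] objects defined on \code{map}.
#' @param map a [MarkerMap-class].
#' @return data.frame of the sites at which the two haplotypes differ
#'   (ascending position), with columns \code{position}, \code{role},
#'   \code{note} and one state column per haplotype.
#' @export
setGeneric("heterologies", function(h1, h2, map) standardGeneric("heterologies"))

#' Selectability predicate: does a haplotype restore wild-type function?
#'
#' A gamete survives purine selection if and only if it carries the wild-type
#' state at both selected (mutant) positions.
#'
#' @param h a [Haplotype-class].
#' @param map a [MarkerMap-class] containing both selected sites.
#' @param wildtype allele label whose states define "wild type"
#'   (default \code{"ry_plus"}).
#' @return logical(1).
#' @export
setGeneric("isFunctional", function(h, map, wildtype = "ry_plus")
  standardGeneric("isFunctional"))

#' @rdname TractEstimate-accessors
#' @export
setGeneric("minBp", function(x) standardGeneric("minBp"))

#' @rdname TractEstimate-accessors
#' @export
setGeneric("midBp", function(x) standardGeneric("midBp"))

#' @rdname TractEstimate-accessors
#' @export
setGeneric("maxBp", function(x) standardGeneric("maxBp"))

#' @rdname FisherResult-class
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
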