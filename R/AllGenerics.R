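#' @include isletMC-package.R
NULL

#' Accessor generics for islet study objects
#'
#' Accessors for the cell table, islet table, per-islet count table,
#' analysis parameters, provenance record and boundary polygons of an
#' \linkS4class{IsletStudy}, and for the components of histogram and
#' earth-mover's-distance result objects.
#'
#' @param x an object.
#' @param ... further arguments passed to methods.
#' @return See the method documentation on \linkS4class{IsletStudy},
#'   \linkS4class{Histogram1D}, \linkS4class{Histogram2D} and
#'   \linkS4class{EMDResult}.
#' @name isletMC-generics
NULL

#' @rdname isletMC-generics
#' @export
setGeneric("cells", function(x, ...) standardGeneric("cells"))

#' @rdname isletMC-generics
#' @export
setGeneric("islets", function(x, ...) standardGeneric("islets"))

#' @rdname isletMC-generics
#' @export
setGeneric("isletCounts", function(x, ...) standardGeneric("isletCounts"))

#' @rdname isletMC-generics
#' @export
setGeneric("analysisParams", function(x, ...) standardGeneric("analysisParams"))

#' @rdname isletMC-generics
#' @export
setGeneric("analysisParams<-", function(x, value) standardGeneric("analysisParams<-"))

#' @rdname isletMC-generics
#' @export
setGeneric("provenance", function(x, ...) standardGeneric("provenance"))

#' @rdname isletMC-generics
#' @export
setGeneric("isletBoundary", function(x, id, ...) standardGeneric("isletBoundary"))

#' @rdname isletMC-generics
#' @export
setGeneric("cellBoundary", function(x, id, ...) standardGeneric("cellBoundary"))

#' @rdname isletMC-generics
#' @export
setGeneric("nIslets", function(x) standardGeneric("nIslets"))

#' @rdname isletMC-generics
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname isletMC-generics
#' @export
setGeneric("binMass", function(x) standardGeneric("binMass"))

#' @rdname isletMC-generics
#' @export
setGeneric("binBreaks", function(x) standardGeneric("binBreaks"))

#' @rdname isletMC-generics
#' @export
setGeneric("emdDistance", function(x) standardGeneric("emdDistance"))

#' @rdname isletMC-generics
#' @export
setGeneric("transportPlan", function(x) standardGeneric("transportPlan"))
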