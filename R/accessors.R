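#' @include AllClasses.R
NULL

#' @describeIn IsletStudy-class the cell table.
#' @param x an \code{IsletStudy}.
#' @param ... unused.
#' @export
setMethod("cells", "IsletStudy", function(x, ...) x@cells)

#' @describeIn IsletStudy-class the islet table.
#' @export
setMethod("islets", "IsletStudy", function(x, ...) x@islets)

#' @describeIn IsletStudy-class the per-islet count table (one row per islet
#'   with columns N, NB, B, M, C, NB_m); empty until
#'   \code{\link{annotatePositions}} has run.
#' @export
setMethod("isletCounts", "IsletStudy", function(x, ...) x@counts)

#' @describeIn IsletStudy-class the analysis parameters.
#' @export
setMethod("analysisParams", "IsletStudy", function(x, ...) x@params)

#' @describeIn IsletStudy-class replace the analysis parameters.
#' @param value an \linkS4class{AnalysisParams}.
#' @export
setMethod("analysisParams<-", "IsletStudy", function(x, value) {
  stopifnot(is(value, "AnalysisParams"))
  x@params <- value
  validObject(x)
  x
})

#' @describeIn IsletStudy-class provenance list (sources, filter tallies,
#'   orphans, warnings).
#' @export
setMethod("provenance", "IsletStudy", function(x, ...) x@provenance)

#' @describeIn IsletStudy-class boundary polygon of one islet (two-column
#'   matrix, um).
#' @param id an islet or cell identifier.
#' @export
setMethod("isletBoundary", "IsletStudy", function(x, id, ...) {
  p <- x@isletBoundaries[[as.character(id)]]
  if (is.null(p)) stop("no boundary stored for islet '", id, "'")
  p
})

#' @describeIn IsletStudy-class nuclear boundary polygon of one cell.
#' @export
setMethod("cellBoundary", "IsletStudy", function(x, id, ...) {
  p <- x@cellBoundaries[[as.character(id)]]
  if (is.null(p)) stop("no nuclear boundary stored for cell '", id, "'")
  p
})

#' @describeIn IsletStudy-class number of islets.
#' @export
setMethod("nIslets", "IsletStudy", function(x) nrow(x@islets))

#' @describeIn IsletStudy-class number of cells.
#' @export
setMethod("nCells", "IsletStudy", function(x) nrow(x@cells))

setMethod("show", "IsletStudy", function(object) {
  cat("IsletStudy with", nrow(object@islets), "islets and",
      nrow(object@cells), "cells\n")
  if (nrow(object@islets)) {
    tab <- table(object@islets$disease_status)
    cat("  cohorts:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  if (nrow(object@cells)) {
    tab <- table(object@cells$hormone_class)
    cat("  hormone classes:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  ann <- nrow(object@counts) > 0
  filt <- !is.null(object@provenance$filters)
  cat("  filtered:", filt, "| positions annotated:", ann, "\n")
  cat("  params: dMin =", object@params@dMin, "um, minIsletArea =",
      object@params@minIsletArea, "um^2\n")
  invisible(NULL)
})

setMethod("show", "AnalysisParams", function(object) {
  cat("AnalysisParams: dMin =", object@dMin, "um; minIsletArea =",
      object@minIsletArea, "um^2; alpha =", object@alphaLevel,
      "; nBootstrap =", object@nBootstrap, "; seed =", object@rngSeed, "\n")
  invisible(NULL)
})

#' @describeIn Histogram1D-class bin masses.
#' @param x a histogram object.
#' @export
setMethod("binMass", "Histogram1D", function(x) x@mass)

#' @describeIn Histogram1D-class bin edges.
#' @export
setMethod("binBreaks", "Histogram1D", function(x) x@breaks)

#' @describeIn Histogram2D-class bin mass matrix (x bins in rows).
#' @param x a histogram object.
#' @export
setMethod("binMass", "Histogram2D", function(x) x@mass)

#' @describeIn Histogram2D-class list of x and y bin edges.
#' @export
setMethod("binBreaks", "Histogram2D",
          function(x) list(x = x@xBreaks, y = x@yBreaks))

setMethod("show", "Histogram1D", function(object) {
  cat("Histogram1D:", length(object@mass), "equidistant bins on [",
      min(object@breaks), ",", max(object@breaks), "],",
      object@nSamples, "samples\n")
  invisible(NULL)
})

setMethod("show", "Histogram2D", function(object) {
  cat("Histogram2D:", nrow(object@mass), "x", ncol(object@mass),
      "bins,", object@nSamples, "islets",
      if (!is.na(object@areaScale))
        paste0("(area scale ", signif(object@areaScale, 6), " um^2)"), "\n")
  invisible(NULL)
})

#' @describeIn EMDResult-class the normalized distance.
#' @param x an \code{EMDResult}.
#' @export
setMethod("emdDistance", "EMDResult", function(x) x@distance)

#' @describeIn EMDResult-class the optimal transport plan (rows = source
#'   bins, columns = target bins).
#' @export
setMethod("transportPlan", "EMDResult", function(x) x@plan)

setMethod("show", "EMDResult", function(object) {
  cat("EMDResult: distance =", format(object@distance, digits = 6),
      "(", object@normalization$label, ")\n")
  cat("  plan:", nrow(object@plan), "x", ncol(object@plan), "bins;",
      sum(object@plan > 1e-12), "non-zero entries\n")
  invisible(NULL)
})

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig:", object@nIslets, "islets, theta =", object@theta,
      ", folding =", object@folding, "\n")
  cat("  area ~ lognormal(median", object@areaMedian, "um^2, sdlog",
      object@areaSdlog, ") truncated >", object@areaMin, "um^2\n")
  cat("  density", object@cellDensity, "cells/um^2, nucleus radius",
      object@nucleusRadius, "um, none fraction", object@noneFraction, "\n")
  cat("  t1d fraction", object@t1dFraction, ", seed", object@seed, "\n")
  invisible(NULL)
})
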