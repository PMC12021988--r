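#' @include AllGenerics.R
NULL

HORMONE_CLASSES <- c("alpha", "beta", "delta", "epsilon", "gamma", "none")
NON_BETA <- c("alpha", "delta", "epsilon", "gamma")

# canonical column sets for the two tables inside an IsletStudy
CELL_COLUMNS <- c("cell_id", "islet_id", "case_id", "x", "y",
                  "hormone_class", "binary_type", "position",
                  "boundary_distance")
ISLET_COLUMNS <- c("islet_id", "case_id", "disease_status", "area_um2",
                   "centroid_x", "centroid_y")
COUNT_COLUMNS <- c("islet_id", "N", "NB", "B", "M", "C", "NB_m")

#' Analysis parameters
#'
#' Holds the study-level tuning constants: the mantle distance threshold
#' \code{dMin} (cells whose nuclear boundary lies strictly closer than this to
#' the islet boundary are mantle cells), the minimum islet cross-sectional
#' area (islets must exceed it strictly to enter the analysis), the
#' significance threshold, the bootstrap resample count and the RNG seed.
#'
#' @slot dMin numeric(1), mantle threshold in micrometres; default 8.
#' @slot minIsletArea numeric(1), minimum islet area in square micrometres;
#'   default 1000 (strict: islets of exactly this area are removed).
#' @slot alphaLevel numeric(1), significance threshold; default 0.001.
#' @slot nBootstrap integer(1), bootstrap resample count; default 500.
#' @slot rngSeed integer(1), master seed for stochastic steps.
#'
#' @examples
#' AnalysisParams(dMin = 8)
#' @export
setClass("AnalysisParams",
  slots = c(dMin = "numeric", minIsletArea = "numeric",
            alphaLevel = "numeric", nBootstrap = "integer",
            rngSeed = "integer"),
  prototype = list(dMin = 8, minIsletArea = 1000, alphaLevel = 0.001,
                   nBootstrap = 500L, rngSeed = 1L))

setValidity("AnalysisParams", function(object) {
  msg <- character()
  if (length(object@dMin) != 1 || !is.finite(object@dMin) || object@dMin <= 0)
    msg <- c(msg, "dMin must be a single positive number")
  if (length(object@minIsletArea) != 1 || object@minIsletArea <= 0)
    msg <- c(msg, "minIsletArea must be a single positive number")
  if (length(object@alphaLevel) != 1 || object@alphaLevel <= 0 ||
      object@alphaLevel >= 1)
    msg <- c(msg, "alphaLevel must lie strictly between 0 and 1")
  if (length(object@nBootstrap) != 1 || object@nBootstrap < 1)
    msg <- c(msg, "nBootstrap must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' @param dMin,minIsletArea,alphaLevel,nBootstrap,rngSeed see slot
#'   descriptions.
#' @return \code{AnalysisParams()} returns an \code{AnalysisParams} object.
#' @rdname AnalysisParams-class
#' @export
AnalysisParams <- function(dMin = 8, minIsletArea = 1000, alphaLevel = 0.001,
                           nBootstrap = 500L, rngSeed = 1L) {
  new("AnalysisParams", dMin = as.numeric(dMin),
      minIsletArea = as.numeric(minIsletArea),
      alphaLevel = as.numeric(alphaLevel),
      nBootstrap = as.integer(nBootstrap), rngSeed = as.integer(rngSeed))
}

#' IsletStudy: a cohort of detected islets and their cells
#'
#' The central container of the package. It wraps two tables mirroring the
#' detection exports of whole-slide image analysis -- one row per islet
#' (boundary polygon, area, donor, disease status) and one row per detected
#' endocrine cell (nuclear centroid and boundary, hormone class, and, after
#' annotation, binary type, mantle/core position and boundary distance) --
#' together with the boundary polygons, the per-islet count table, the
#' analysis parameters and a provenance record of every filter decision.
#'
#' All coordinates are in micrometres. Boundary polygons are two-column
#' matrices of vertices with the first vertex not repeated.
#'
#' @slot cells data.frame with columns \code{cell_id}, \code{islet_id},
#'   \code{case_id}, \code{x}, \code{y}, \code{hormone_class},
#'   \code{binary_type}, \code{position}, \code{boundary_distance}.
#' @slot islets data.frame with columns \code{islet_id}, \code{case_id},
#'   \code{disease_status}, \code{area_um2}, \code{centroid_x},
#'   \code{centroid_y}.
#' @slot cellBoundaries named list of nuclear boundary polygons keyed by
#'   \code{cell_id}.
#' @slot isletBoundaries named list of islet boundary polygons keyed by
#'   \code{islet_id}.
#' @slot counts data.frame of per-islet counts (columns \code{islet_id},
#'   \code{N}, \code{NB}, \code{B}, \code{M}, \code{C}, \code{NB_m}); filled
#'   by \code{\link{annotatePositions}}.
#' @slot params an \linkS4class{AnalysisParams}.
#' @slot provenance list recording sources, filter tallies, orphan cells and
#'   warnings.
#'
#' @seealso \code{\link{readTabular}}, \code{\link{readQuPathGeoJSON}},
#'   \code{\link{generateCohort}}, \code{\link{applyStudyFilters}},
#'   \code{\link{annotatePositions}}
#' @export
setClass("IsletStudy",
  slots = c(cells = "data.frame", islets = "data.frame",
            cellBoundaries = "list", isletBoundaries = "list",
            counts = "data.frame", params = "AnalysisParams",
            provenance = "list"))

setValidity("IsletStudy", function(object) {
  msg <- character()
  if (!all(CELL_COLUMNS %in% names(object@cells)))
    msg <- c(msg, paste("cells table must have columns:",
                        paste(CELL_COLUMNS, collapse = ", ")))
  if (!all(ISLET_COLUMNS %in% names(object@islets)))
    msg <- c(msg, paste("islets table must have columns:",
                        paste(ISLET_COLUMNS, collapse = ", ")))
  if (anyDuplicated(object@islets$islet_id))
    msg <- c(msg, "islet_id values must be unique")
  if (nrow(object@cells) && anyDuplicated(object@cells$cell_id))
    msg <- c(msg, "cell_id values must be unique")
  if (nrow(object@cells) &&
      !all(object@cells$islet_id %in% object@islets$islet_id))
    msg <- c(msg, "every cell's islet_id must resolve to an islet")
  if (nrow(object@islets) &&
      !all(object@islets$islet_id %in% names(object@isletBoundaries)))
    msg <- c(msg, "every islet must have a boundary polygon")
  bad <- !object@cells$hormone_class %in% HORMONE_CLASSES
  if (any(bad))
    msg <- c(msg, paste("unknown hormone_class:",
                        paste(unique(object@cells$hormone_class[bad]),
                              collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @rdname IsletStudy-class
#' @param cells,islets,cellBoundaries,isletBoundaries,counts,params,provenance
#'   see slot descriptions.
#' @return \code{IsletStudy()} returns an \code{IsletStudy} object.
#' @export
IsletStudy <- function(cells, islets, cellBoundaries = list(),
                       isletBoundaries = list(),
                       counts = emptyCountTable(),
                       params = AnalysisParams(), provenance = list()) {
  rownames(cells) <- NULL
  rownames(islets) <- NULL
  new("IsletStudy", cells = cells, islets = islets,
      cellBoundaries = cellBoundaries, isletBoundaries = isletBoundaries,
      counts = counts, params = params, provenance = provenance)
}

emptyCountTable <- function() {
  data.frame(islet_id = character(), N = integer(), NB = integer(),
             B = integer(), M = integer(), C = integer(), NB_m = integer(),
             stringsAsFactors = FALSE)
}

#' Binned one-dimensional distribution on the unit interval
#'
#' Equidistant bins on [0, 1]; the last bin is closed on the right so a
#' value of exactly 1 (an islet with a fully random-compatible arrangement,
#' r = 1) is counted.
#'
#' @slot breaks numeric vector of K + 1 ascending, equidistant bin edges.
#' @slot mass numeric vector of K non-negative bin masses summing to 1.
#' @slot nSamples integer, number of raw values binned.
#' @seealso \code{\link{histogram1D}}, \code{\link{emd1D}}
#' @export
setClass("Histogram1D",
  slots = c(breaks = "numeric", mass = "numeric", nSamples = "integer"))

setValidity("Histogram1D", function(object) {
  msg <- character()
  k <- length(object@mass)
  if (length(object@breaks) != k + 1)
    msg <- c(msg, "breaks must have length(mass) + 1 entries")
  d <- diff(object@breaks)
  if (any(d <= 0) || (k > 1 && diff(range(d)) > 1e-9 * mean(d)))
    msg <- c(msg, "breaks must be ascending and equidistant")
  if (any(object@mass < 0) || abs(sum(object@mass) - 1) > 1e-12)
    msg <- c(msg, "mass must be non-negative and sum to 1")
  if (length(msg)) msg else TRUE
})

#' Binned two-dimensional distribution
#'
#' Joint distribution of islets over (beta cell fraction, normalized area),
#' both axes rescaled to [0, 1] with equidistant bins per axis.
#'
#' @slot xBreaks,yBreaks ascending equidistant bin edges per axis.
#' @slot mass non-negative matrix (x bins in rows) summing to 1.
#' @slot nSamples integer, number of islets binned.
#' @slot areaScale numeric(1), the pooled maximum area (um^2) used to map the
#'   area axis onto [0, 1]; NA when the axis is already normalized.
#' @seealso \code{\link{cohortHistograms}}, \code{\link{emd2D}}
#' @export
setClass("Histogram2D",
  slots = c(xBreaks = "numeric", yBreaks = "numeric", mass = "matrix",
            nSamples = "integer", areaScale = "numeric"))

setValidity("Histogram2D", function(object) {
  msg <- character()
  if (nrow(object@mass) != length(object@xBreaks) - 1 ||
      ncol(object@mass) != length(object@yBreaks) - 1)
    msg <- c(msg, "mass dimensions must match bin edges")
  for (br in list(object@xBreaks, object@yBreaks)) {
    d <- diff(br)
    if (any(d <= 0) || (length(d) > 1 && diff(range(d)) > 1e-9 * mean(d)))
      msg <- c(msg, "bin edges must be ascending and equidistant")
  }
  if (any(object@mass < 0) || abs(sum(object@mass) - 1) > 1e-12)
    msg <- c(msg, "mass must be non-negative and sum to 1")
  if (length(msg)) msg else TRUE
})

#' Earth mover's distance result
#'
#' The normalized optimal-transport distance between two binned
#' distributions together with the transport plan realizing it. Plan rows
#' index source bins, columns target bins; row sums equal the source mass
#' and column sums the target mass. The \code{normalization} record states
#' the ground metric and scale so the distance can be recomputed as
#' \code{sum(plan * cost)}.
#'
#' @slot distance numeric(1), the normalized EMD.
#' @slot plan non-negative matrix, the optimal transport plan.
#' @slot cost matrix of normalized ground distances between bin centers.
#' @slot sourceMass,targetMass the histogram masses compared.
#' @slot normalization list describing the ground metric and its scale.
#' @seealso \code{\link{emd1D}}, \code{\link{emd2D}}
#' @export
setClass("EMDResult",
  slots = c(distance = "numeric", plan = "matrix", cost = "matrix",
            sourceMass = "numeric", targetMass = "numeric",
            normalization = "list"))

setValidity("EMDResult", function(object) {
  msg <- character()
  if (any(object@plan < -1e-12))
    msg <- c(msg, "plan must be non-negative")
  if (max(abs(rowSums(object@plan) - object@sourceMass)) > 1e-9)
    msg <- c(msg, "plan row sums must equal source mass")
  if (max(abs(colSums(object@plan) - object@targetMass)) > 1e-9)
    msg <- c(msg, "plan column sums must equal target mass")
  if (abs(sum(object@plan * object@cost) - object@distance) > 1e-9)
    msg <- c(msg, "distance must equal the plan cost")
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic islet-cohort generator
#'
#' Describes a cohort of synthetic islets: how many, their size law, cell
#' packing, per-cohort beta-fraction laws, the degree \eqn{\theta} of
#' mantle-core adherence, and boundary waviness. See
#' \code{\link{generateCohort}} for the generative model and the package
#' vignette for the rationale behind the defaults.
#'
#' @slot nIslets integer, islets to generate.
#' @slot areaMedian,areaSdlog log-normal islet-area law (um^2); draws are
#'   truncated below at \code{areaMin}.
#' @slot areaMin numeric, lower truncation of the area law (um^2).
#' @slot cellDensity numeric, cells per um^2 (default 0.005, about five
#'   cells per 1000 um^2).
#' @slot nucleusRadius numeric, nuclear radius in um.
#' @slot betaShape1,betaShape2 Beta-law parameters of the control per-islet
#'   beta fraction (defaults give a mode of 0.8).
#' @slot t1dShape1,t1dShape2 Beta-law parameters of the type 1 diabetes
#'   beta fraction before size coupling.
#' @slot t1dSizeCoupling numeric, exponent coupling beta-cell depletion to
#'   islet size in the t1d cohort (0 disables; larger values deplete small
#'   islets more).
#' @slot t1dFraction numeric in [0, 1], fraction of islets assigned to the
#'   t1d cohort (0 = control-only cohort).
#' @slot theta numeric in [0, 1], probability that an islet is assigned its
#'   types by the mantle-core rule rather than uniformly at random.
#' @slot folding numeric in [0, 1], amplitude of radial lobes on the islet
#'   boundary (0 = near-circle).
#' @slot noneFraction numeric, fraction of cells left unlabelled by any
#'   hormone ("none"), emulating detection dropout.
#' @slot dMin numeric, mantle threshold (um) used by the ordered regime.
#' @slot seed integer, generator seed.
#' @export
setClass("SyntheticConfig",
  slots = c(nIslets = "integer", areaMedian = "numeric", areaSdlog = "numeric",
            areaMin = "numeric", cellDensity = "numeric",
            nucleusRadius = "numeric", betaShape1 = "numeric",
            betaShape2 = "numeric", t1dShape1 = "numeric",
            t1dShape2 = "numeric", t1dSizeCoupling = "numeric",
            t1dFraction = "numeric", theta = "numeric", folding = "numeric",
            noneFraction = "numeric", dMin = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nIslets < 1) msg <- c(msg, "nIslets must be >= 1")
  if (object@theta < 0 || object@theta > 1)
    msg <- c(msg, "theta must lie in [0, 1]")
  if (object@folding < 0 || object@folding > 1)
    msg <- c(msg, "folding must lie in [0, 1]")
  if (object@t1dFraction < 0 || object@t1dFraction > 1)
    msg <- c(msg, "t1dFraction must lie in [0, 1]")
  if (object@noneFraction < 0 || object@noneFraction >= 1)
    msg <- c(msg, "noneFraction must lie in [0, 1)")
  if (object@areaMedian <= 0 || object@areaMin <= 0 ||
      object@cellDensity <= 0 || object@nucleusRadius <= 0 ||
      object@dMin <= 0)
    msg <- c(msg, "areas, density, radius and dMin must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname SyntheticConfig-class
#' @param nIslets,areaMedian,areaSdlog,areaMin,cellDensity,nucleusRadius see
#'   slot descriptions.
#' @param betaShape1,betaShape2,t1dShape1,t1dShape2,t1dSizeCoupling,t1dFraction
#'   see slot descriptions.
#' @param theta,folding,noneFraction,dMin,seed see slot descriptions.
#' @return \code{syntheticConfig()} returns a \code{SyntheticConfig} object.
#' @export
syntheticConfig <- function(nIslets = 300L, areaMedian = 9000,
                            areaSdlog = 0.9, areaMin = 1200,
                            cellDensity = 0.005, nucleusRadius = 3,
                            betaShape1 = 9, betaShape2 = 3,
                            t1dShape1 = 2.2, t1dShape2 = 3.4,
                            t1dSizeCoupling = 0.4, t1dFraction = 0,
                            theta = 0.8, folding = 0.3,
                            noneFraction = 0.06, dMin = 8, seed = 1L) {
  new("SyntheticConfig", nIslets = as.integer(nIslets),
      areaMedian = areaMedian, areaSdlog = areaSdlog, areaMin = areaMin,
      cellDensity = cellDensity, nucleusRadius = nucleusRadius,
      betaShape1 = betaShape1, betaShape2 = betaShape2,
      t1dShape1 = t1dShape1, t1dShape2 = t1dShape2,
      t1dSizeCoupling = t1dSizeCoupling, t1dFraction = t1dFraction,
      theta = theta, folding = folding, noneFraction = noneFraction,
      dMin = dMin, seed = as.integer(seed))
}
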