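#' @include AllClasses.R geometry.R mantleCore.R utils.R
NULL

#' Synthetic islet boundary polygon
#'
#' A star-shaped polygon of prescribed area: a circle of matching radius
#' with smooth radial lobes superimposed. \code{folding = 0} gives a
#' near-circle; larger values give the folded, lobed outlines seen in
#' tissue sections. The vertex radii are rescaled so the polygon area
#' matches \code{area} exactly (well within the 2\% contract).
#'
#' @param area target area in um^2.
#' @param folding lobe amplitude in [0, 1].
#' @param nVertices number of boundary vertices (default 64).
#' @param center polygon center, length-2 numeric.
#' @return a two-column vertex matrix (um); simple by construction.
#' @examples
#' b <- makeIsletBoundary(10000, folding = 0.5)
#' abs(polygonArea(b) - 10000) < 1e-6
#' @export
makeIsletBoundary <- function(area, folding = 0.3, nVertices = 64L,
                              center = c(0, 0)) {
  if (area <= 0) stop("area must be positive")
  if (folding < 0 || folding > 1) stop("folding must lie in [0, 1]")
  phi <- seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
  nLobes <- sample(3:6, 1)
  phase <- runif(2, 0, 2 * pi)
  radial <- 1 + folding * (0.35 * cos(nLobes * phi + phase[1]) +
                           0.10 * cos((nLobes + 3) * phi + phase[2]))
  poly <- cbind(radial * cos(phi), radial * sin(phi))
  poly <- poly * sqrt(area / polygonArea(poly))
  cbind(poly[, 1] + center[1], poly[, 2] + center[2])
}

#' Place cell nuclei inside an islet boundary
#'
#' Samples nuclear centroids uniformly inside the boundary under a
#' hard-core constraint: centroids keep at least \code{2 * nucleusRadius}
#' from each other (where the packing permits) and at least
#' \code{nucleusRadius} from the islet boundary, so the circular nuclei
#' never cross it. The cell count is Poisson with mean
#' \code{area * density}; when the polygon saturates before reaching it,
#' fewer cells are returned with a warning.
#'
#' @param boundary islet polygon (two-column matrix, um).
#' @param density cells per um^2 (default 0.005).
#' @param nucleusRadius nuclear radius in um (default 3).
#' @param nVertices vertices of the polygonized nuclear discs (default 16).
#' @return list with \code{centroids} (n x 2 matrix) and \code{boundaries}
#'   (list of n nuclear polygons).
#' @export
placeCells <- function(boundary, density = 0.005, nucleusRadius = 3,
                       nVertices = 16L) {
  if (density <= 0) stop("density must be positive")
  poly <- asPolygon(boundary)
  area <- polygonArea(poly)
  nTarget <- stats::rpois(1, area * density)
  pts <- cpp_place_hardcore(poly, nTarget, 2 * nucleusRadius,
                            nucleusRadius, 200L)
  if (nrow(pts) < nTarget)
    warning("placed ", nrow(pts), " of ", nTarget,
            " cells; polygon saturated at this separation")
  boundaries <- lapply(seq_len(nrow(pts)), function(i)
    discPolygon(pts[i, ], nucleusRadius, nVertices))
  list(centroids = pts, boundaries = boundaries)
}

#' Assign binary cell types with tunable mantle-core adherence
#'
#' Given each cell's nuclear boundary distance to the islet border, draws
#' the islet's type arrangement. Exact counts are fixed first
#' (\code{B = round(N * betaFraction)} beta cells, the rest non-beta).
#' With probability \code{theta} the islet is ordered by the mantle-core
#' rule: non-beta cells fill the mantle positions (distance <
#' \code{dMin}) first -- a random subset of them when non-beta cells are
#' scarcer than mantle positions, ties randomized -- and any overflow
#' spills into the core. Otherwise the types are a uniform random
#' permutation over positions. The regime actually used is returned as an
#' attribute, the generator's ground truth.
#'
#' @param boundaryDistance numeric vector, per-cell nuclear boundary
#'   distance in um.
#' @param betaFraction target beta fraction in [0, 1].
#' @param theta adherence probability in [0, 1].
#' @param dMin mantle threshold in um (default 8).
#' @return character vector (\code{"beta"}/\code{"non-beta"}) with
#'   attribute \code{regime} (\code{"ordered"} or \code{"random"}).
#' @examples
#' d <- c(0, 2, 5, 10, 20, 30)
#' tt <- assignTypes(d, betaFraction = 0.5, theta = 1)
#' all(tt[d < 8] == "non-beta")
#' @export
assignTypes <- function(boundaryDistance, betaFraction, theta, dMin = 8) {
  if (betaFraction < 0 || betaFraction > 1 || theta < 0 || theta > 1)
    stop("betaFraction and theta must lie in [0, 1]")
  n <- length(boundaryDistance)
  b <- round(n * betaFraction)
  nb <- n - b
  type <- rep("beta", n)
  ordered <- runif(1) < theta
  if (n > 0) {
    if (ordered) {
      mantle <- which(boundaryDistance < dMin)
      core <- which(boundaryDistance >= dMin)
      if (nb <= length(mantle)) {
        take <- if (nb > 0) sample(mantle, nb) else integer()
      } else {
        spill <- nb - length(mantle)
        take <- c(mantle, if (spill > 0) sample(core, min(spill, length(core))))
      }
      type[take] <- "non-beta"
    } else if (nb > 0) {
      type[sample.int(n, nb)] <- "non-beta"
    }
  }
  attr(type, "regime") <- if (ordered) "ordered" else "random"
  type
}

# split the non-beta cells into the minor hormone lineages with typical
# compositional weights (alpha-dominated)
NONBETA_WEIGHTS <- c(alpha = 0.70, delta = 0.20, gamma = 0.08,
                     epsilon = 0.02)

#' Generate a synthetic islet cohort
#'
#' Builds a full \linkS4class{IsletStudy} of synthetic islets with known
#' ground-truth architecture: log-normal islet areas, folded boundaries,
#' hard-core-packed circular nuclei, per-islet beta fractions from
#' per-cohort Beta laws (control mode near 0.8; the t1d law additionally
#' depletes beta cells in small islets), a fraction of hormone-negative
#' ("none") cells, and type arrangements drawn with mantle-core adherence
#' \code{theta} -- a mixture of perfectly ordered and fully random islets.
#' Boundary distances used for the ordered regime are computed from the
#' very nuclear polygons the study carries, so downstream annotation
#' reproduces the generator's ground truth exactly.
#'
#' The output passes \code{\link{applyStudyFilters}} and
#' \code{\link{annotatePositions}} unchanged. Ground truth is stored in
#' \code{provenance(study)$ground_truth}: per-islet regime and target beta
#' fraction, and per-cell true position and distance. All randomness flows
#' from \code{config@seed} through per-islet derived substreams, so
#' cohorts are reproducible.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return an \linkS4class{IsletStudy}.
#' @examples
#' cohort <- generateCohort(syntheticConfig(nIslets = 10, seed = 42))
#' cohort
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  n <- config@nIslets
  isletSeeds <- deriveSeeds(config@seed, n + 1L)

  # donors: islets grouped into cases of ~50, disease status per donor;
  # with both cohorts requested, force at least one case of each
  nCases <- max(1L, ceiling(n / 50))
  if (config@t1dFraction > 0 && config@t1dFraction < 1)
    nCases <- max(nCases, 2L)
  nT1dCases <- round(nCases * config@t1dFraction)
  if (config@t1dFraction > 0) nT1dCases <- max(1L, nT1dCases)
  if (config@t1dFraction < 1) nT1dCases <- min(nCases - 1L, nT1dCases)
  caseStatus <- c(rep("t1d", nT1dCases), rep("control", nCases - nT1dCases))
  caseOfIslet <- ((seq_len(n) - 1L) %% nCases) + 1L

  # grid layout keeps islets disjoint in one global coordinate frame
  spacing <- 2.2 * sqrt(exp(log(config@areaMedian) + 3 * config@areaSdlog) / pi)
  nGrid <- ceiling(sqrt(n))

  cellRows <- vector("list", n)
  isletRows <- vector("list", n)
  cellBnds <- vector("list", n)
  isletBnds <- vector("list", n)
  gtIslet <- vector("list", n)
  gtCell <- vector("list", n)

  for (i in seq_len(n)) {
    withSeed(isletSeeds[i], {
      iid <- sprintf("islet_%05d", i)
      status <- caseStatus[caseOfIslet[i]]
      caseId <- sprintf("case_%s_%02d", status, caseOfIslet[i])
      area <- stats::rlnorm(1, log(config@areaMedian), config@areaSdlog)
      for (try in 1:100) {
        if (area > config@areaMin) break
        area <- stats::rlnorm(1, log(config@areaMedian), config@areaSdlog)
      }
      if (area <= config@areaMin) area <- config@areaMin * 1.01
      center <- c(((i - 1L) %% nGrid) * spacing,
                  ((i - 1L) %/% nGrid) * spacing)
      bnd <- makeIsletBoundary(area, config@folding, center = center)
      placed <- suppressWarnings(
        placeCells(bnd, config@cellDensity, config@nucleusRadius))
      nc <- nrow(placed$centroids)
      betaFrac <- if (status == "control") {
        stats::rbeta(1, config@betaShape1, config@betaShape2)
      } else {
        stats::rbeta(1, config@t1dShape1, config@t1dShape2) *
          min(1, (area / 10000)^config@t1dSizeCoupling)
      }
      if (nc > 0) {
        cids <- sprintf("%s_c%04d", iid, seq_len(nc))
        dist <- vapply(placed$boundaries, function(p)
          cpp_polygon_min_distance(p, bnd), 0)
        isNone <- runif(nc) < config@noneFraction
        lab <- which(!isNone)
        hormone <- rep("none", nc)
        regime <- "random"
        if (length(lab)) {
          type <- assignTypes(dist[lab], betaFrac, config@theta, config@dMin)
          regime <- attr(type, "regime")
          nonbeta <- lab[type == "non-beta"]
          hormone[lab[type == "beta"]] <- "beta"
          if (length(nonbeta))
            hormone[nonbeta] <- sample(names(NONBETA_WEIGHTS),
                                       length(nonbeta), replace = TRUE,
                                       prob = NONBETA_WEIGHTS)
        }
        cellRows[[i]] <- data.frame(
          cell_id = cids, islet_id = iid, case_id = caseId,
          x = placed$centroids[, 1], y = placed$centroids[, 2],
          hormone_class = hormone, stringsAsFactors = FALSE)
        cellBnds[[i]] <- setNames(placed$boundaries, cids)
        gtCell[[i]] <- data.frame(
          cell_id = cids, true_distance = dist,
          true_position = ifelse(dist < config@dMin, "mantle", "core"),
          stringsAsFactors = FALSE)
      } else {
        regime <- "random"
      }
      isletRows[[i]] <- data.frame(
        islet_id = iid, case_id = caseId, disease_status = status,
        area_um2 = polygonArea(bnd),
        centroid_x = center[1], centroid_y = center[2],
        stringsAsFactors = FALSE)
      isletBnds[[i]] <- bnd
      gtIslet[[i]] <- data.frame(islet_id = iid, regime = regime,
                                 target_beta_fraction = betaFrac,
                                 seed = isletSeeds[i],
                                 stringsAsFactors = FALSE)
    })
  }

  isletDf <- do.call(rbind, isletRows)
  cellDf <- do.call(rbind, cellRows[!vapply(cellRows, is.null, TRUE)])
  if (is.null(cellDf))
    cellDf <- data.frame(cell_id = character(), islet_id = character(),
                         case_id = character(), x = numeric(), y = numeric(),
                         hormone_class = character(), stringsAsFactors = FALSE)
  cellDf$binary_type <- NA_character_
  cellDf$position <- NA_character_
  cellDf$boundary_distance <- NA_real_
  names(isletBnds) <- isletDf$islet_id
  cellBnds <- do.call(c, cellBnds[!vapply(cellBnds, is.null, TRUE)])

  prov <- list(
    sources = list(generator = "generateCohort",
                   config = configAsList(config)),
    warnings = character(),
    orphans = cellDf[0, , drop = FALSE],
    ground_truth = list(
      islets = do.call(rbind, gtIslet),
      cells = do.call(rbind, gtCell[!vapply(gtCell, is.null, TRUE)])))
  IsletStudy(cells = cellDf[, CELL_COLUMNS], islets = isletDf,
             cellBoundaries = cellBnds, isletBoundaries = isletBnds,
             params = AnalysisParams(dMin = config@dMin,
                                     rngSeed = config@seed),
             provenance = prov)
}

configAsList <- function(config) {
  sn <- slotNames(class(config))
  setNames(lapply(sn, function(s) slot(config, s)), sn)
}
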