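#' @include AllClasses.R geometry.R
NULL

#' Hormone classification synonyms
#'
#' Detection exports label cells by hormone stain; this map translates the
#' common marker names to the canonical classes
#' \code{alpha, beta, delta, epsilon, gamma, none}. Matching is
#' case-insensitive. Extend it by passing additional \code{name = class}
#' pairs to the readers.
#'
#' @return named character vector mapping export labels to canonical classes.
#' @examples
#' defaultHormoneSynonyms()["ins"]
#' @export
defaultHormoneSynonyms <- function() {
  c(alpha = "alpha", beta = "beta", delta = "delta", epsilon = "epsilon",
    gamma = "gamma", none = "none",
    ins = "beta", insulin = "beta",
    gcg = "alpha", glucagon = "alpha",
    sst = "delta", somatostatin = "delta",
    ppy = "gamma", pp = "gamma", "pancreatic polypeptide" = "gamma",
    ghrl = "epsilon", ghrelin = "epsilon",
    negative = "none", unclassified = "none")
}

normalizeHormone <- function(labels, synonyms = defaultHormoneSynonyms()) {
  key <- tolower(trimws(as.character(labels)))
  out <- unname(synonyms[key])
  bad <- is.na(out)
  if (any(bad))
    stop("unrecognised hormone classification(s): ",
         paste(unique(labels[bad]), collapse = ", "),
         " (extend the synonym map to accept them)")
  out
}

# ---- WKT helpers (POLYGON only, the single format the tables carry) -----

formatWKT <- function(poly) {
  p <- asPolygon(poly)
  ring <- rbind(p, p[1, ])
  paste0("POLYGON ((",
         paste(sprintf("%.10g %.10g", ring[, 1], ring[, 2]), collapse = ", "),
         "))")
}

parseWKT <- function(wkt) {
  s <- trimws(wkt)
  if (!grepl("^POLYGON", s, ignore.case = TRUE))
    stop("expected a WKT POLYGON, got: ", substr(s, 1, 30))
  inner <- sub("^POLYGON\\s*\\(\\(", "", s, ignore.case = TRUE)
  inner <- sub("\\)\\).*$", "", inner)
  parts <- strsplit(inner, ",")[[1]]
  xy <- vapply(parts, function(pt) {
    nums <- as.numeric(strsplit(trimws(pt), "\\s+")[[1]])
    if (length(nums) < 2 || anyNA(nums)) stop("malformed WKT coordinate: ", pt)
    nums[1:2]
  }, numeric(2))
  asPolygon(t(xy))
}

# ---- shared assembly ----------------------------------------------------

# Build an IsletStudy from parsed pieces, assigning parentless cells to
# islets by centroid containment (even-odd rule; boundary points count as
# inside) and routing cells contained by no islet to the orphan list.
assembleStudy <- function(cellDf, isletDf, cellBoundaries, isletBoundaries,
                          params, provenance) {
  if (anyDuplicated(isletDf$islet_id))
    stop("duplicate islet_id: ",
         paste(unique(isletDf$islet_id[duplicated(isletDf$islet_id)]),
               collapse = ", "))
  # resolve parentless cells by containment
  needs <- which(is.na(cellDf$islet_id) | cellDf$islet_id == "")
  if (length(needs)) {
    pts <- cbind(cellDf$x[needs], cellDf$y[needs])
    assigned <- rep(NA_character_, length(needs))
    for (iid in isletDf$islet_id) {
      open <- is.na(assigned)
      if (!any(open)) break
      hit <- pointsInPolygon(pts[open, , drop = FALSE], isletBoundaries[[iid]])
      assigned[open][hit] <- iid
    }
    cellDf$islet_id[needs] <- assigned
  }
  unknown <- !is.na(cellDf$islet_id) & cellDf$islet_id != "" &
    !cellDf$islet_id %in% isletDf$islet_id
  if (any(unknown))
    stop("cell row(s) reference unknown islet_id: ",
         paste(unique(cellDf$islet_id[unknown]), collapse = ", "))
  orphan <- is.na(cellDf$islet_id)
  provenance$orphans <- cellDf[orphan, , drop = FALSE]
  if (any(orphan))
    provenance$warnings <- c(provenance$warnings, paste(
      sum(orphan), "cell(s) fell inside no islet boundary;",
      "routed to the orphan list"))
  cellDf <- cellDf[!orphan, , drop = FALSE]
  # case_id inherited from the islet when absent on the cell
  miss <- is.na(cellDf$case_id) | cellDf$case_id == ""
  if (any(miss)) {
    lookup <- setNames(isletDf$case_id, isletDf$islet_id)
    cellDf$case_id[miss] <- unname(lookup[cellDf$islet_id[miss]])
  }
  cellDf$binary_type <- NA_character_
  cellDf$position <- NA_character_
  cellDf$boundary_distance <- NA_real_
  IsletStudy(cells = cellDf[, CELL_COLUMNS],
             islets = isletDf[, ISLET_COLUMNS],
             cellBoundaries = cellBoundaries,
             isletBoundaries = isletBoundaries,
             params = params, provenance = provenance)
}

# validate a recorded area against the authoritative polygon area (1%)
reconcileAreas <- function(isletDf, isletBoundaries, provenance) {
  polyArea <- vapply(isletDf$islet_id,
                     function(i) polygonArea(isletBoundaries[[i]]), 0)
  if ("area_um2" %in% names(isletDf) && any(!is.na(isletDf$area_um2))) {
    rec <- isletDf$area_um2
    off <- !is.na(rec) & abs(rec - polyArea) > 0.01 * polyArea
    if (any(off))
      provenance$warnings <- c(provenance$warnings, paste0(
        "recorded area deviates from polygon area by >1% for islet(s): ",
        paste(isletDf$islet_id[off], collapse = ", "),
        " (polygon area used)"))
  }
  isletDf$area_um2 <- polyArea
  list(islets = isletDf, provenance = provenance)
}

readDelim <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
  read.csv(path, sep = sep, stringsAsFactors = FALSE,
           check.names = TRUE, fileEncoding = "UTF-8")
}

requireColumns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("missing required column(s) in ", what, ": ",
         paste(miss, collapse = ", "))
}

#' Read a tabular (CSV/TSV) detection export
#'
#' Reads the two-table export format: a cell table (one row per detected
#' endocrine cell) and an islet table (one row per islet). Comma- or
#' tab-delimited UTF-8 files are accepted; the delimiter is sniffed from the
#' header line.
#'
#' Required cell columns: \code{cell_id}, \code{islet_id}, \code{case_id},
#' \code{centroid_x_um}, \code{centroid_y_um}, \code{hormone_class};
#' optionally \code{nuclear_boundary_wkt} (a WKT POLYGON). Required islet
#' columns: \code{islet_id}, \code{case_id}, \code{disease_status},
#' \code{boundary_wkt}; optionally \code{area_um2}. The boundary polygon is
#' authoritative for area; a recorded \code{area_um2} deviating by more than
#' 1\% is flagged in the provenance record. When nuclear boundaries are
#' absent a disc of radius \code{discRadius} centred on the centroid is
#' substituted and flagged in provenance.
#'
#' @param cellPath,isletPath file paths.
#' @param discRadius radius (um) of the substitute nuclear disc used when
#'   the cell table carries no boundary column.
#' @param scale optional scale factor applied to all coordinates (and
#'   squared for areas), for exports in pixels; default 1 (coordinates
#'   already in um).
#' @param synonyms hormone-label synonym map, see
#'   \code{\link{defaultHormoneSynonyms}}.
#' @param params an \linkS4class{AnalysisParams}.
#' @return an \linkS4class{IsletStudy}.
#' @seealso \code{\link{writeTabular}}, \code{\link{readQuPathGeoJSON}},
#'   \code{\link{applyStudyFilters}}
#' @export
readTabular <- function(cellPath, isletPath, discRadius = 4, scale = 1,
                        synonyms = defaultHormoneSynonyms(),
                        params = AnalysisParams()) {
  cellsRaw <- readDelim(cellPath)
  isletsRaw <- readDelim(isletPath)
  requireColumns(cellsRaw, c("cell_id", "islet_id", "case_id",
                             "centroid_x_um", "centroid_y_um",
                             "hormone_class"), "cell table")
  requireColumns(isletsRaw, c("islet_id", "case_id", "disease_status",
                              "boundary_wkt"), "islet table")
  prov <- list(sources = list(cell_table = cellPath, islet_table = isletPath),
               warnings = character())

  isletDf <- data.frame(islet_id = as.character(isletsRaw$islet_id),
                        case_id = as.character(isletsRaw$case_id),
                        disease_status = as.character(isletsRaw$disease_status),
                        area_um2 = if ("area_um2" %in% names(isletsRaw))
                          isletsRaw$area_um2 * scale^2 else NA_real_,
                        stringsAsFactors = FALSE)
  isletBoundaries <- lapply(seq_len(nrow(isletsRaw)), function(i)
    parseWKT(isletsRaw$boundary_wkt[i]) * scale)
  names(isletBoundaries) <- isletDf$islet_id
  cent <- t(vapply(isletBoundaries[isletDf$islet_id], polygonCentroid,
                   numeric(2)))
  isletDf$centroid_x <- cent[, 1]
  isletDf$centroid_y <- cent[, 2]
  rec <- reconcileAreas(isletDf, isletBoundaries, prov)
  isletDf <- rec$islets
  prov <- rec$provenance

  cellDf <- data.frame(cell_id = as.character(cellsRaw$cell_id),
                       islet_id = as.character(cellsRaw$islet_id),
                       case_id = as.character(cellsRaw$case_id),
                       x = cellsRaw$centroid_x_um * scale,
                       y = cellsRaw$centroid_y_um * scale,
                       hormone_class = normalizeHormone(cellsRaw$hormone_class,
                                                        synonyms),
                       stringsAsFactors = FALSE)
  if (anyDuplicated(cellDf$cell_id))
    stop("duplicate cell_id in cell table")
  if ("nuclear_boundary_wkt" %in% names(cellsRaw) &&
      any(nzchar(cellsRaw$nuclear_boundary_wkt))) {
    cellBoundaries <- lapply(seq_len(nrow(cellsRaw)), function(i)
      parseWKT(cellsRaw$nuclear_boundary_wkt[i]) * scale)
  } else {
    prov$warnings <- c(prov$warnings, paste0(
      "no nuclear boundary column; substituted discs of radius ",
      discRadius, " um"))
    prov$disc_substituted <- TRUE
    cellBoundaries <- lapply(seq_len(nrow(cellDf)), function(i)
      discPolygon(c(cellDf$x[i], cellDf$y[i]), discRadius))
  }
  names(cellBoundaries) <- cellDf$cell_id
  assembleStudy(cellDf, isletDf, cellBoundaries, isletBoundaries,
                params, prov)
}

#' Read QuPath-style GeoJSON detection exports
#'
#' Reads two GeoJSON FeatureCollections: islet annotations (Polygon features
#' with properties \code{islet_id}, \code{case_id} and optionally
#' \code{disease_status} and \code{area_um2}) and cell detections (Polygon
#' nuclear boundaries or Point centroids with properties \code{cell_id},
#' optional \code{islet_id}, and a \code{classification} that may be either
#' a string or a QuPath-style object with a \code{name} field). Cells
#' without an explicit parent are assigned to the islet whose boundary
#' contains their centroid; cells contained by no islet are routed to the
#' provenance orphan list and reported, never silently dropped.
#'
#' @param isletPath,cellPath GeoJSON file paths.
#' @param caseMeta optional named vector mapping \code{case_id} to disease
#'   status (\code{"control"} or \code{"t1d"}); used when islet features do
#'   not carry a \code{disease_status} property.
#' @param pointRadius radius (um) of the substitute nuclear disc for cell
#'   features delivered as Points.
#' @inheritParams readTabular
#' @return an \linkS4class{IsletStudy}.
#' @seealso \code{\link{readTabular}}, \code{\link{writeGeoJSON}}
#' @export
readQuPathGeoJSON <- function(isletPath, cellPath, caseMeta = NULL,
                              pointRadius = 4, scale = 1,
                              synonyms = defaultHormoneSynonyms(),
                              params = AnalysisParams()) {
  gjIslet <- jsonlite::read_json(isletPath)
  gjCell <- jsonlite::read_json(cellPath)
  for (gj in list(gjIslet, gjCell))
    if (!identical(gj$type, "FeatureCollection") || is.null(gj$features))
      stop("not a GeoJSON FeatureCollection")
  prov <- list(sources = list(islet_geojson = isletPath,
                              cell_geojson = cellPath),
               warnings = character())

  ringToMatrix <- function(coords) {
    ring <- coords[[1]] # exterior ring
    m <- t(vapply(ring, function(v) as.numeric(unlist(v)[1:2]), numeric(2)))
    asPolygon(m) * scale
  }
  featProp <- function(f, key) {
    v <- f$properties[[key]]
    if (is.null(v)) NA_character_ else as.character(v)
  }

  nI <- length(gjIslet$features)
  isletRows <- vector("list", nI)
  isletBoundaries <- vector("list", nI)
  for (i in seq_len(nI)) {
    f <- gjIslet$features[[i]]
    ok <- tryCatch({
      if (!identical(f$geometry$type, "Polygon"))
        stop("islet feature must be a Polygon")
      isletBoundaries[[i]] <- ringToMatrix(f$geometry$coordinates)
      isletRows[[i]] <- data.frame(
        islet_id = featProp(f, "islet_id"),
        case_id = featProp(f, "case_id"),
        disease_status = featProp(f, "disease_status"),
        area_um2 = suppressWarnings(
          as.numeric(featProp(f, "area_um2"))) * scale^2,
        stringsAsFactors = FALSE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop("malformed islet GeoJSON at feature ", i, ": ",
           conditionMessage(ok))
  }
  isletDf <- do.call(rbind, isletRows)
  if (anyNA(isletDf$islet_id))
    stop("islet feature(s) missing the islet_id property")
  names(isletBoundaries) <- isletDf$islet_id
  if (anyNA(isletDf$disease_status) && !is.null(caseMeta))
    isletDf$disease_status <- ifelse(
      is.na(isletDf$disease_status),
      unname(caseMeta[isletDf$case_id]), isletDf$disease_status)
  cent <- t(vapply(isletBoundaries[isletDf$islet_id], polygonCentroid,
                   numeric(2)))
  isletDf$centroid_x <- cent[, 1]
  isletDf$centroid_y <- cent[, 2]
  rec <- reconcileAreas(isletDf, isletBoundaries, prov)
  isletDf <- rec$islets
  prov <- rec$provenance

  nC <- length(gjCell$features)
  cellRows <- vector("list", nC)
  cellBoundaries <- vector("list", nC)
  for (i in seq_len(nC)) {
    f <- gjCell$features[[i]]
    ok <- tryCatch({
      cls <- f$properties$classification
      if (is.list(cls)) cls <- cls$name
      if (is.null(cls)) stop("cell feature missing classification")
      gt <- f$geometry$type
      if (identical(gt, "Polygon")) {
        poly <- ringToMatrix(f$geometry$coordinates)
        cen <- polygonCentroid(poly)
      } else if (identical(gt, "Point")) {
        cen <- as.numeric(unlist(f$geometry$coordinates)[1:2]) * scale
        poly <- discPolygon(cen, pointRadius)
      } else stop("cell geometry must be Polygon or Point")
      cellBoundaries[[i]] <- poly
      cid <- featProp(f, "cell_id")
      cellRows[[i]] <- data.frame(
        cell_id = if (is.na(cid)) paste0("cell_", i) else cid,
        islet_id = featProp(f, "islet_id"),
        case_id = featProp(f, "case_id"),
        x = cen[1], y = cen[2],
        hormone_class = normalizeHormone(cls, synonyms),
        stringsAsFactors = FALSE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop("malformed cell GeoJSON at feature ", i, ": ",
           conditionMessage(ok))
  }
  cellDf <- do.call(rbind, cellRows)
  names(cellBoundaries) <- cellDf$cell_id
  assembleStudy(cellDf, isletDf, cellBoundaries, isletBoundaries,
                params, prov)
}

#' Write a study to the tabular export format
#'
#' Writes the canonical two-table representation (cell table with WKT
#' nuclear boundaries, islet table with WKT boundaries) so that
#' \code{\link{readTabular}} round-trips the dataset. Annotation columns
#' (\code{binary_type}, \code{position}, \code{boundary_distance_um}) are
#' included when present.
#'
#' @param study an \linkS4class{IsletStudy}.
#' @param cellPath,isletPath output file paths.
#' @return invisibly, the two paths.
#' @export
writeTabular <- function(study, cellPath, isletPath) {
  cl <- cells(study)
  out <- data.frame(cell_id = cl$cell_id, islet_id = cl$islet_id,
                    case_id = cl$case_id,
                    centroid_x_um = sprintf("%.10g", cl$x),
                    centroid_y_um = sprintf("%.10g", cl$y),
                    hormone_class = cl$hormone_class,
                    binary_type = cl$binary_type,
                    position = cl$position,
                    boundary_distance_um = ifelse(
                      is.na(cl$boundary_distance), "",
                      sprintf("%.10g", cl$boundary_distance)),
                    nuclear_boundary_wkt = unname(vapply(
                      study@cellBoundaries[cl$cell_id], formatWKT, "")),
                    stringsAsFactors = FALSE)
  write.csv(out, cellPath, row.names = FALSE)
  il <- islets(study)
  outI <- data.frame(islet_id = il$islet_id, case_id = il$case_id,
                     disease_status = il$disease_status,
                     area_um2 = sprintf("%.10g", il$area_um2),
                     boundary_wkt = vapply(
                       il$islet_id,
                       function(i) formatWKT(study@isletBoundaries[[i]]), ""),
                     stringsAsFactors = FALSE)
  write.csv(outI, isletPath, row.names = FALSE)
  invisible(c(cellPath, isletPath))
}

#' Write a study as QuPath-style GeoJSON
#'
#' Emits two FeatureCollections (islets, cells) that
#' \code{\link{readQuPathGeoJSON}} reads back without loss.
#'
#' @inheritParams writeTabular
#' @return invisibly, the two paths.
#' @export
writeGeoJSON <- function(study, isletPath, cellPath) {
  closeRing <- function(p) {
    ring <- rbind(p, p[1, ])
    lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
  }
  il <- islets(study)
  isletFeatures <- lapply(seq_len(nrow(il)), function(i) list(
    type = "Feature",
    geometry = list(type = "Polygon", coordinates = list(
      closeRing(study@isletBoundaries[[il$islet_id[i]]]))),
    properties = list(islet_id = il$islet_id[i], case_id = il$case_id[i],
                      disease_status = il$disease_status[i],
                      area_um2 = il$area_um2[i])))
  cl <- cells(study)
  cellBnds <- study@cellBoundaries[cl$cell_id]
  cellFeatures <- lapply(seq_len(nrow(cl)), function(i) list(
    type = "Feature",
    geometry = list(type = "Polygon", coordinates = list(
      closeRing(cellBnds[[i]]))),
    properties = list(cell_id = cl$cell_id[i], islet_id = cl$islet_id[i],
                      case_id = cl$case_id[i],
                      classification = cl$hormone_class[i])))
  jsonlite::write_json(
    list(type = "FeatureCollection", features = isletFeatures),
    isletPath, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(type = "FeatureCollection", features = cellFeatures),
    cellPath, auto_unbox = TRUE, digits = NA)
  invisible(c(isletPath, cellPath))
}

#' Apply the study inclusion filters
#'
#' Applies the two study filters in order: (1) islets whose cross-sectional
#' area is not strictly greater than \code{minIsletArea} (default 1000 um^2,
#' about five cells) are removed together with their cells -- clusters at or
#' below the threshold are too small to exhibit a mantle-core structure;
#' (2) cells not labelled by any hormone (\code{hormone_class == "none"},
#' about 6\% of detections in typical exports) are removed. Remaining cells
#' receive their binary type: \code{beta}, or \code{non-beta} for alpha,
#' delta, epsilon and gamma cells. Islets left with zero cells are retained
#' but flagged in \code{provenance(study)$empty_islets}; downstream stages
#' skip them. The operation is idempotent and records exact tallies so that
#' cells in = cells kept + cells removed ('none') + cells removed with
#' sub-threshold islets.
#'
#' @param study an \linkS4class{IsletStudy}.
#' @return the filtered \linkS4class{IsletStudy}; an empty result is legal.
#' @examples
#' cohort <- generateCohort(syntheticConfig(nIslets = 5, seed = 1))
#' filtered <- applyStudyFilters(cohort)
#' provenance(filtered)$filters
#' @export
applyStudyFilters <- function(study) {
  prov <- study@provenance
  il <- study@islets
  cl <- study@cells
  nCellsIn <- nrow(cl)
  nIsletsIn <- nrow(il)

  keepIslet <- il$area_um2 > study@params@minIsletArea
  removedIsletIds <- il$islet_id[!keepIslet]
  il <- il[keepIslet, , drop = FALSE]
  withRemoved <- cl$islet_id %in% removedIsletIds
  noneCell <- !withRemoved & cl$hormone_class == "none"
  keepCell <- !withRemoved & !noneCell
  cl <- cl[keepCell, , drop = FALSE]
  cl$binary_type <- ifelse(cl$hormone_class == "beta", "beta", "non-beta")

  emptyIslets <- setdiff(il$islet_id, unique(cl$islet_id))
  prov$filters <- list(
    islets_in = nIsletsIn,
    islets_removed_small = length(removedIsletIds),
    islets_kept = nrow(il),
    cells_in = nCellsIn,
    cells_removed_with_islet = sum(withRemoved),
    cells_removed_none = sum(noneCell),
    cells_kept = nrow(cl),
    min_islet_area = study@params@minIsletArea)
  prov$empty_islets <- emptyIslets
  if (length(emptyIslets))
    prov$warnings <- c(prov$warnings, paste(
      length(emptyIslets),
      "islet(s) retained with zero cells after filtering"))

  IsletStudy(cells = cl, islets = il,
             cellBoundaries = study@cellBoundaries[cl$cell_id],
             isletBoundaries = study@isletBoundaries[il$islet_id],
             counts = emptyCountTable(),
             params = study@params, provenance = prov)
}
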