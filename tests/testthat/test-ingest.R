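test_that("tabular round trip preserves counts, classes, coordinates and areas", {
  cohort <- generateCohort(syntheticConfig(nIslets = 6, t1dFraction = 0.5,
                                           seed = 21))
  cellsCsv <- withr::local_tempfile(fileext = ".csv")
  isletsCsv <- withr::local_tempfile(fileext = ".csv")
  writeTabular(cohort, cellsCsv, isletsCsv)
  back <- readTabular(cellsCsv, isletsCsv)
  expect_equal(nCells(back), nCells(cohort))
  expect_equal(nIslets(back), nIslets(cohort))
  m <- match(cells(cohort)$cell_id, cells(back)$cell_id)
  expect_lt(max(abs(cells(back)$x[m] - cells(cohort)$x)), 1e-6)
  expect_lt(max(abs(cells(back)$y[m] - cells(cohort)$y)), 1e-6)
  expect_identical(cells(back)$hormone_class[m], cells(cohort)$hormone_class)
  mi <- match(islets(cohort)$islet_id, islets(back)$islet_id)
  expect_lt(max(abs(islets(back)$area_um2[mi] - islets(cohort)$area_um2) /
                  islets(cohort)$area_um2), 1e-6)
  expect_identical(islets(back)$disease_status[mi],
                   islets(cohort)$disease_status)
})

test_that("GeoJSON round trip preserves the dataset", {
  cohort <- generateCohort(syntheticConfig(nIslets = 4, seed = 8))
  gi <- withr::local_tempfile(fileext = ".geojson")
  gc <- withr::local_tempfile(fileext = ".geojson")
  writeGeoJSON(cohort, gi, gc)
  back <- readQuPathGeoJSON(gi, gc)
  expect_equal(nCells(back), nCells(cohort))
  expect_equal(nIslets(back), nIslets(cohort))
  m <- match(cells(cohort)$cell_id, cells(back)$cell_id)
  expect_lt(max(abs(cells(back)$x[m] - cells(cohort)$x)), 1e-6)
  expect_identical(cells(back)$hormone_class[m], cells(cohort)$hormone_class)
  # boundary polygons survive vertex for vertex
  iid <- islets(cohort)$islet_id[1]
  expect_lt(max(abs(isletBoundary(back, iid) - isletBoundary(cohort, iid))),
            1e-9)
})

test_that("cells without a parent islet are assigned by containment, orphans reported", {
  dir <- withr::local_tempdir()
  isletGj <- file.path(dir, "islets.geojson")
  cellGj <- file.path(dir, "cells.geojson")
  ring <- list(list(c(0, 0), c(100, 0), c(100, 100), c(0, 100), c(0, 0)))
  jsonlite::write_json(list(type = "FeatureCollection", features = list(
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = ring),
         properties = list(islet_id = "A", case_id = "k1",
                           disease_status = "control")))),
    isletGj, auto_unbox = TRUE, digits = NA)
  mkCell <- function(id, x, y, cls)
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(x, y)),
         properties = list(cell_id = id, classification = cls))
  jsonlite::write_json(list(type = "FeatureCollection", features = list(
    mkCell("in1", 50, 50, "INS"),
    mkCell("in2", 0, 50, "GCG"),     # on the boundary: inside
    mkCell("out1", 500, 500, "SST"))),
    cellGj, auto_unbox = TRUE, digits = NA)
  study <- readQuPathGeoJSON(isletGj, cellGj)
  expect_equal(nCells(study), 2)
  expect_equal(nrow(provenance(study)$orphans), 1)
  expect_identical(provenance(study)$orphans$cell_id, "out1")
  # synonym map applied case-insensitively
  expect_identical(sort(cells(study)$hormone_class), c("alpha", "beta"))
  expect_identical(cells(study)$islet_id, c("A", "A"))
})

test_that("malformed inputs produce named, early errors", {
  dir <- withr::local_tempdir()
  cellsCsv <- file.path(dir, "cells.csv")
  isletsCsv <- file.path(dir, "islets.csv")
  wkt <- "POLYGON ((0 0, 100 0, 100 100, 0 100, 0 0))"
  write.csv(data.frame(islet_id = "A", case_id = "k", disease_status = "control",
                       boundary_wkt = wkt, area_um2 = 10000),
            isletsCsv, row.names = FALSE)
  write.csv(data.frame(cell_id = "c1", islet_id = "B", case_id = "k",
                       centroid_x_um = 5, centroid_y_um = 5,
                       hormone_class = "beta"),
            cellsCsv, row.names = FALSE)
  expect_error(readTabular(cellsCsv, isletsCsv), "unknown islet_id")

  write.csv(data.frame(cell_id = "c1", islet_id = "A",
                       centroid_x_um = 5, centroid_y_um = 5,
                       hormone_class = "beta"),
            cellsCsv, row.names = FALSE)
  expect_error(readTabular(cellsCsv, isletsCsv), "case_id")

  write.csv(data.frame(islet_id = c("A", "A"), case_id = "k",
                       disease_status = "control", boundary_wkt = wkt,
                       area_um2 = 10000),
            isletsCsv, row.names = FALSE)
  write.csv(data.frame(cell_id = "c1", islet_id = "A", case_id = "k",
                       centroid_x_um = 5, centroid_y_um = 5,
                       hormone_class = "beta"),
            cellsCsv, row.names = FALSE)
  expect_error(readTabular(cellsCsv, isletsCsv), "duplicate islet_id")
})

test_that("recorded area conflicting with the polygon is flagged, polygon wins", {
  dir <- withr::local_tempdir()
  cellsCsv <- file.path(dir, "cells.csv")
  isletsCsv <- file.path(dir, "islets.csv")
  wkt <- "POLYGON ((0 0, 100 0, 100 100, 0 100, 0 0))"
  write.csv(data.frame(islet_id = "A", case_id = "k", disease_status = "control",
                       boundary_wkt = wkt, area_um2 = 12000), # >1% off
            isletsCsv, row.names = FALSE)
  write.csv(data.frame(cell_id = "c1", islet_id = "A", case_id = "k",
                       centroid_x_um = 5, centroid_y_um = 5,
                       hormone_class = "none"),
            cellsCsv, row.names = FALSE)
  study <- readTabular(cellsCsv, isletsCsv)
  expect_true(any(grepl("deviates", provenance(study)$warnings)))
  expect_equal(islets(study)$area_um2, 10000)
  # 'none' is retained at ingest; exclusion is a filter step
  expect_identical(cells(study)$hormone_class, "none")
})

test_that("study filters apply the strict area and none-cell rules", {
  mkIslet <- function(id, side, hormones) {
    spec <- data.frame(x = seq(10, side - 10, length.out = length(hormones)),
                       y = side / 2, hormone_class = hormones)
    squareStudy(side = side, cellSpec = spec, isletId = id)
  }
  # merge two single-islet studies into one
  a <- mkIslet("small", sqrt(999), c("beta", "alpha"))
  b <- mkIslet("kept", sqrt(1001), c("beta", "alpha", "none"))
  study <- IsletStudy(
    cells = rbind(cells(a), within(cells(b), cell_id <- paste0("b", cell_id))),
    islets = rbind(islets(a), islets(b)),
    cellBoundaries = c(a@cellBoundaries,
                       setNames(b@cellBoundaries,
                                paste0("b", names(b@cellBoundaries)))),
    isletBoundaries = c(a@isletBoundaries, b@isletBoundaries))
  filtered <- applyStudyFilters(study)
  expect_identical(islets(filtered)$islet_id, "kept")
  expect_equal(nCells(filtered), 2)
  expect_identical(sort(unique(cells(filtered)$binary_type)),
                   c("beta", "non-beta"))
  tall <- provenance(filtered)$filters
  expect_equal(tall$cells_in,
               tall$cells_kept + tall$cells_removed_none +
                 tall$cells_removed_with_islet)
  # idempotence
  again <- applyStudyFilters(filtered)
  expect_equal(cells(again), cells(filtered))
  expect_equal(islets(again), islets(filtered))
})

test_that("islets left empty by the none-filter are retained and flagged", {
  spec <- data.frame(x = c(40, 60), y = 50,
                     hormone_class = c("none", "none"))
  study <- squareStudy(cellSpec = spec)
  filtered <- applyStudyFilters(study)
  expect_equal(nIslets(filtered), 1)
  expect_equal(nCells(filtered), 0)
  expect_identical(provenance(filtered)$empty_islets, "isl1")
  # downstream stages skip empty islets rather than fail
  ann <- annotatePositions(filtered)
  expect_equal(nrow(isletCounts(ann)), 0)
})
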