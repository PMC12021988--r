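# shared fixture builders (everything is generated in code; no data files)

# a single square islet with cells at hand-chosen centroids; nuclei are
# small discs so boundary distances are centroid distance minus the radius
squareStudy <- function(side = 100, cellSpec, discRadius = 2,
                        status = "control", isletId = "isl1",
                        params = AnalysisParams()) {
  bnd <- cbind(c(0, side, side, 0), c(0, 0, side, side))
  n <- nrow(cellSpec)
  ids <- sprintf("c%03d", seq_len(n))
  cellDf <- data.frame(
    cell_id = ids, islet_id = isletId, case_id = "case1",
    x = cellSpec$x, y = cellSpec$y,
    hormone_class = cellSpec$hormone_class,
    binary_type = NA_character_, position = NA_character_,
    boundary_distance = NA_real_, stringsAsFactors = FALSE)
  cellBnds <- lapply(seq_len(n), function(i)
    isletMC:::discPolygon(c(cellSpec$x[i], cellSpec$y[i]), discRadius))
  names(cellBnds) <- ids
  isletDf <- data.frame(
    islet_id = isletId, case_id = "case1", disease_status = status,
    area_um2 = side^2, centroid_x = side / 2, centroid_y = side / 2,
    stringsAsFactors = FALSE)
  IsletStudy(cells = cellDf, islets = isletDf, cellBoundaries = cellBnds,
             isletBoundaries = setNames(list(bnd), isletId), params = params)
}

# brute-force oracle for the randomness probability: enumerate every way of
# choosing the M mantle positions among N cells (the first NB of which are
# non-beta) and count arrangements with at least nbm non-beta mantle cells
rEnumOracle <- function(N, NB, M, nbm) {
  if (M == 0) return(if (nbm <= 0) 1 else 0)
  picks <- utils::combn(N, M)
  counts <- colSums(picks <= NB)
  mean(counts >= nbm)
}

# small annotated synthetic cohort
annotatedCohort <- function(nIslets = 30, theta = 0.8, seed = 1,
                            t1dFraction = 0, ...) {
  cohort <- generateCohort(syntheticConfig(
    nIslets = nIslets, theta = theta, seed = seed,
    t1dFraction = t1dFraction, ...))
  annotatePositions(applyStudyFilters(cohort))
}

# deterministic pseudo-random histogram pair on shared equidistant bins
randomHistPair <- function(k) {
  p <- runif(k)
  q <- runif(k)
  br <- seq(0, 1, length.out = k + 1)
  list(p = new("Histogram1D", breaks = br, mass = p / sum(p),
               nSamples = as.integer(k)),
       q = new("Histogram1D", breaks = br, mass = q / sum(q),
               nSamples = as.integer(k)))
}

hist2dFromRaw <- function(raw, k) {
  new("Histogram2D", xBreaks = seq(0, 1, length.out = k + 1),
      yBreaks = seq(0, 1, length.out = k + 1),
      mass = matrix(raw / sum(raw), k, k), nSamples = length(raw),
      areaScale = NA_real_)
}
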