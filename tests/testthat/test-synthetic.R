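test_that("islet boundaries hit the target area and stay simple", {
  set.seed(5)
  for (i in 1:10) {
    area <- runif(1, 2000, 30000)
    fold <- runif(1)
    b <- makeIsletBoundary(area, folding = fold)
    expect_lt(abs(polygonArea(b) - area) / area, 0.02)
    expect_true(polygonIsSimple(b))
  }
  set.seed(7); b1 <- makeIsletBoundary(5000, 0.4)
  set.seed(7); b2 <- makeIsletBoundary(5000, 0.4)
  expect_identical(b1, b2)
  expect_error(makeIsletBoundary(-1), "positive")
})

test_that("cell placement respects density, containment and separation", {
  set.seed(9)
  b <- makeIsletBoundary(20000, folding = 0.2)
  placed <- placeCells(b, density = 0.005, nucleusRadius = 3)
  n <- nrow(placed$centroids)
  lambda <- 20000 * 0.005
  expect_gt(n, lambda - 4 * sqrt(lambda))
  expect_lt(n, lambda + 4 * sqrt(lambda))
  expect_true(all(pointsInPolygon(placed$centroids, b)))
  # nuclei never cross the islet boundary
  expect_true(all(pointPolygonDistance(placed$centroids, b) >= 3 - 1e-9))
  # hard-core separation at moderate occupancy
  d <- as.matrix(dist(placed$centroids))
  diag(d) <- Inf
  expect_gte(min(d), 6 - 1e-9)
})

test_that("type assignment honours the adherence regimes", {
  d <- c(rep(2, 5), rep(20, 15)) # 5 mantle, 15 core positions
  # theta = 1, NB (10) >= M (5): every mantle position is non-beta
  set.seed(2)
  t1 <- assignTypes(d, betaFraction = 0.5, theta = 1)
  expect_identical(attr(t1, "regime"), "ordered")
  expect_true(all(t1[d < 8] == "non-beta"))
  expect_equal(sum(t1 == "non-beta"), 10)
  # scarce non-beta: all of them sit in the mantle
  set.seed(3)
  t2 <- assignTypes(d, betaFraction = 0.9, theta = 1)
  expect_equal(sum(t2 == "non-beta"), 2)
  expect_true(all(which(t2 == "non-beta") %in% which(d < 8)))
  # theta = 0 reproduces the hypergeometric null across repeats
  set.seed(4)
  nbm <- replicate(4000, {
    tt <- assignTypes(d, betaFraction = 0.5, theta = 0)
    sum(tt[d < 8] == "non-beta")
  })
  expected <- dhyper(0:5, 10, 10, 5)
  gof <- chisq.test(tabulate(nbm + 1L, 6), p = expected)
  expect_gt(gof$p.value, 0.01)
})

test_that("generated cohorts are reproducible and filter-stable", {
  cfg <- syntheticConfig(nIslets = 12, seed = 77)
  c1 <- generateCohort(cfg)
  c2 <- generateCohort(cfg)
  expect_equal(cells(c1), cells(c2))
  expect_equal(islets(c1), islets(c2))
  expect_identical(c1@isletBoundaries, c2@isletBoundaries)
  # byte-identical export
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  g1 <- withr::local_tempfile(); g2 <- withr::local_tempfile()
  writeTabular(c1, f1, g1)
  writeTabular(c2, f2, g2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(g1), readLines(g2))
  # all areas exceed the study threshold under the default truncation
  expect_true(all(islets(c1)$area_um2 > 1000))
  # pipeline closure: filters and annotation accept the output unchanged
  ann <- annotatePositions(applyStudyFilters(c1))
  expect_equal(nIslets(ann), 12)
  expect_gt(nCells(ann), 0)
})

test_that("cohort beta fractions and composition mirror the study conditions", {
  ann <- annotatedCohort(nIslets = 120, theta = 0.8, seed = 101)
  ct <- isletCounts(ann)
  frac <- ct$B / ct$N
  # control beta-fraction distribution peaks near 0.8
  dens <- density(frac, from = 0, to = 1)
  mode <- dens$x[which.max(dens$y)]
  expect_gt(mode, 0.7)
  expect_lt(mode, 0.9)
  # roughly 6% of raw detections are hormone-negative
  raw <- generateCohort(syntheticConfig(nIslets = 60, seed = 55))
  noneFrac <- mean(cells(raw)$hormone_class == "none")
  expect_gt(noneFrac, 0.03)
  expect_lt(noneFrac, 0.09)
})

test_that("adherence strength drives the pooled odds ratio monotonically", {
  ors <- vapply(c(0, 0.5, 1), function(th) {
    ann <- annotatedCohort(nIslets = 80, theta = th, seed = 303)
    oddsRatio(buildContingency(cells(ann)))
  }, 0)
  expect_true(all(diff(ors) < 0))
  expect_gt(ors[1], 0.8) # theta = 0: no mantle-core signal
  expect_lt(ors[3], 0.5) # theta = 1: strong depletion
})

test_that("the t1d law depletes beta cells, most strongly in small islets", {
  ann <- annotatedCohort(nIslets = 160, theta = 0.8, seed = 404,
                         t1dFraction = 0.5)
  ct <- isletCounts(ann)
  il <- islets(ann)
  m <- match(ct$islet_id, il$islet_id)
  frac <- ct$B / ct$N
  t1d <- il$disease_status[m] == "t1d"
  expect_lt(mean(frac[t1d]), mean(frac[!t1d]))
  small <- il$area_um2[m] < 10000
  expect_lt(mean(frac[t1d & small]), mean(frac[t1d & !small]))
})
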