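test_that("histogram binning is equidistant with a right-closed top bin", {
  h <- histogram1D(rep(1, 7), nBins = 12)
  expect_equal(binMass(h)[12], 1)
  expect_equal(sum(binMass(h)), 1)
  expect_equal(h@nSamples, 7L)
  set.seed(3)
  u <- runif(400)
  h10 <- histogram1D(u, 10)
  expect_true(all(abs(binMass(h10) - 0.1) < 4 * sqrt(0.1 * 0.9 / 400)))
  expect_error(histogram1D(numeric()), "non-empty")
  expect_error(histogram1D(c(0.5, 1.2)), "0, 1")
  expect_error(histogram1D(0.5, nBins = 1), "at least 2")
})

test_that("1D EMD attains its printed bounds exactly", {
  vals <- c(0.03, 0.2, 0.2, 0.77, 1)
  h <- histogram1D(vals, 20)
  expect_identical(emdDistance(emd1D(h, h)), 0)
  lo <- histogram1D(rep(0.001, 4), 20)
  hi <- histogram1D(rep(0.999, 4), 20)
  expect_equal(emdDistance(emd1D(lo, hi)), 1)
  # mass in adjacent bins moves one step: 1/(K-1)
  for (k in c(5, 10, 20)) {
    a <- histogram1D(rep(0.5 / k, 3), k)   # bin 1
    b <- histogram1D(rep(1.5 / k, 3), k)   # bin 2
    expect_equal(emdDistance(emd1D(a, b)), 1 / (k - 1), tolerance = 1e-12)
  }
  expect_error(emd1D(histogram1D(0.5, 10), histogram1D(0.5, 12)),
               "identical bin edges")
})

test_that("the monotone 1D construction equals the LP solution", {
  set.seed(11)
  worst <- 0
  for (i in 1:60) {
    k <- sample(4:30, 1)
    hp <- randomHistPair(k)
    res <- emd1D(hp$p, hp$q)
    lp <- solveTransport(hp$p@mass, hp$q@mass, res@cost)
    worst <- max(worst, abs(lp$cost - emdDistance(res)))
  }
  expect_lt(worst, 1e-9)
})

test_that("transport plans have exact marginals and reproduce the distance", {
  set.seed(21)
  for (i in 1:25) {
    k <- sample(4:20, 1)
    hp <- randomHistPair(k)
    res <- emd1D(hp$p, hp$q)
    expect_lt(max(abs(rowSums(transportPlan(res)) - binMass(hp$p))), 1e-9)
    expect_lt(max(abs(colSums(transportPlan(res)) - binMass(hp$q))), 1e-9)
    expect_lt(abs(sum(transportPlan(res) * res@cost) - emdDistance(res)), 1e-9)
  }
})

test_that("EMD satisfies the metric axioms", {
  set.seed(31)
  for (i in 1:20) {
    k <- sample(4:15, 1)
    a <- randomHistPair(k)$p
    b <- randomHistPair(k)$p
    c <- randomHistPair(k)$p
    dab <- emdDistance(emd1D(a, b))
    expect_gte(dab, 0)
    expect_equal(dab, emdDistance(emd1D(b, a)), tolerance = 1e-12)
    expect_equal(emdDistance(emd1D(a, a)), 0)
    expect_lte(dab, emdDistance(emd1D(a, c)) + emdDistance(emd1D(c, b)) + 1e-9)
  }
  # 2D: same axioms through the LP path
  set.seed(41)
  for (i in 1:8) {
    k <- 4
    a <- hist2dFromRaw(runif(k * k), k)
    b <- hist2dFromRaw(runif(k * k), k)
    c <- hist2dFromRaw(runif(k * k), k)
    dab <- emdDistance(emd2D(a, b))
    expect_equal(dab, emdDistance(emd2D(b, a)), tolerance = 1e-9)
    expect_equal(emdDistance(emd2D(a, a)), 0)
    expect_lte(dab,
               emdDistance(emd2D(a, c)) + emdDistance(emd2D(c, b)) + 1e-9)
  }
})

test_that("2D EMD reproduces an independent LP oracle and its bounds", {
  # expected values frozen from an external simplex-method LP solution
  i <- 0:15
  a <- hist2dFromRaw((i * 7) %% 11 + 1, 4)
  b <- hist2dFromRaw((i * 5) %% 13 + 2, 4)
  expect_equal(emdDistance(emd2D(a, b)), 0.1106529209621993,
               tolerance = 1e-12)
  i <- 0:24
  a5 <- hist2dFromRaw((i * 3) %% 7 + 1, 5)
  b5 <- hist2dFromRaw((i * 11) %% 5 + 1, 5)
  expect_equal(emdDistance(emd2D(a5, b5)), 0.15363636363636365,
               tolerance = 1e-12)
  # opposite corners: one unit of work per axis
  c1 <- histogram2D(0.001, 0.001, nBins = 10)
  c2 <- histogram2D(0.999, 0.999, nBins = 10)
  expect_equal(emdDistance(emd2D(c1, c2)), 2)
  # full-range move along x only
  x1 <- histogram2D(0.001, 0.5, nBins = 10)
  x2 <- histogram2D(0.999, 0.5, nBins = 10)
  expect_equal(emdDistance(emd2D(x1, x2)), 1)
  # L2 ground metric: corner move costs sqrt(2)
  expect_equal(emdDistance(emd2D(c1, c2, groundMetric = "L2")), sqrt(2))
  expect_error(emd2D(c1, histogram2D(0.5, 0.5, nBins = 8)),
               "identical bin geometry")
})

test_that("1D robustness sweep: self-comparison is near zero and deterministic", {
  set.seed(51)
  obs <- runif(300)
  gen <- function() sample(obs, replace = TRUE)
  r1 <- robustness1D(obs, gen, binCounts = 8:20, nResamples = 30, seed = 9)
  r2 <- robustness1D(obs, gen, binCounts = 8:20, nResamples = 30, seed = 9)
  expect_identical(r1, r2)
  expect_equal(nrow(r1$binSweep), 13)
  expect_lt(max(r1$resamples$emd), 2 / sqrt(length(obs)))
})

test_that("cohort histograms share geometry and conserve islet mass", {
  ann <- annotatedCohort(nIslets = 50, theta = 0.8, seed = 17,
                         t1dFraction = 0.5)
  hs <- cohortHistograms(ann, binsPerAxis = 12)
  expect_equal(hs$control@xBreaks, hs$t1d@xBreaks)
  expect_equal(hs$control@areaScale, hs$t1d@areaScale)
  ct <- isletCounts(ann)
  il <- islets(ann)
  nCtrl <- sum(il$disease_status[match(ct$islet_id, il$islet_id)] == "control")
  expect_equal(hs$control@nSamples, nCtrl)
  expect_equal(hs$t1d@nSamples, nrow(ct) - nCtrl)
  expect_equal(sum(binMass(hs$control)), 1, tolerance = 1e-12)
  # all-beta islets pile into the top beta-fraction bins
  allBeta <- squareStudy(cellSpec = data.frame(
    x = c(30, 50, 70), y = 50, hormone_class = "beta"))
  expect_error(cohortHistograms(annotatePositions(applyStudyFilters(allBeta))),
               "islet counts|zero islets")
})

test_that("2D robustness sweep covers the bin range and is reproducible", {
  ann <- annotatedCohort(nIslets = 40, theta = 0.8, seed = 27,
                         t1dFraction = 0.5)
  r1 <- robustness2D(ann, binCounts = 8:12, nResamples = 5, nBins = 8,
                     seed = 3)
  r2 <- robustness2D(ann, binCounts = 8:12, nResamples = 5, nBins = 8,
                     seed = 3)
  expect_identical(r1, r2)
  expect_equal(r1$binSweep$n_bins, 8:12)
  expect_true(all(r1$binSweep$emd >= 0 & r1$binSweep$emd <= 2))
})

test_that("the default bin sweep has 33 rows (8..40 inclusive)", {
  expect_length(8:40, 33) # the documented default range used by the sweeps
  set.seed(61)
  obs <- runif(80)
  r <- robustness1D(obs, function() runif(80), nResamples = 2, seed = 1)
  expect_equal(nrow(r$binSweep), 33)
})

test_that("the transportation solver handles degenerate and unbalanced input", {
  expect_error(solveTransport(c(1, 0), c(0.4, 0.7),
                              matrix(1, 2, 2)), "balance")
  res <- solveTransport(1, 1, matrix(0.3, 1, 1))
  expect_equal(res$cost, 0.3)
  # zero-mass rows/columns are passed through untouched
  res2 <- solveTransport(c(0, 1, 0), c(1, 0, 0), matrix(1:9 / 10, 3, 3))
  expect_equal(res2$plan[2, 1], 1)
  expect_equal(sum(res2$plan), 1)
})
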