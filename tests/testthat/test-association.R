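tab4 <- function(bm, bc, nm, nc)
  matrix(c(bm, nm, bc, nc), 2, 2,
         dimnames = list(type = c("beta", "non-beta"),
                         position = c("mantle", "core")))

test_that("contingency table is an exact cross-tabulation", {
  df <- data.frame(
    binary_type = rep(c("beta", "beta", "non-beta", "non-beta"),
                      c(2, 3, 4, 1)),
    position = rep(c("mantle", "core", "mantle", "core"), c(2, 3, 4, 1)))
  expect_identical(buildContingency(df), tab4(2L, 3L, 4L, 1L))
  expect_error(buildContingency(data.frame(binary_type = "beta",
                                           position = NA_character_)),
               "annotated")
  # all-zero table is legal to build but degenerate to test
  empty <- buildContingency(df[0, ])
  expect_equal(sum(empty), 0)
  expect_error(chi2Independence(empty), "degenerate")
})

test_that("chi-square matches hand computation and the closed form", {
  r <- chi2Independence(tab4(10, 10, 10, 10))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # E = 20 in all four cells, sum (O-E)^2/E = 4 * 100/20
  expect_equal(chi2Independence(tab4(30, 10, 10, 30))$statistic, 20)
  # classical 2x2 closed form on random tables
  set.seed(7)
  for (i in 1:100) {
    t <- matrix(rpois(4, 40) + 1, 2)
    a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
    n <- sum(t)
    closed <- (abs(a * d - b * c))^2 * n /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(chi2Independence(t)$statistic, closed, tolerance = 1e-12)
  }
})

test_that("the p value shrinks with sample size at fixed proportions", {
  t1 <- tab4(30, 20, 20, 30)
  t2 <- t1 * 2
  r1 <- chi2Independence(t1)
  r2 <- chi2Independence(t2)
  expect_gt(r2$statistic, r1$statistic)
  expect_lt(r2$p_value, r1$p_value)
  expect_equal(oddsRatio(t1), oddsRatio(t2)) # effect size unchanged
})

test_that("odds ratio arithmetic, orientation and zero handling", {
  expect_equal(oddsRatio(tab4(10, 10, 10, 10)), 1)
  expect_equal(oddsRatio(tab4(5, 20, 20, 5)), 0.0625)
  orZero <- oddsRatio(tab4(0, 20, 20, 5))
  expect_true(is.finite(orZero) && orZero < 1) # Haldane-corrected
  # swap rows and columns together: invariant; swap rows only: reciprocal
  t <- tab4(12, 7, 30, 9)
  expect_equal(oddsRatio(t[2:1, 2:1]), oddsRatio(t))
  expect_equal(oddsRatio(t[2:1, ]), 1 / oddsRatio(t))
})

test_that("odds ratio stays finite at whole-slide cell counts", {
  # cross-products of pooled counts exceed 2^31; must not overflow
  big <- tab4(40000L, 70000L, 65000L, 45000L)
  expect_false(is.na(oddsRatio(big)))
  expect_equal(oddsRatio(big),
               (40000 * 45000) / (70000 * 65000), tolerance = 1e-12)
  draws <- matrix(c(40000L, 65000L, 70000L, 45000L), 4, 1)
  expect_false(anyNA(isletMC:::orFromCounts(draws[1, ], draws[2, ],
                                            draws[3, ], draws[4, ])))
})

test_that("bootstrap OR is deterministic given a seed and covers the point", {
  ann <- annotatedCohort(nIslets = 25, theta = 0.8, seed = 2)
  r1 <- bootstrapOR(ann, nResamples = 200, seed = 11)
  r2 <- bootstrapOR(ann, nResamples = 200, seed = 11)
  expect_identical(r1, r2)
  expect_lte(r1$ci_low, r1$or_median)
  expect_lte(r1$or_median, r1$ci_high)
  # observed OR computed directly from the pooled contingency table
  expect_equal(r1$or_point, oddsRatio(buildContingency(cells(ann))))
  # islet-level cluster bootstrap runs and is deterministic too
  c1 <- bootstrapOR(ann, nResamples = 100, seed = 3, unit = "islets")
  c2 <- bootstrapOR(ann, nResamples = 100, seed = 3, unit = "islets")
  expect_identical(c1, c2)
})

test_that("subgroup analysis yields the nine default groups with consistent recounts", {
  ann <- annotatedCohort(nIslets = 60, theta = 0.8, seed = 6,
                         t1dFraction = 0.5)
  res <- subgroupAnalysis(ann, nResamples = 50, seed = 5)
  expect_equal(nrow(res), 9)
  expect_setequal(
    res$group_label,
    c("all", "all, small", "all, large", "control", "control, small",
      "control, large", "t1d", "t1d, small", "t1d, large"))
  # the identity subgroup equals a direct bootstrap with the same seed
  allRow <- res[res$group_label == "all", ]
  direct <- bootstrapOR(ann, nResamples = 50, seed = allRow$seed,
                        groupLabel = "all")
  expect_equal(allRow[names(direct)], direct)
  # recount: subgroup cell totals respect the disease split
  il <- islets(ann)
  ct <- isletCounts(ann)
  nCtrl <- sum(ct$N[ct$islet_id %in% il$islet_id[il$disease_status == "control"]])
  expect_equal(res$n_cells[res$group_label == "control"], nCtrl)
  expect_equal(res$n_cells[res$group_label == "all"], sum(ct$N))
  # size split partitions the cells
  expect_equal(res$n_cells[res$group_label == "all, small"] +
                 res$n_cells[res$group_label == "all, large"],
               res$n_cells[res$group_label == "all"])
})

test_that("an empty subgroup is flagged, not fatal", {
  ann <- annotatedCohort(nIslets = 10, theta = 0.5, seed = 3) # control only
  res <- subgroupAnalysis(ann, nResamples = 20, seed = 1)
  t1dRows <- res[grepl("^t1d", res$group_label), ]
  expect_true(all(t1dRows$note == "insufficient data"))
  expect_true(all(is.na(t1dRows$or_median)))
  expect_equal(sum(res$note == ""), 6)
})
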