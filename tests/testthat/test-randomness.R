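countsRow <- function(N, NB, M, NB_m)
  data.frame(N = N, NB = NB, B = N - NB, M = M, C = N - M, NB_m = NB_m)

test_that("r value matches enumeration and boundary cases", {
  # N=4, NB=2, M=2, NB_m=2: one of the C(4,2)=6 arrangements
  expect_equal(rValue(countsRow(4, 2, 2, 2)), 1 / 6)
  # nothing observed in the mantle: r = 1
  expect_equal(rValue(countsRow(10, 4, 5, 0)), 1)
  # all-non-beta islet: the configuration is forced
  expect_equal(rValue(countsRow(7, 7, 4, 4)), 1)
  # invalid counts rejected
  expect_error(rValue(countsRow(4, 2, 2, 3)), "invariant")
  expect_error(rValue(data.frame(N = 4, NB = 5, B = -1, M = 2, C = 2,
                                 NB_m = 0)), "non-negative")
})

test_that("r agrees with the brute-force oracle on a small exhaustive grid", {
  for (N in 2:8) {
    for (NB in 0:N) {
      for (M in 0:N) {
        lo <- max(0, NB + M - N)
        hi <- min(NB, M)
        for (nbm in lo:hi) {
          expect_equal(rValue(countsRow(N, NB, M, nbm)),
                       rEnumOracle(N, NB, M, nbm),
                       tolerance = 1e-12,
                       label = sprintf("N=%d NB=%d M=%d NBm=%d", N, NB, M, nbm))
        }
      }
    }
  }
})

test_that("r is non-increasing in the observed non-beta mantle count", {
  for (cfg in list(c(20, 8, 10), c(15, 15, 6), c(30, 5, 25))) {
    N <- cfg[1]; NB <- cfg[2]; M <- cfg[3]
    rng <- max(0, NB + M - N):min(NB, M)
    rs <- rValue(countsRow(N, NB, M, rng))
    expect_true(all(diff(rs) <= 1e-15))
  }
})

test_that("constrained islets are identified with reasons", {
  res <- classifyConstrained(countsRow(7, 7, 4, 4)) # B = 0
  expect_true(res$constrained)
  expect_identical(res$reasons, "too_few_beta")
  expect_false(classifyConstrained(countsRow(6, 3, 3, 1))$constrained)
  res2 <- classifyConstrained(countsRow(20, 10, 18, 9)) # C = 2
  expect_true(res2$constrained)
  expect_identical(res2$reasons, "too_few_core")
  res3 <- classifyConstrained(countsRow(4, 2, 2, 1)) # all three scarce
  expect_identical(res3$reasons, "too_few_beta;too_few_nonbeta;too_few_core")
})

test_that("digital siblings preserve every marginal count", {
  ann <- annotatedCohort(nIslets = 20, theta = 1, seed = 14)
  sib <- digitalSibling(ann, seed = 2)
  a <- isletCounts(ann)
  b <- isletCounts(sib)
  expect_identical(a$islet_id, b$islet_id)
  for (col in c("N", "NB", "B", "M", "C")) expect_equal(a[[col]], b[[col]])
  # geometry untouched
  expect_identical(sib@isletBoundaries, ann@isletBoundaries)
  expect_identical(cells(sib)$position, cells(ann)$position)
  # an islet with a single type is unchanged by permutation
  one <- squareStudy(cellSpec = data.frame(
    x = c(40, 50, 60), y = 50, hormone_class = "beta"))
  one <- annotatePositions(applyStudyFilters(one))
  expect_identical(cells(digitalSibling(one, seed = 1))$binary_type,
                   cells(one)$binary_type)
})

test_that("sibling rearrangements follow the hypergeometric null", {
  # one islet with N=4, NB=2, M=2; law of NB_m is (1/6, 4/6, 1/6)
  spec <- data.frame(x = c(2, 2, 50, 60), y = c(40, 60, 50, 50),
                     hormone_class = c("alpha", "delta", "beta", "beta"))
  one <- annotatePositions(applyStudyFilters(squareStudy(cellSpec = spec)))
  expect_equal(isletCounts(one)$M, 2)
  draws <- vapply(1:4000, function(i)
    isletCounts(digitalSibling(one, seed = i))$NB_m, 0L)
  obs <- tabulate(draws + 1L, 3)
  gof <- chisq.test(obs, p = c(1, 4, 1) / 6)
  expect_gt(gof$p.value, 0.01)
})

test_that("population r tables have the right shape and determinism", {
  ann <- annotatedCohort(nIslets = 30, theta = 0.5, seed = 19)
  obs <- populationRValues(ann)
  expect_equal(nrow(obs), sum(isletCounts(ann)$N > 0))
  expect_true(all(obs$r > 0 & obs$r <= 1))
  s1 <- populationRValues(ann, "siblings", nReplicates = 2, seed = 7)
  s2 <- populationRValues(ann, "siblings", nReplicates = 2, seed = 7)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 2 * nrow(obs))
  # sibling counts preserve the observed margins
  m <- match(s1$islet_id[s1$replicate == 1], obs$islet_id)
  expect_equal(s1$NB[s1$replicate == 1], obs$NB[m])
  expect_equal(s1$M[s1$replicate == 1], obs$M[m])
  # constrained exclusion drops flagged islets only
  uncon <- populationRValues(ann, includeConstrained = FALSE)
  expect_equal(nrow(uncon), sum(!obs$constrained))
})

test_that("sibling r values are superuniform (conservative null tails)", {
  ann <- annotatedCohort(nIslets = 150, theta = 0.8, seed = 23)
  sib <- populationRValues(ann, "siblings", nReplicates = 4, seed = 31,
                           includeConstrained = FALSE)
  n <- nrow(sib)
  for (q in seq(0.05, 0.95, by = 0.05)) {
    se <- sqrt(q * (1 - q) / n)
    expect_lte(mean(sib$r <= q), q + 3 * se)
  }
})
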