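#' @include AllClasses.R mantleCore.R utils.R
NULL

#' Build the type-by-position contingency table
#'
#' Cross-tabulates annotated cells into the 2 x 2 table of binary type
#' (beta / non-beta) by position (mantle / core) that feeds the chi-square
#' test and the odds ratio.
#'
#' @param cellTable a cell data.frame with \code{binary_type} and
#'   \code{position} filled (see \code{\link{annotatePositions}}).
#' @return 2 x 2 integer matrix with rows \code{beta}, \code{non-beta} and
#'   columns \code{mantle}, \code{core}.
#' @examples
#' df <- data.frame(binary_type = c("beta", "beta", "non-beta"),
#'                  position = c("mantle", "core", "mantle"))
#' buildContingency(df)
#' @export
buildContingency <- function(cellTable) {
  if (anyNA(cellTable$binary_type) || anyNA(cellTable$position))
    stop("all cells must be annotated with binary_type and position")
  tab <- table(factor(cellTable$binary_type, levels = c("beta", "non-beta")),
               factor(cellTable$position, levels = c("mantle", "core")))
  m <- matrix(as.integer(tab), 2, 2,
              dimnames = list(type = c("beta", "non-beta"),
                              position = c("mantle", "core")))
  m
}

checkContingency <- function(tab) {
  if (!is.matrix(tab) || any(dim(tab) != 2) || any(tab < 0))
    stop("a contingency table must be a non-negative 2 x 2 matrix")
  tab
}

#' Pearson chi-square test of type/position independence
#'
#' Uncorrected Pearson chi-square test (1 df) on the 2 x 2 table. No
#' continuity correction is applied: the pooled tables here hold tens of
#' thousands of cells, where the correction is immaterial.
#'
#' @param tab a 2 x 2 contingency table (see \code{\link{buildContingency}}).
#' @return list with \code{statistic} and \code{p_value}.
#' @examples
#' chi2Independence(matrix(c(30, 10, 10, 30), 2))$statistic # 20
#' @export
chi2Independence <- function(tab) {
  tab <- checkContingency(tab)
  if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: a zero margin leaves independence untestable")
  ht <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Odds ratio of the type-by-position table
#'
#' Cross-product ratio
#' \deqn{OR = \frac{n_{beta,mantle} \cdot n_{nonbeta,core}}
#'                 {n_{beta,core} \cdot n_{nonbeta,mantle}},}
#' oriented so that OR < 1 means beta cells are depleted from the mantle
#' relative to non-beta cells -- i.e. adherence to the mantle-core
#' hypothesis. When any cell of the table is zero the Haldane-Anscombe
#' correction (+0.5 to every cell) is applied, keeping the ratio finite.
#'
#' @param tab a 2 x 2 contingency table, rows (beta, non-beta), columns
#'   (mantle, core).
#' @return numeric(1), the odds ratio.
#' @examples
#' oddsRatio(matrix(c(5, 20, 20, 5), 2, byrow = TRUE)) # 0.0625
#' @export
oddsRatio <- function(tab) {
  tab <- checkContingency(tab)
  storage.mode(tab) <- "double" # pooled cross-products overflow integers
  if (any(tab == 0)) tab <- tab + 0.5
  (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
}

orFromCounts <- function(bm, bc, nm, nc) {
  # vectorized odds ratio with per-element Haldane correction; doubles
  # because cross-products of pooled counts overflow integers
  bm <- as.double(bm); bc <- as.double(bc)
  nm <- as.double(nm); nc <- as.double(nc)
  zero <- bm == 0 | bc == 0 | nm == 0 | nc == 0
  bm[zero] <- bm[zero] + 0.5
  bc[zero] <- bc[zero] + 0.5
  nm[zero] <- nm[zero] + 0.5
  nc[zero] <- nc[zero] + 0.5
  (bm * nc) / (bc * nm)
}

# per-islet 2x2 cell counts derived from the count table
isletCellQuadrants <- function(ct) {
  bm <- ct$M - ct$NB_m
  data.frame(islet_id = ct$islet_id,
             beta_mantle = bm, beta_core = ct$B - bm,
             nonbeta_mantle = ct$NB_m, nonbeta_core = ct$NB - ct$NB_m)
}

#' Bootstrap odds ratio with percentile confidence interval
#'
#' Resamples the data with replacement \code{nResamples} times (default
#' 500), recomputes the odds ratio on each resample, and reports the median
#' as the point summary with the percentile 95\% interval. The chi-square
#' statistic and p value are computed once on the observed table. The
#' resampling unit is \code{"cells"} by default (each resample redraws
#' cells, equivalently a multinomial redraw of the four table cells); an
#' islet-level cluster bootstrap (\code{unit = "islets"}) is available
#' because cells within an islet are not independent.
#'
#' @param study an annotated \linkS4class{IsletStudy}.
#' @param isletFilter optional logical vector or predicate
#'   \code{function(isletTable)} selecting the islets whose cells form the
#'   group; default all.
#' @param nResamples number of bootstrap resamples.
#' @param seed RNG seed (results are reproducible given the seed).
#' @param unit resampling unit, \code{"cells"} or \code{"islets"}.
#' @param groupLabel label carried into the result row.
#' @return one-row data.frame: \code{group_label}, \code{n_cells},
#'   \code{n_islets}, \code{beta_fraction}, \code{chi2}, \code{p_value},
#'   \code{or_point} (observed), \code{or_median}, \code{ci_low},
#'   \code{ci_high}, \code{n_resamples}, \code{seed}.
#' @seealso \code{\link{subgroupAnalysis}}
#' @export
bootstrapOR <- function(study, isletFilter = NULL, nResamples = NULL,
                        seed = NULL, unit = c("cells", "islets"),
                        groupLabel = "all") {
  unit <- match.arg(unit)
  if (is.null(nResamples)) nResamples <- study@params@nBootstrap
  if (is.null(seed)) seed <- study@params@rngSeed
  ct <- isletCounts(study)
  if (!nrow(ct))
    stop("study has no islet counts; run annotatePositions() first")
  il <- islets(study)
  keep <- if (is.null(isletFilter)) rep(TRUE, nrow(il))
          else if (is.function(isletFilter)) isletFilter(il)
          else as.logical(isletFilter)
  ids <- il$islet_id[keep]
  ct <- ct[ct$islet_id %in% ids, , drop = FALSE]
  quad <- isletCellQuadrants(ct)
  obs <- c(beta_mantle = sum(quad$beta_mantle),
           beta_core = sum(quad$beta_core),
           nonbeta_mantle = sum(quad$nonbeta_mantle),
           nonbeta_core = sum(quad$nonbeta_core))
  n <- sum(obs)
  if (n < 2) stop("group has fewer than 2 cells")
  tab <- matrix(obs, 2, 2, byrow = TRUE,
                dimnames = list(type = c("beta", "non-beta"),
                                position = c("mantle", "core")))
  ht <- chi2Independence(tab)
  orObs <- oddsRatio(tab)
  ors <- withSeed(seed, {
    if (unit == "cells") {
      draws <- stats::rmultinom(nResamples, n, prob = obs / n)
      orFromCounts(draws[1, ], draws[2, ], draws[3, ], draws[4, ])
    } else {
      k <- nrow(quad)
      vapply(seq_len(nResamples), function(i) {
        pick <- sample.int(k, k, replace = TRUE)
        orFromCounts(sum(quad$beta_mantle[pick]), sum(quad$beta_core[pick]),
                     sum(quad$nonbeta_mantle[pick]),
                     sum(quad$nonbeta_core[pick]))
      }, 0)
    }
  })
  qs <- unname(quantile(ors, c(0.025, 0.5, 0.975)))
  data.frame(group_label = groupLabel, n_cells = n, n_islets = nrow(ct),
             beta_fraction = (obs[["beta_mantle"]] + obs[["beta_core"]]) / n,
             chi2 = ht$statistic, p_value = ht$p_value,
             or_point = orObs, or_median = qs[2],
             ci_low = qs[1], ci_high = qs[3],
             n_resamples = nResamples, seed = as.integer(seed),
             stringsAsFactors = FALSE)
}

#' Default nine-subgroup specification
#'
#' The subgroup breakdown crosses disease status \{all, control, t1d\} with
#' islet size \{all sizes, small (< \code{sizeCut} um^2), large (>=
#' \code{sizeCut})\}, giving nine cell groupings. The 10,000 um^2 cut
#' separates the small islets in which beta-cell loss is most marked.
#'
#' @param sizeCut islet-area cut in um^2 (default 10000).
#' @return named list of predicate functions \code{function(isletTable)}
#'   returning a logical islet selector; pass to
#'   \code{\link{subgroupAnalysis}} or replace with your own.
#' @export
defaultSubgroups <- function(sizeCut = 10000) {
  mk <- function(status, size) {
    force(status); force(size)
    function(il) {
      sel <- rep(TRUE, nrow(il))
      if (!is.na(status)) sel <- sel & il$disease_status == status
      if (!is.na(size)) {
        sel <- sel & if (size == "small") il$area_um2 < sizeCut
                     else il$area_um2 >= sizeCut
      }
      sel
    }
  }
  list("all" = mk(NA, NA),
       "all, small" = mk(NA, "small"),
       "all, large" = mk(NA, "large"),
       "control" = mk("control", NA),
       "control, small" = mk("control", "small"),
       "control, large" = mk("control", "large"),
       "t1d" = mk("t1d", NA),
       "t1d, small" = mk("t1d", "small"),
       "t1d, large" = mk("t1d", "large"))
}

#' Subgroup association analysis
#'
#' Runs \code{\link{bootstrapOR}} on each subgroup of a grouping
#' specification (by default the nine-group breakdown of
#' \code{\link{defaultSubgroups}}), with identical resample counts and
#' per-group seeds derived from one master seed. Subgroups left empty by
#' their filter yield a flagged row (\code{note = "insufficient data"})
#' rather than an error.
#'
#' @param study an annotated \linkS4class{IsletStudy}.
#' @param grouping named list of islet predicates, see
#'   \code{\link{defaultSubgroups}}.
#' @param nResamples,seed,unit as in \code{\link{bootstrapOR}}; \code{seed}
#'   is the master seed from which per-group seeds are derived.
#' @return data.frame with one row per subgroup (columns as in
#'   \code{\link{bootstrapOR}} plus \code{note}).
#' @examples
#' cohort <- annotatePositions(applyStudyFilters(generateCohort(
#'   syntheticConfig(nIslets = 40, t1dFraction = 0.5, seed = 3))))
#' res <- subgroupAnalysis(cohort, nResamples = 50, seed = 1)
#' res[, c("group_label", "or_median", "ci_low", "ci_high")]
#' @export
subgroupAnalysis <- function(study, grouping = defaultSubgroups(),
                             nResamples = NULL, seed = NULL,
                             unit = "cells") {
  if (is.null(seed)) seed <- study@params@rngSeed
  seeds <- deriveSeeds(seed, length(grouping))
  rows <- lapply(seq_along(grouping), function(i) {
    res <- tryCatch(
      cbind(bootstrapOR(study, isletFilter = grouping[[i]],
                        nResamples = nResamples, seed = seeds[i],
                        unit = unit, groupLabel = names(grouping)[i]),
            note = ""),
      error = function(e) data.frame(
        group_label = names(grouping)[i], n_cells = 0L, n_islets = 0L,
        beta_fraction = NA_real_, chi2 = NA_real_, p_value = NA_real_,
        or_point = NA_real_, or_median = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, n_resamples = nResamples %||% NA_integer_,
        seed = seeds[i], note = "insufficient data",
        stringsAsFactors = FALSE))
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
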