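#' @include AllClasses.R mantleCore.R utils.R
NULL

checkCounts <- function(counts) {
  req <- c("N", "NB", "B", "M", "C", "NB_m")
  if (!all(req %in% names(counts)))
    stop("counts must have columns ", paste(req, collapse = ", "))
  with(counts, {
    if (any(N < 0 | NB < 0 | B < 0 | M < 0 | C < 0 | NB_m < 0))
      stop("counts must be non-negative")
    if (any(N != NB + B)) stop("invariant violated: N = NB + B")
    if (any(N != M + C)) stop("invariant violated: N = M + C")
    if (any(NB_m > pmin(NB, M)))
      stop("invariant violated: NB_m <= min(NB, M)")
    if (any(NB_m < pmax(0, NB + M - N)))
      stop("invariant violated: NB_m >= max(0, NB + M - N)")
  })
  counts
}

#' Per-islet randomness probability r
#'
#' The probability that at least the observed number of non-beta cells
#' occupies mantle positions when the islet's fixed multiset of cell types
#' is arranged uniformly at random over its fixed positions. Under that
#' null the number of non-beta mantle cells follows the hypergeometric law
#' of drawing the M mantle positions from N cells of which NB are non-beta:
#' \deqn{r = P(X \ge NB_m) = \sum_{k = NB_m}^{\min(NB, M)}
#'       \binom{NB}{k}\binom{N - NB}{M - k} / \binom{N}{M}.}
#' Values near 1 indicate an arrangement compatible with randomness; small
#' values are evidence of a mantle-core structure. \eqn{r = 1} exactly
#' whenever \eqn{NB_m = 0} or the configuration is forced (e.g. an islet
#' containing only non-beta cells admits a single arrangement).
#'
#' The tail is evaluated exactly via the log-space hypergeometric
#' distribution function, so it is stable for islets with thousands of
#' cells.
#'
#' @param counts data.frame of islet counts with columns \code{N},
#'   \code{NB}, \code{B}, \code{M}, \code{C}, \code{NB_m} (one row per
#'   islet), as produced by \code{\link{isletCounts}}.
#' @return numeric vector of r values in (0, 1].
#' @examples
#' rValue(data.frame(N = 4, NB = 2, B = 2, M = 2, C = 2, NB_m = 2)) # 1/6
#' @seealso \code{\link{populationRValues}}, \code{\link{classifyConstrained}}
#' @export
rValue <- function(counts) {
  counts <- checkCounts(counts)
  stats::phyper(counts$NB_m - 1, counts$NB, counts$B, counts$M,
                lower.tail = FALSE)
}

#' Constrained-islet classification
#'
#' An islet is constrained -- unable to meaningfully exhibit a mantle-core
#' structure -- when it has fewer than three beta cells, fewer than three
#' non-beta cells, or fewer than three core positions.
#'
#' @inheritParams rValue
#' @return data.frame with logical \code{constrained} and a \code{reasons}
#'   string joining the failing conditions (\code{too_few_beta},
#'   \code{too_few_nonbeta}, \code{too_few_core}) with ";".
#' @examples
#' classifyConstrained(data.frame(N = 7, NB = 7, B = 0, M = 4, C = 3,
#'                                NB_m = 4))
#' @export
classifyConstrained <- function(counts) {
  counts <- checkCounts(counts)
  reasons <- mapply(function(b, nb, co) {
    r <- c(if (b < 3) "too_few_beta",
           if (nb < 3) "too_few_nonbeta",
           if (co < 3) "too_few_core")
    paste(r, collapse = ";")
  }, counts$B, counts$NB, counts$C)
  data.frame(constrained = counts$B < 3 | counts$NB < 3 | counts$C < 3,
             reasons = unname(reasons), stringsAsFactors = FALSE)
}

#' Digital sibling of a study
#'
#' Creates the label-permutation null copy of every islet: geometry,
#' positions and the per-islet multiset of cell identities are retained,
#' but the identities are reallocated uniformly at random over the islet's
#' cell positions. Each islet's counts N, NB, B, M and C are unchanged by
#' construction; only \code{NB_m} (and hence r) is redrawn. Hormone classes
#' travel with their binary type so the sibling remains a valid study.
#'
#' @param study an annotated \linkS4class{IsletStudy}.
#' @param seed RNG seed.
#' @return an \linkS4class{IsletStudy}, the digital-sibling population.
#' @seealso \code{\link{populationRValues}}
#' @export
digitalSibling <- function(study, seed = NULL) {
  if (is.null(seed)) seed <- study@params@rngSeed
  cl <- study@cells
  if (nrow(cl) && (anyNA(cl$position) || anyNA(cl$binary_type)))
    stop("study must be annotated before building digital siblings")
  withSeed(seed, {
    grp <- split(seq_len(nrow(cl)), cl$islet_id)
    for (idx in grp) {
      perm <- if (length(idx) > 1) idx[sample.int(length(idx))] else idx
      cl$hormone_class[idx] <- cl$hormone_class[perm]
      cl$binary_type[idx] <- cl$binary_type[perm]
    }
  })
  study@cells <- cl
  study@counts <- if (nrow(cl)) countsFromCells(cl) else emptyCountTable()
  study@provenance$sibling <- list(seed = as.integer(seed))
  study
}

# Count-level digital sibling: draw a uniform arrangement of each islet's
# type multiset over its positions and count non-beta cells landing in the
# mantle. Identical in law to permuting the labels cell by cell (and to the
# hypergeometric distribution), without touching cell-level tables.
siblingNBm <- function(counts) {
  mapply(function(n, nb, m) {
    if (m == 0L || nb == 0L) return(0L)
    sum(sample.int(n, m) <= nb)
  }, counts$N, counts$NB, counts$M)
}

#' Population r values for observed islets or digital siblings
#'
#' Scores every non-empty islet with its randomness probability r --- either
#' as observed, or for \code{nReplicates} independent digital-sibling
#' rearrangements per islet --- and flags constrained islets. Both the full
#' table and the unconstrained subset are of interest downstream; use
#' \code{constrained} to subset.
#'
#' @param study an annotated \linkS4class{IsletStudy}.
#' @param which \code{"observed"} or \code{"siblings"}.
#' @param nReplicates sibling rearrangements per islet (siblings only).
#' @param seed RNG seed (siblings only).
#' @param includeConstrained keep constrained islets in the returned table
#'   (default TRUE; they are flagged either way).
#' @return data.frame with columns \code{islet_id}, \code{replicate},
#'   \code{N}, \code{NB}, \code{B}, \code{M}, \code{C}, \code{NB_m},
#'   \code{r}, \code{constrained}, \code{reasons}.
#' @examples
#' cohort <- annotatePositions(applyStudyFilters(generateCohort(
#'   syntheticConfig(nIslets = 20, seed = 11))))
#' obs <- populationRValues(cohort)
#' sib <- populationRValues(cohort, which = "siblings", seed = 5)
#' mean(obs$r) < mean(sib$r) # adherent cohorts concentrate at low r
#' @export
populationRValues <- function(study, which = c("observed", "siblings"),
                              nReplicates = 1L, seed = NULL,
                              includeConstrained = TRUE) {
  which <- match.arg(which)
  ct <- isletCounts(study)
  if (!nrow(ct))
    stop("study has no islet counts; run annotatePositions() first")
  ct <- ct[ct$N > 0, , drop = FALSE] # empty (flagged) islets are skipped
  flags <- classifyConstrained(ct)
  build <- function(counts, rep) {
    data.frame(islet_id = counts$islet_id, replicate = rep,
               counts[, c("N", "NB", "B", "M", "C", "NB_m")],
               r = rValue(counts), flags, stringsAsFactors = FALSE)
  }
  if (which == "observed") {
    out <- build(ct, 0L)
  } else {
    if (is.null(seed)) seed <- study@params@rngSeed
    seeds <- deriveSeeds(seed, nReplicates)
    out <- do.call(rbind, lapply(seq_len(nReplicates), function(i) {
      sib <- ct
      sib$NB_m <- withSeed(seeds[i], siblingNBm(ct))
      build(sib, i)
    }))
  }
  if (!includeConstrained) out <- out[!out$constrained, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export an r-value table
#'
#' @param rTable a table from \code{\link{populationRValues}}.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeRValues <- function(rTable, path) {
  write.csv(rTable, path, row.names = FALSE)
  invisible(path)
}
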