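#' @include AllClasses.R transport.R utils.R
NULL

#' Bin values into an equidistant histogram on [0, 1]
#'
#' Bins are half-open \code{[a, b)} with the last bin closed on the right,
#' so a value of exactly 1 (e.g. r = 1, a fully random-compatible islet) is
#' counted in the top bin.
#'
#' @param values numeric vector in [0, 1]; must be non-empty.
#' @param nBins number of equidistant bins (>= 2), default 20.
#' @return a \linkS4class{Histogram1D}.
#' @examples
#' h <- histogram1D(c(0.05, 0.5, 1, 1), nBins = 10)
#' binMass(h)
#' @export
histogram1D <- function(values, nBins = 20L) {
  if (!length(values)) stop("values must be non-empty")
  if (anyNA(values) || any(values < 0 | values > 1))
    stop("values must lie in [0, 1]")
  nBins <- as.integer(nBins)
  if (nBins < 2) stop("nBins must be at least 2")
  idx <- pmin(floor(values * nBins) + 1L, nBins)
  mass <- tabulate(idx, nbins = nBins) / length(values)
  new("Histogram1D", breaks = seq(0, 1, length.out = nBins + 1L),
      mass = mass, nSamples = length(values))
}

#' Bin paired values into an equidistant 2D histogram
#'
#' Both axes are binned on [0, 1] with half-open bins, the top bin closed.
#' For islet data the x axis is the beta cell fraction and the y axis the
#' islet area rescaled by \code{areaScale} (the pooled maximum), recorded in
#' the result so two histograms built with the same scale are comparable.
#'
#' @param x,y numeric vectors in [0, 1] of equal length.
#' @param nBins bins per axis (>= 2), default 20.
#' @param areaScale optional scale (um^2) used to normalize the y axis.
#' @return a \linkS4class{Histogram2D}.
#' @export
histogram2D <- function(x, y, nBins = 20L, areaScale = NA_real_) {
  if (!length(x) || length(x) != length(y))
    stop("x and y must be non-empty and of equal length")
  if (any(c(x, y) < 0 | c(x, y) > 1) || anyNA(c(x, y)))
    stop("values must lie in [0, 1]")
  nBins <- as.integer(nBins)
  if (nBins < 2) stop("nBins must be at least 2")
  ix <- pmin(floor(x * nBins) + 1L, nBins)
  iy <- pmin(floor(y * nBins) + 1L, nBins)
  mass <- matrix(tabulate((iy - 1L) * nBins + ix, nbins = nBins * nBins),
                 nBins, nBins) / length(x)
  new("Histogram2D", xBreaks = seq(0, 1, length.out = nBins + 1L),
      yBreaks = seq(0, 1, length.out = nBins + 1L), mass = mass,
      nSamples = length(x), areaScale = areaScale)
}

binCenters <- function(breaks) (breaks[-1] + breaks[-length(breaks)]) / 2

#' Normalized 1D earth mover's distance
#'
#' Optimal-transport distance between two histograms on identical
#' equidistant bins. The ground distance between bins i and j is
#' \code{|center_i - center_j|} divided by the distance between the two
#' extreme bin centers, so the distance is 0 for identical histograms and
#' exactly 1 when all mass must travel from one extreme bin to the other.
#' The optimal plan is the monotone (CDF-matching) coupling, provably
#' optimal for convex ground costs in one dimension; the distance equals
#' the closed form \eqn{\sum_k |P_k - Q_k| / (K - 1)} over the K - 1 inner
#' cumulative sums.
#'
#' @param source,target \linkS4class{Histogram1D} objects on identical
#'   bins. Conventionally the source is the digital-sibling population and
#'   the target the observed islets, so the plan reads as "how the sibling
#'   r values must be redistributed to recreate the observed ones".
#' @return an \linkS4class{EMDResult}.
#' @examples
#' a <- histogram1D(rep(0.01, 5), nBins = 20)
#' b <- histogram1D(rep(0.99, 5), nBins = 20)
#' emdDistance(emd1D(a, b)) # 1
#' @seealso \code{\link{emd2D}}, \code{\link{solveTransport}}
#' @export
emd1D <- function(source, target) {
  stopifnot(is(source, "Histogram1D"), is(target, "Histogram1D"))
  if (length(source@breaks) != length(target@breaks) ||
      max(abs(source@breaks - target@breaks)) > 1e-12)
    stop("histograms must share identical bin edges")
  p <- source@mass
  q <- target@mass
  k <- length(p)
  centers <- binCenters(source@breaks)
  scale <- centers[k] - centers[1]
  cost <- abs(outer(centers, centers, `-`)) / scale
  distance <- sum(abs(cumsum(p - q)[-k])) / (k - 1)
  # monotone two-pointer coupling
  plan <- matrix(0, k, k)
  i <- 1L; j <- 1L
  a <- p[1]; b <- q[1]
  while (i <= k && j <= k) {
    t <- min(a, b)
    if (t > 0) plan[i, j] <- plan[i, j] + t
    a <- a - t
    b <- b - t
    if (a <= b && i < k) { i <- i + 1L; a <- a + p[i] }
    else if (j < k) { j <- j + 1L; b <- b + q[j] }
    else if (i < k) { i <- i + 1L; a <- a + p[i] }
    else break
  }
  # guard against accumulated rounding in the marginals
  planCost <- sum(plan * cost)
  if (abs(planCost - distance) > 1e-9)
    stop("internal error: monotone plan cost disagrees with CDF closed form")
  new("EMDResult", distance = distance, plan = plan, cost = cost,
      sourceMass = p, targetMass = q,
      normalization = list(
        label = "1D |bin centre difference| / extreme-centre range",
        scale = scale, bins = k))
}

#' Normalized 2D earth mover's distance
#'
#' Exact optimal-transport distance between two 2D histograms with
#' identical bin geometry, computed by linear programming
#' (\code{\link{solveTransport}}) on the bin centers. The ground distance
#' is the per-axis-normalized L1 metric
#' \code{|dx|/xrange + |dy|/yrange} (ranges between extreme bin centers),
#' the metric under which moving all mass between opposite corners costs
#' exactly 2 -- one unit of work per axis. An L2 (Euclidean on the
#' normalized axes) alternative is available via \code{groundMetric}.
#'
#' @param source,target \linkS4class{Histogram2D} objects with identical
#'   bin geometry.
#' @param groundMetric \code{"L1"} (default) or \code{"L2"}.
#' @return an \linkS4class{EMDResult}; plan and cost matrices are indexed
#'   by flattened bins (x fastest, column-major).
#' @examples
#' a <- histogram2D(0.01, 0.01, nBins = 4)
#' b <- histogram2D(0.99, 0.99, nBins = 4)
#' emdDistance(emd2D(a, b)) # 2
#' @export
emd2D <- function(source, target, groundMetric = c("L1", "L2")) {
  groundMetric <- match.arg(groundMetric)
  stopifnot(is(source, "Histogram2D"), is(target, "Histogram2D"))
  if (length(source@xBreaks) != length(target@xBreaks) ||
      length(source@yBreaks) != length(target@yBreaks) ||
      max(abs(source@xBreaks - target@xBreaks)) > 1e-12 ||
      max(abs(source@yBreaks - target@yBreaks)) > 1e-12)
    stop("histograms must share identical bin geometry")
  cx <- binCenters(source@xBreaks)
  cy <- binCenters(source@yBreaks)
  grid <- expand.grid(x = cx, y = cy) # x fastest: matches column-major flatten
  dx <- abs(outer(grid$x, grid$x, `-`)) / (cx[length(cx)] - cx[1])
  dy <- abs(outer(grid$y, grid$y, `-`)) / (cy[length(cy)] - cy[1])
  cost <- if (groundMetric == "L1") dx + dy else sqrt(dx^2 + dy^2)
  p <- as.vector(source@mass)
  q <- as.vector(target@mass)
  sol <- solveTransport(p, q, cost)
  new("EMDResult", distance = sol$cost, plan = sol$plan, cost = cost,
      sourceMass = p, targetMass = q,
      normalization = list(
        label = paste0("2D per-axis-normalized ", groundMetric,
                       " on bin centres (corner-to-corner = 2)"),
        bins = c(length(cx), length(cy)), metric = groundMetric))
}

#' Robustness of the 1D EMD to resampling and bin count
#'
#' Two diagnostics for the observed-vs-sibling comparison: (a) the
#' distribution of the EMD when the sibling population is re-randomized
#' \code{nResamples} times at the default bin count, and (b) the EMD as a
#' function of the number of equidistant bins for one fixed sibling draw.
#' Deterministic given \code{seed}.
#'
#' @param observedR numeric vector of observed r values in [0, 1].
#' @param siblingGenerator function() returning one freshly randomized
#'   sibling r-value vector (e.g. wrapping
#'   \code{\link{populationRValues}}).
#' @param binCounts integer vector of bin counts to sweep (default 8:40).
#' @param nResamples number of sibling re-randomizations (default 500).
#' @param nBins default bin count for the resampling arm (default 20).
#' @param seed RNG seed.
#' @return list with data.frames \code{resamples} (resample, emd) and
#'   \code{binSweep} (n_bins, emd).
#' @export
robustness1D <- function(observedR, siblingGenerator, binCounts = 8:40,
                         nResamples = 500L, nBins = 20L, seed = 1L) {
  if (!length(observedR)) stop("observedR must be non-empty")
  withSeed(seed, {
    obsH <- histogram1D(observedR, nBins)
    emds <- vapply(seq_len(nResamples), function(i) {
      sib <- siblingGenerator()
      emdDistance(emd1D(histogram1D(sib, nBins), obsH))
    }, 0)
    fixedSib <- siblingGenerator()
    sweep <- vapply(binCounts, function(k)
      emdDistance(emd1D(histogram1D(fixedSib, k),
                        histogram1D(observedR, k))), 0)
    list(resamples = data.frame(resample = seq_len(nResamples), emd = emds),
         binSweep = data.frame(n_bins = as.integer(binCounts), emd = sweep))
  })
}

#' Cohort 2D histograms of beta fraction versus islet area
#'
#' Builds the per-cohort joint distribution of islets over (beta cell
#' fraction B/N, islet area). The area axis is rescaled linearly by the
#' pooled maximum area so both cohorts share bin geometry; a log-area
#' variant is available since small islets dominate counts.
#'
#' @param study an annotated \linkS4class{IsletStudy} containing both a
#'   control and a t1d cohort.
#' @param binsPerAxis bins per axis (default 20).
#' @param logArea use log10(area) before rescaling (default FALSE).
#' @return list with \code{control} and \code{t1d}
#'   \linkS4class{Histogram2D} objects sharing geometry and area scale.
#' @export
cohortHistograms <- function(study, binsPerAxis = 20L, logArea = FALSE) {
  ct <- isletCounts(study)
  if (!nrow(ct))
    stop("study has no islet counts; run annotatePositions() first")
  ct <- ct[ct$N > 0, , drop = FALSE]
  il <- islets(study)
  m <- match(ct$islet_id, il$islet_id)
  status <- il$disease_status[m]
  area <- il$area_um2[m]
  if (logArea) area <- log10(area)
  frac <- ct$B / ct$N
  out <- list()
  scale <- max(area)
  lo <- if (logArea) min(area) else 0
  ynorm <- if (scale > lo) (area - lo) / (scale - lo) else rep(0.5, length(area))
  for (grp in c("control", "t1d")) {
    sel <- status == grp
    if (!any(sel))
      stop("cohort '", grp, "' has zero islets")
    out[[grp]] <- histogram2D(frac[sel], ynorm[sel],
                              nBins = binsPerAxis, areaScale = scale)
  }
  out
}

#' Robustness of the 2D cohort EMD
#'
#' As \code{\link{robustness1D}}, for the control-vs-t1d comparison:
#' (a) EMD distribution under islet-level resampling with replacement
#' within each cohort at the default bin count, and (b) the EMD over a
#' sweep of bin counts (default 8 to 40). Deterministic given \code{seed}.
#'
#' @param study an annotated \linkS4class{IsletStudy} with both cohorts.
#' @param binCounts bin counts to sweep (default 8:40).
#' @param nResamples islet resamples (default 500).
#' @param nBins default bin count for the resampling arm (default 20).
#' @param seed RNG seed.
#' @param logArea passed to \code{\link{cohortHistograms}}.
#' @return list with data.frames \code{resamples} and \code{binSweep}.
#' @export
robustness2D <- function(study, binCounts = 8:40, nResamples = 500L,
                         nBins = 20L, seed = 1L, logArea = FALSE) {
  ct <- isletCounts(study)
  ct <- ct[ct$N > 0, , drop = FALSE]
  il <- islets(study)
  m <- match(ct$islet_id, il$islet_id)
  status <- il$disease_status[m]
  area0 <- il$area_um2[m]
  area <- if (logArea) log10(area0) else area0
  frac <- ct$B / ct$N
  scale <- max(area)
  lo <- if (logArea) min(area) else 0
  ynorm <- (area - lo) / (scale - lo)
  mkH <- function(sel, k) histogram2D(frac[sel], ynorm[sel], nBins = k,
                                      areaScale = scale)
  ctrl <- which(status == "control")
  t1d <- which(status == "t1d")
  if (!length(ctrl) || !length(t1d))
    stop("both cohorts must be present")
  withSeed(seed, {
    emds <- vapply(seq_len(nResamples), function(i) {
      rc <- ctrl[sample.int(length(ctrl), replace = TRUE)]
      rt <- t1d[sample.int(length(t1d), replace = TRUE)]
      emdDistance(emd2D(mkH(rc, nBins), mkH(rt, nBins)))
    }, 0)
    sweep <- vapply(binCounts, function(k)
      emdDistance(emd2D(mkH(ctrl, k), mkH(t1d, k))), 0)
    list(resamples = data.frame(resample = seq_len(nResamples), emd = emds),
         binSweep = data.frame(n_bins = as.integer(binCounts), emd = sweep))
  })
}
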