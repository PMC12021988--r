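# isletMC

Quantitative analysis of **mantle–core (M-C) architecture** in pancreatic
islets of Langerhans, working from the detection exports of whole-slide
image analysis (QuPath-style GeoJSON or tabular files) rather than from
images.

Human islets contain insulin-producing beta cells and non-beta endocrine
cells (alpha, delta, gamma, epsilon). Whether non-beta cells preferentially
form a peripheral *mantle* around a beta-rich *core* — and whether that
organisation survives type 1 diabetes — is a quantitative question about
cell positions. isletMC answers it with three linked analyses:

1. **Type/position association.** Each cell is labelled *mantle* if the
   minimal distance between its nuclear boundary and the islet boundary is
   strictly below d_min = 8 µm, else *core*. The pooled 2×2 table of binary
   type (beta / non-beta) by position is tested with Pearson's χ² (1 df),
   and the effect size is the odds ratio
   `OR = (n_beta,mantle · n_nonbeta,core) / (n_beta,core · n_nonbeta,mantle)`,
   oriented so OR < 1 means beta cells are depleted from the mantle.
   95% CIs come from a 500-resample bootstrap (median + percentile bounds),
   repeated over nine subgroups of disease status × islet size.
2. **Per-islet randomness probability.** Each islet with N cells, NB
   non-beta, M mantle positions and NB_m observed non-beta mantle cells is
   scored with the hypergeometric tail
   `r = P(X ≥ NB_m)`, `X ~ Hypergeom(N, NB, M)` — the probability that at
   least the observed mantle occupancy arises from a uniformly random
   arrangement. The empirical null is a population of **digital siblings**:
   copies of each islet with identical geometry and type counts but labels
   permuted at random. Islets with fewer than three beta cells, non-beta
   cells or core positions are flagged *constrained* and set aside.
3. **Distribution comparison by earth mover's distance.** Observed and
   sibling r distributions are compared with a normalized 1D EMD
   (0 = identical, 1 = all mass moved between extreme bins), with the
   transport plan showing *where* the mass moves; control and t1d cohorts
   are compared with a normalized 2D EMD on (beta fraction × islet area)
   (per-axis-normalized L1 ground metric, corner-to-corner cost exactly 2),
   solved exactly by an in-package transportation simplex.

A synthetic cohort generator with a tunable adherence parameter θ ∈ [0, 1]
(θ = 0: random arrangements; θ = 1: perfect mantle-core ordering) provides
ground-truth data at whole-slide scale for calibration and testing.

## Worked example

```r
library(isletMC)

cfg    <- syntheticConfig(nIslets = 300, theta = 0.8, t1dFraction = 0.5, seed = 42)
cohort <- generateCohort(cfg)
study  <- annotatePositions(applyStudyFilters(cohort))
study
#> IsletStudy with 300 islets and 20340 cells
#>   cohorts: control=150, t1d=150
#>   hormone classes: alpha=6614, beta=10907, delta=1916, epsilon=193, gamma=710
#>   filtered: TRUE | positions annotated: TRUE
#>   params: dMin = 8 um, minIsletArea = 1000 um^2

buildContingency(cells(study))
#>           position
#> type       mantle core
#>   beta       1062 9845
#>   non-beta   3717 5716

res <- bootstrapOR(study, nResamples = 500, seed = 1)
#> chi2 = 2476.8, p = 0, OR = 0.165 [0.153, 0.180]
```

The odds ratio far below 1 says non-beta cells are strongly enriched at the
mantle — as expected for a cohort generated with θ = 0.8. At islet level:

```r
obs <- populationRValues(study, includeConstrained = FALSE)
sib <- populationRValues(study, "siblings", seed = 2, includeConstrained = FALSE)
#> unconstrained islets: 271 of 300
emdDistance(emd1D(histogram1D(sib$r, 20), histogram1D(obs$r, 20)))
#> 0.4803
hs <- cohortHistograms(study, binsPerAxis = 20)
emdDistance(emd2D(hs$control, hs$t1d))
#> 0.4688
```

The 1D EMD of 0.48 quantifies how far the observed r distribution (a sharp
peak at small r) sits from its permutation null; the 2D EMD of 0.47
measures the control-vs-t1d shift in (beta fraction, area), driven by
beta-cell depletion in small t1d islets. `runPipeline()` wraps the whole
chain — ingest/generate, filter, annotate, all three analyses — into one
seeded run with CSV/JSON outputs and a manifest;
`inst/scripts/islet-mc.R` exposes it on the command line.

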