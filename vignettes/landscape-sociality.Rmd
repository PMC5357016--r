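---
title: "Linking landscape structure to animal social networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking landscape structure to animal social networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socioscape)
```

This vignette is the package's own account of the models it implements,
the choices that were genuinely open, and what its validation does and does
not establish.

## The scientific problem

Female white-tailed deer live in matrilineal social groups; contacts
*between* neighbouring groups are rare but epidemiologically decisive,
because they are the route by which an infection crosses the landscape.
The question the pipeline addresses is whether landscape composition
(how much forest, agriculture, forest–agriculture edge) and landscape
connectivity (how easily a moving animal traverses each cover type)
explain variation in sociality, at two levels: individual animals within a
network (local) and whole networks compared across study areas (global).

## Proximity-based association

Two collars are *simultaneous* when their fix timestamps differ by at most
3 minutes, and *associated* when additionally the fixes are within 25 m.
The association rate of a dyad is associated/simultaneous fixes. Both
thresholds are configurable but default to the standard values for
2-hourly deer collars; with one fix every 2 hours a fully monitored
gestation season (134 days) yields at most 1608 simultaneous fixes, so the
smallest nonzero rate observable is 1/1608 ≈ 0.00062 — which is why
zero-rate dyads in local networks are carried at the nominal weight 10⁻⁵,
safely below any real signal.

Simultaneity pairing is greedy chronological nearest-time matching with
ties broken toward the earlier candidate. The matching algorithm behind
the published deer analyses is not documented; greedy matching is our
explicit stand-in. It is deterministic, uses each fix at most once, and on
schedule-plus-jitter data (the regime collars actually produce) it
coincides with the optimal assignment, which the test suite verifies by
exhaustive search on small instances.

Two diagnostics guard data sufficiency: subsampling curves (does the mean
rate at *n* subsampled fixes fall within the rate implied by ±1 full-season
association?) and bi-monthly bias (is a 2-month block's rate offset from
the season's?). These motivate the default filter: keep dyads with ≥600
simultaneous fixes and positive home-range overlap.

## Home ranges and overlap

Utilization distributions are bivariate Gaussian kernel density estimates
with the pooled-axis reference bandwidth h = σ·n^(−1/6),
σ² = (var(x)+var(y))/2. The reference rule is stated in several forms in
the literature; this is the standard bivariate version. Home ranges are
95% isopleths: cells accumulated in decreasing density order (row-major
tie-break) until 0.95 of the mass is contained — the minimal such superset.

Two overlap indices serve different roles. PHR, the integral of animal
*i*'s UD over animal *j*'s isopleth, is directional and answers "how much
of *i*'s time is spent where *j* lives"; its neighbour-average is the
local-model predictor. VI = ∫ min(UD_i, UD_j) is symmetric, 0 for disjoint
and 1 for identical distributions, and controls for space sharing in the
global analysis. VI is computed over the **full** UDs by default although
it is often described alongside "95% UDs": the cited index is defined on
full distributions, and truncation is available via the `p` argument for
sensitivity analysis. Both indices are fit on the common monitoring window
of the pair.

## Circuit-theory connectivity

Each binary cover layer becomes a conductance surface (presence 101,
absence 1). Cells are nodes of an 8-neighbour lattice; edge conductance is
the arithmetic mean of the two cell conductances, with diagonal edges
divided by √2 for their longer span. The external tool used in the
published workflow does not document its neighbour scheme; these
conventions are therefore stated assumptions, validated against analytic
circuits (series strips, the 2×2 lattice with effective resistance 2−√2)
and a dense direct solve rather than against that tool.

For omnidirectional connectivity, sites ring the perimeter of the buffered
study region (50 sites at 3.6 km spacing for a 30 km square with a 7.5 km
buffer), a unit current is passed between every site pair, per-cell
currents (half the sum of absolute incident edge currents; the full sum,
equal to the injected unit, at the two terminals) are summed over pairs,
and the buffer is clipped from the result so current inflated by arbitrary
site placement is discarded. Pair maps are summed, not averaged; since
downstream regressions standardize predictors, the distinction is
immaterial and is recorded in the map metadata (`n_site_pairs`).

Numerically, the grounded graph Laplacian is factorized once per scene
(sparse Cholesky) and reused across all site pairs. A direct solve was
preferred over an iterative one: it is exact to machine precision,
deterministic, and at the package's raster sizes (hundreds of cells per
side) faster than preconditioned iteration. Reciprocity, Kirchhoff
conservation and invariance under global conductance scaling are enforced
by tests.

## Network metrics

Local sociality is the **average weighted degree**: the mean weight of a
node's incident edges. Unlike degree or summed weighted degree it does not
grow mechanically with the number of neighbours that happened to be
collared. Zero-rate dyads (shared space, no simultaneous proximity) are
included at weight 10⁻⁵.

Global sociality is **weighted closeness** C(i) = Σ_j 1/d_ij, where d_ij
is the Dijkstra shortest path with edge cost 1/weight, so strong ties make
short paths, and unreachable nodes contribute 0. Closeness depends on
network size, so networks are compared through exhaustive 4-node
subsampling: the mean node closeness of every `choose(n, 4)` induced
subgraph (isolated nodes counting 0), averaged over subgraphs. With at
most 13 nodes in scope the enumeration (≤715 subsets) is exact; a guard
errors beyond 10⁶ subsets.

Global edges are weighted by standardized residuals of the pooled
regression log(rate) ~ VI, isolating sociality beyond what space sharing
predicts. (The published description is internally inconsistent about
which variable is logged; we follow the main-text and scatter-plot form,
log association rate on overlap.) Standardized residuals can be negative,
which shortest paths cannot accept; the published account is silent on
this, so the package shifts weights by −min + 0.01 to strict positivity.
The shift affects absolute closeness values, not their rank order, and is
an explicit, configurable assumption (`eps`). Zero-rate dyads are excluded
entirely from global networks — no 10⁻⁵ substitution — because a nominal
edge would alter shortest paths.

## The statistical layer

The local response (average weighted degree) is Box-Cox transformed;
λ is estimated from the data by profile likelihood over a −2…2 grid
(step 0.01) by default, with any fixed value (e.g. the published λ = 0.22)
available as an override. The candidate set contains 14 models: null, each
of the six landscape variables alone, home-range overlap alone, and each
landscape variable with overlap. Landscape variables never co-occur in one
model because they are mutually correlated (|Pearson r| > 0.5 screening).
Parameter counts include intercept, slopes and the error variance, so the
null model has k = 2 and a two-predictor model k = 4. Models are ranked by
AICc; Akaike weights normalize the evidence; the top set is Δ < 2.

Model averaging defaults to the *conditional* form — weights renormalized
over the models containing a variable — with full-set zero-substitution
available via `method = "full"`. The published tables are compatible with
either; conditional is the form consistent with reporting per-variable
confidence intervals next to relative importance (the unrenormalized
weight sum). Significance of top models is assessed by permuting the
response 9999 times and asking whether the observed F exceeds the 95th
percentile of the permuted distribution (strict exceedance). The global
analysis, with only one observation per network, uses univariate
regressions of subset-normalised closeness on each z-scored landscape
variable, compared by R².

## The synthetic-data generator

With no public telemetry deposited, the generator supplies data whose
ground truth is known by construction:

* **Landscape** — a Gaussian white-noise field smoothed by circular
  convolution (autocorrelation length = `patch_scale`, default 300 m) and
  thresholded at class-mix quantiles, so realized class proportions match
  targets to within one cell. Default scene: 6 × 6 km of 30 m cells,
  mirroring the cover classes of the Illinois study areas.
* **Movement** — discrete-time mean-reverting (Ornstein–Uhlenbeck-style)
  steps toward per-animal activity centres, arranged as social groups
  (default 4 groups of 2, centres 1500 m apart, individual centres 250 m
  off the group centre, pull 0.3 per step, step SD 75 m). Movement is not
  landscape-responsive by default; an optional mode biases steps toward
  high-value raster cells so landscape-coupled sociality scenarios can be
  synthesized.
* **Association** — rather than hoping sociality emerges from a movement
  model (with unknown true rates), meetings are *scheduled*: each dyad
  receives exactly `round(rate × n_slots)` meeting slots, drawn uniformly
  among slots where both animals are free, at which one animal is placed
  beside the other. Groupmates meet at `within_group_cohesion` (0.2),
  rook-adjacent groups at `between_group_rate` (0.02), non-adjacent groups
  never. The configured rates *are* the ground truth table.
* **Observation** — 2-hourly fixes with Gaussian time jitter (SD 60 s,
  kept well inside the 3-minute matching window), isotropic position error
  scaled to an 8.8 m median displacement (the published closed-canopy
  collar error), and optional fix loss.

Defaults were chosen once to represent the study conditions: a 134-day
monitoring span reproduces the gestation season's 1608 scheduled fixes;
rates, spacings and error magnitudes are either the published values or
field-plausible round numbers.

What end-to-end validation shows: estimated rates regress on configured
rates with slope ≈ 0.93–0.94 and r > 0.99. The shortfall from 1 is real
measurement attenuation — two collars each with ~7.5 m error SD per axis
sit beyond 25 m about 6% of the time even when the animals are together —
exactly the attenuation field estimates carry. What it does not show: the
generator has no fission–fusion dynamics, no habitat selection by default,
no seasonal behaviour change, and its meetings are instantaneous; passing
tests therefore certify the *pipeline arithmetic*, not the realism of any
ecological inference drawn from real collars.

## Numerical and edge-case decisions

* Timestamps are UTC instants throughout; season windows are evaluated on
  UTC calendar dates (the published windows do not state a time zone).
  Windows are inclusive at both ends and never span a year boundary.
* Regularization slots are anchored at midnight UTC with a 30-minute
  tolerance; within a slot the nearest fix wins, earlier on ties. The
  operation is idempotent.
* The KDE grid must catch ≥99% of kernel mass or `kde_ud()` errors,
  rather than silently renormalizing a clipped distribution.
* Isopleth ties (exactly equal densities) resolve in row-major order,
  making home ranges reproducible across platforms.
* `permutation_F` permutes with a caller-supplied seed; identical seeds
  give identical permutation streams.
* Degenerate inputs error loudly: < 5 fixes or zero variance for
  bandwidths, isolated nodes for average weighted degree, non-positive
  weights for closeness, n ≤ k+1 for AICc, constant columns for
  correlation screening.
* Problem sizes used in the validation suite — rasters up to 10×10 cells
  against the dense oracle, graphs up to 7 nodes against path enumeration,
  one 134-day 8-animal synthetic study, 500 null datasets × 200
  permutations for type-I calibration — were chosen as the smallest sizes
  at which each property is demonstrated convincingly.

## Known limitations

* Greedy simultaneity matching is not globally optimal for pathological
  timestamp patterns (it is for schedule-plus-jitter data).
* PHR across non-identical grids uses nearest-cell sampling, adequate when
  grids are similar; VI requires a genuinely shared grid and refuses
  otherwise.
* The circuit solver targets desk-scale rasters; an Illinois-scale
  1500×1500 scene with 1225 site pairs is out of scope by design.
* The residual-weight shift makes absolute global closeness values
  convention-dependent; only comparisons across networks computed under
  the same convention are meaningful.
* Model-averaged confidence intervals use the normal approximation with
  unconditional standard errors; small candidate sets on small n inherit
  that approximation's optimism.
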