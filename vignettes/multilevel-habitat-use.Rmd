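---
title: "Multilevel habitat use from telemetry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel habitat use from telemetry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(udlevels)
```

## The problem

Animals that alternate between communal aggregation and solitary activity —
episodic gregariousness, typical of temperate snakes that overwinter in
shared hibernacula and disperse to individual summer ranges — use space in a
way no single-level analysis captures. The habitat where the *population*
concentrates (the rocky, forested slope around a hibernaculum) can have a
covariate signature opposite to the habitat where *individuals* concentrate
(open, vegetated summer foraging patches). A covariate such as canopy cover
can then show a negative effect on intensity of use at the individual level
and a positive effect at the population level, and managing for either level
alone would misdescribe the species' needs.

`udlevels` implements a complete pipeline for quantifying this contrast from
radio-telemetry relocations with per-observation habitat covariates, plus a
synthetic-data generator that plants known level-dependent effects so every
stage can be validated against ground truth.

## Space use model

**Home ranges.** Seasonal home ranges are percent minimum convex polygons:
the `floor(p * n)` relocations nearest the arithmetic centroid (Euclidean
distance, ties broken by observation id for determinism) are retained and
their convex hull taken, with `p = 0.95` by default. Seasons with fewer than
20 relocations, or flagged incomplete (e.g. truncated by mortality), are
removed first; `mcp_area_curve()` reproduces the subsampling analysis that
motivates the 20-observation threshold (mean MCP area rises with sample size
and plateaus near 20). The percent-peel variant and floor rounding are a
declared convention — the dominant one in home-range tooling — not something
the method prescribes uniquely.

**Utilization distributions.** A UD is a bivariate-Gaussian kernel density
(equal bandwidth in x and y) evaluated at cell centers of a planar grid and
renormalized to integrate to 1. The bandwidth is not chosen by a plug-in or
cross-validation rule but by *area matching*: starting from the step size,
the bandwidth grows in 1-m increments until the area of the 95% volume
contour first reaches the 95% MCP area of the same points. Exact equality is
unattainable on a discrete raster, so the first crossing on the step grid is
the operational rule; because contour area is non-decreasing in bandwidth,
the first crossing is unique and warm starts (used inside the population
resampling loop) cannot change the answer, only skip evaluations. A
configurable cap (`h_max`, default 500 m) turns a hopeless search into an
error carrying the evaluation trace.

**Volume contours.** The q% volume contour is the smallest set of grid cells
whose cumulative probability mass reaches q, assembled by sorting cells on
density (descending) with ties broken by row-major cell index. Core areas
are the 30% contour; the 95% contour is the tuning target. Cell membership,
not polygon geometry, defines containment, so points on contour boundaries
are never ambiguous.

**Two levels.** Individual-level UDs are per-season. The population UD
controls for unequal tracking durations by resampling: each of 1000
iterations draws one season per animal, pools the relocations, recomputes
the 95% MCP and the matched bandwidth, and evaluates the UD on a fixed
population grid; the cellwise mean, renormalized, is the population UD. The
MCP target is recomputed per iteration — the pooled point set changes, so
its home-range area must too. Means of normalized surfaces on a shared grid
are normalized up to float error; renormalization simply enforces the
invariant.

## Resource-utilization models

Each retained relocation carries two binary responses: membership in its
season's 30% core (`core_ind`) and in the population 30% core (`core_pop`).
Covariates are z-score standardized once and shared by both designs so
effect sizes are comparable within and across models; a VIF screen
(threshold 2) reports collinearity.

The individual-level model is a single pooled logistic regression — core
labels are season-relative, so a season random effect would not be
meaningful. The population-level model is a logistic regression with a
Gaussian random intercept per animal-season, fitted by `lme4::glmer`
(Laplace by default; adaptive Gauss–Hermite quadrature via `nAGQ`, which the
test suite uses to confirm the likelihood is insensitive to node count). The
mixed model's AIC counts the random-intercept variance as one parameter.

All 32 covariate subsets are fitted at each level. Candidates within ΔAIC
< 2 of the best model form the averaging set; Akaike weights are
renormalized within the set, and full model averages assign a coefficient of
zero (with zero SE) where a covariate is absent. The unconditional standard
error combines within-model variance and between-model spread,
`SE_j = Σ w_m sqrt(SE_mj² + (β_mj − β̄_j)²)`, and 95% CIs are Wald. AIC, not
AICc, ranks the candidates: at roughly 870 observations and at most 7
parameters the small-sample correction is negligible.

The cross-level contrast per covariate is
`W = (β̄_ind − β̄_pop)² / (SE_ind² + SE_pop²)` against χ² with 1 df. The two
averaged coefficients are treated as independent: the two labelings come
from different UD constructions, and no cross-level covariance is estimated.
This is a declared simplification — the labels derive from the same
relocations, so the test's size is verified by simulation (500 datasets with
identical planted effects; rejection rate close to nominal 0.05) rather than
assumed. No multiple-testing correction is applied across the five
contrasts; the raw p-values are reported. CIs are Wald rather than profile
likelihood, also declared rather than inferred.

## Reproductive-class comparison

Core-area habitat composition is compared with two multinomial logistic
models on standardized covariates: by reproductive class (gravid female
reference) over individual-core observations, and by ecological level
(individual reference), where each observation contributes one row per level
at which it is core — an observation core at both levels appears twice. The
row construction for the level model is a declared convention; nothing in
the method fixes it uniquely.

Pairwise group differences are estimated-marginal-mean contrasts at the
covariate mean vector (all zeros under standardization): latent-scale
log-odds with delta-method SEs from the multinomial information matrix and a
normal reference (large-n approximation). The EMMs are unweighted; a
cross-check against the emmeans package's latent mode is part of the test
suite.

PCA uses the correlation matrix — the covariates share a percent scale but
not variances, and the correlation matrix matches the Bartlett-sphericity
framing that precedes it. Loadings are sign-normalized (largest element
positive) for backend-independent output and flagged at |0.5|;
covariate–component correlations are flagged at r > 0.40. Bootstrap class
summaries use the seeded percentile bootstrap (1000 iterations by default)
because the covariates are bounded and skewed.

Empirical semivariograms (omnidirectional, 15 equal-width bins, maximum lag
half the maximum pairwise distance by default) confirm the spatial
autocorrelation the habitat covariates are expected to carry; no variogram
model is fitted, matching the diagnostic rather than inferential role of
the plot.

## The synthetic study

The generator emulates a four-year copperhead telemetry study at desk scale:
16 animals contributing 27 animal-seasons, each with about 32 ± 7
relocations truncated to 20–49, in a class mix of 9 male, 10
nongravid-female and 8 gravid-female seasons, on a 600 m × 600 m landscape
gridded at 2 m.

**Landscape.** Each covariate surface is `100 * plogis(μ + 0.8 z + offset)`
where `z` is a unit-variance Gaussian random field with exponential
covariance (practical range 40 m) sampled by circulant embedding on the
doubled torus — exact stationary covariance at this scale, with the logistic
transform keeping percent cover in [0, 100] without truncation artifacts.
The hibernaculum zone (radius 120 m, the rocky forested slope, not just the
den) receives logit offsets of +1.25 canopy, +2.0 rock and −0.75 ground
vegetation; meadow patches receive −1.25 canopy, +1.5 ground vegetation and
+0.5 woody vegetation. These magnitudes were fixed once, jointly, so that
(a) communal and summer habitats differ detectably at the study's sample
size and (b) realized covariate VIFs stay below 2, the noncollinearity
condition the analysis assumes; stronger paired canopy/ground-vegetation
offsets push the two covariates into collinearity.

**Movement.** Each season runs through communal spring (19% of relocations,
isotropic Gaussian of sd 20 m around the hibernaculum), dispersal (12%,
interpolated with jitter), solitary summer (53%, Gaussian mixture of sd
10 m around 1–3 summer cores), and communal fall (16%). A phase-switched
point process, not a continuous-time movement model, is deliberate: at
multi-day relocation intervals step autocorrelation is weak and the pipeline
consumes only point patterns. Summer core centers are drawn from cells
outside the hibernaculum zone (animals disperse away from it) with
probability `∝ exp(w_class · z(covariates))`: males weight ground vegetation
+2.5 and canopy −2.0 (up to 3 cores), nongravid females canopy +1.0 (1–2
cores), gravid females coarse woody debris +2.5 (1 core). Observed
covariates are bilinear landscape samples plus Gaussian noise (sd 5%),
clipped to [0, 100].

The planted consequence: population cores sit in high-canopy, high-rock,
low-ground-vegetation habitat; individual cores in the opposite. Canopy is
expected negative at the individual level and positive at the population
level, ground vegetation the reverse, and class contrasts follow the
preference weights. `planted_truth()` records these expectations so tests
never re-derive them from the code under test.

**What the generator does not emulate.** Real relocation error, serial
autocorrelation within phases, multi-year site fidelity, transmitter
failure, observer-missed relocations, and nonstationary landscapes. Passing
tests demonstrate that the pipeline recovers known structure of this
planted kind at the study's scale — not that any field dataset satisfies
the model's assumptions.

## Numerical choices

- Grids use a lower-left origin; points map to cells by
  `floor((coord − origin)/cellsize)` with exact right/top-edge points
  assigned to the last cell. Grids are fixed before bandwidth tuning so all
  area comparisons are grid-consistent.
- The Gaussian kernel is truncated at 5σ (mass error < 1e-6) so each KDE
  evaluation is a pair of banded matrix products; every UD is renormalized
  over its grid.
- All randomness descends from one root seed; each stochastic stage
  (landscape, telemetry, population resampling, each bootstrap) draws from
  its own child stream keyed by stage name, so consuming more randomness in
  one stage never perturbs another, and identical configuration plus seed
  reproduces every output bit-for-bit.
- Distance ties at the MCP retention boundary break by observation id;
  density ties in volume contours break by row-major cell index.
- Degenerate inputs error early and specifically: fewer than 5 points for
  an MCP, collinear retained points, unnormalized rasters, empty cell sets,
  zero-variance covariates, separation in logistic fits, groups with fewer
  than 10 multinomial rows.

## Problem sizes

The validation suite exercises the defaults the generator states (16
animals, 27 seasons, ~870 relocations, 1000 population-resampling
iterations) for the end-to-end structural checks, and reduced designs
elsewhere: a 6-animal/9-season study for stage-level contracts, 500
model-level simulated datasets for the Wald-test calibration, and 20 seeded
replicates for sign-recovery rates. These sizes are the package's own
validation design, chosen to make each property measurable with stable
Monte-Carlo error.

## Known limitations

- The Wald level contrast ignores dependence between the two labelings of
  the same relocations; its empirical size is verified by simulation under
  the generator's conditions, not proven in general.
- Area matching inherits the MCP's sensitivity to outlying relocations:
  a single distant point inflates the target area and thus the bandwidth.
- The EMM reference distribution is a normal approximation; at small core
  samples the pairwise p-values are approximate.
- PCA is linear; curvilinear covariate relationships compress into
  components and are better explored with nonlinear ordination, which is
  out of scope here.
- Coordinates must be planar meters. Geographic coordinates are rejected,
  never silently projected, because the bandwidth semantics (meters) would
  otherwise be wrong.
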