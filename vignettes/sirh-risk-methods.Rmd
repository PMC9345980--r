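---
title: "Methods: penalized-spline risk models for fire-ant invasion surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: penalized-spline risk models for fire-ant invasion surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery: the
outcome definition, the three risk models and the penalized-spline engine
behind them, the synthetic data generator that stands in for restricted
surveillance data, and the numerical and design choices a maintainer should
know about.

## 1. The outcome: SIRH on a surveillance grid

Surveillance places one or two baited tubes per 200 m x 200 m cell in each
survey wave and records an ordinal severity 0-3 per tube (0 none, 1 = 1-4,
2 = 5-49, 3 = at least 50 trapped ants).  Each cell is marked per wave with
the maximum scale over its tubes.  Comparing waves,

* **SIRH** (successful invasion or remaining at the highest level):
  the cell's maximum scale increased, or stayed at 3;
* **USIRL**: the scale stayed constant below 3, or decreased;
* **undefined**: the cell was sampled in only one wave.

`classify_cell()` is a total function on `{0, 1, 2, 3, NA}^2`; of the 25
possible pairs, 7 are SIRH, 9 USIRL and 9 undefined.  Wave-2 tubes inherit
their cell's label as a binary response `y`; tubes in undefined cells are
excluded and counted.  Exclusion (rather than imputation) is this package's
documented choice: the outcome is defined only by a two-wave comparison, and
the surveillance design keeps the tube count nearly constant across waves,
so the loss is marginal.  The grid origin defaults to the extent's
lower-left corner but is a configurable field, so registration sensitivity
can be probed.

## 2. Covariates

Each labelled tube gets

* `landuse5`: the land-use category at the tube point, from a point-in-
  polygon overlay of two reference-year layers.  Agreeing years keep their
  category (agriculture, transportation, natural, artificial); disagreeing
  years give the fifth level, *change*.  Natural land cover is the model
  reference level.  Points on shared polygon boundaries (measure zero, but
  determinism matters) resolve by the fixed priority transportation >
  artificial > agriculture > natural.
* `road_dist`: Euclidean distance in meters to the nearest road centerline
  segment.  Coordinates are planar meters throughout (the surveillance
  system is recorded in a projected CRS); no datum handling is performed.

The category is evaluated at the tube point, not area-averaged over the
cell, matching how point records are overlaid on polygon layers in practice.

## 3. The three models

With `y_i` the binary SIRH label of tube `i`:

* **GLM** — all effects linear:
  intercept + 4 category dummies + road distance + `x` + `y` + `x*y`
  (9 coefficients).
* **GAM1** — one penalized smooth of road distance plus a tensor-product
  spatial smooth of the coordinates.
* **GAM2** — the distance smooth interacts with the land-use category as a
  *factor-by* construction: one centered smooth of distance per category,
  each with its own smoothing parameter, alongside the parametric category
  main effects.  This mirrors a varying-coefficient reading of "distance x
  land-use" (separate rows per category in the inferential table) rather
  than a smooth of an arithmetic product of the two variables, which would
  not be meaningful for a categorical factor.

The spatial term is read as a bivariate smooth of `(x, y)` ("geographical
variation"), not a univariate smooth of the product `x*y`; the notation in
field reports is ambiguous, but a product smooth cannot represent, e.g.,
north-south gradients.  Coordinates are standardized internally before
entering the model (meters have magnitude ~1e4 and the raw `x*y` product
~1e8, which needlessly ill-conditions the normal equations); the scaling is
stored on the fit and applied to prediction data automatically.

## 4. The penalized-spline engine

`pslogit(formula, data)` fits `logit P(y=1) = parametric + sum of smooths`
by penalized iteratively reweighted least squares.

**Bases.** Univariate smooths are cubic B-splines of dimension `k`
(default 10) with quantile-based interior knots; for knot placement the
covariate is capped at its 99.5th percentile (road distances have a long
right tail), and evaluation beyond the knot range extrapolates the basis
linearly, so affine functions are reproduced exactly on the whole line.
The tensor smooth uses `k_marginal` (default 6) per direction, giving 36
coefficients, large enough for the spatial term to reach effective degrees
of freedom in the twenties when the data demand it.

**Penalties.** Each univariate smooth carries one quadratic penalty built
from second-order *divided* differences on the Greville abscissae of the
basis.  Its null space is exactly the affine functions of the covariate for
any knot spacing (for uniform knots this is the familiar second-difference
penalty).  The tensor term carries two Kronecker-structured penalties — one
per direction, each with its own smoothing parameter — whose joint null
space is the bilinear surfaces `a + bx + cy + dxy`.  A practical consequence
used by the test suite: as all smoothing parameters grow, GAM1 degenerates
exactly onto the GLM's span (linear distance, bilinear coordinates), with
smooth EDFs tending to the null-space dimensions (1 and 3), not to 0.

**Identifiability.** Every smooth is centered by absorbing one sum-to-zero
constraint (a QR-based reparameterization dropping one column), so the
intercept and category dummies remain identifiable next to the smooths.

**PIRLS.** Starting from `mu = (y + 0.5)/2`, each iteration solves the
penalized weighted least-squares system; a step is halved (up to 30 times)
whenever the penalized deviance would increase, so accepted iterations are
monotone.  Convergence requires a relative penalized-deviance change below
`1e-8` (at most 100 iterations; non-convergence yields a flagged fit with a
warning).  The normal equations are Jacobi-equilibrated before Cholesky
factorization — coefficient blocks (dummies, meters, heavily penalized
spline ranges) differ by many orders of magnitude, and without scaling the
infinite-smoothing limit loses several digits.  A tiny ridge (`1e-8`) is
added only if the factorization fails outright.

**EDF, covariance, AIC.** With `H = X'WX` and `S` the assembled penalty,
per-coefficient EDFs are the diagonal of `(H + S)^{-1} H`, summed per term;
the coefficient covariance is `(H + S)^{-1}` (binomial dispersion 1); and
`AIC = deviance + 2 * total EDF`, which reduces to the usual AIC for
unpenalized fits on binary data.

**Smoothing selection.** `lambda` minimizes the GCV score
`n * deviance / (n - EDF)^2` by coordinate-wise golden-section search on
`log10(lambda)` in `[-6, 6]`, two sweeps over the parameters, PIRLS warm-
started from the incumbent coefficients.  A flat objective falls back to
the smallest `lambda` in the box, with a message.  GCV was chosen as a
standard, derivative-free criterion that needs nothing beyond quantities
the fit already produces; REML selection is out of scope.

**Inference.** Parametric terms are reported on the odds-ratio scale with
delta-method standard errors (`SE(OR) = OR * SE(beta)`) and Wald `z`; this
reporting convention is self-consistent with inferential tables that print
OR, OR-scale SE and `z` together.  Each smooth gets a Wald chi-square
`b' V^- b` with `V^-` the covariance block's eigen-pseudo-inverse truncated
at rank `round(EDF)` and a chi-square reference on that many degrees of
freedom; terms with EDF below 0.5 are skipped with a notice.  The truncated-
rank form is one defensible choice for penalized terms — its finite-sample
size is checked by simulation in the test suite rather than assumed.
P-values are unadjusted.  Nested fits are compared by analysis of deviance
(`delta deviance` on `delta EDF` degrees of freedom), reported both as a
chi-square and as an F statistic with dispersion fixed at 1.

**Degenerate inputs.** A smooth needs at least 4 distinct covariate values;
a factor-by level with fewer (e.g. road-snapped transportation tubes, all at
distance exactly 0) has its smooth dropped with a message, and a level with
4 to `k-1` distinct values gets a correspondingly smaller basis.  Plain
smooths on degenerate input are an error, since that indicates a data
problem rather than a structural zero.

## 5. The synthetic-data generator

No surveillance database or GIS layers are distributable, so the package
generates landscapes with the statistical structure the analysis assumes:

* **Patches.** The extent is tiled by an axis-aligned rectangular patch grid
  (default ~400 patches on an 11.6 x 11.4 km extent), with year-A categories
  drawn from configurable shares (defaults: natural 52.2%, agriculture
  21.1%, artificial 10.4% of patch area).  A rectangular tiling was chosen
  over irregular tessellations because every layer invariant — exact
  coverage, non-overlap, exact changed-area accounting — holds with exact
  arithmetic, and the overlay operations stay simple enough to verify
  against independent scalar oracles.
* **Roads.** A lattice of centerline segments at `road_spacing` (default
  800 m), offset from the extent edge by an eighth of the spacing so roads
  run through the interior of 200 m cells, never along cell boundaries.
  The strip within `road_halfwidth` (default 12 m) of a centerline is
  transportation land in both years — about 5.9% of the extent at the
  defaults, close to the observed transportation share — and tubes falling
  in the strip are snapped onto the centerline, reproducing the observed
  median road distance of exactly 0 for transportation tubes.
* **Change.** A random subset of patches is relabelled in year B until the
  changed (non-strip) area hits the requested fraction (default 10.7%)
  within one patch's area; by default 61.6% of the changed area is drawn
  from natural patches converted to development categories.  Because change
  is patch-granular, the achieved fraction is recorded exactly in the
  bundle metadata.
* **Tubes and labels.** One or two tubes per cell per wave; wave-2 positions
  move by at most `jitter` (default 20 m, clamped to the cell).  Cell-level
  SIRH indicators are Bernoulli draws from a logistic `true_model()`
  (intercept, category offsets with natural fixed at 0, optional
  per-category distance curves, optional smooth spatial field), evaluated at
  the cell's first wave-2 tube.  Severity-scale pairs are then drawn
  uniformly from the label-consistent enumerations — 7 pairs for SIRH, 9 for
  USIRL — so classification round-trips exactly; within a cell the first
  tube carries the maximum and the rest draw below it.  Uniform draws are a
  stand-in: within-class transition frequencies are not identified by any
  published summary, and the flag sits in the configuration where a user
  with real transition data can see it.
* **Shortcut generator.** `simulate_tube_table()` skips the geometry and
  draws categories from stated frequencies (defaults match the observed
  category distribution over 6918 tubes), distances from a stated sampler,
  and outcomes from the truth.  The simulation studies in the tests and the
  acceptance script use it because their conditions are stated in exactly
  those terms (category frequencies, true odds ratios, distance curves).

What the generator does **not** emulate: real island geography and road
topology, colony growth dynamics, dispersal kernels, typhoon disturbance,
temporal severity dynamics within a wave, or the road-biased tube placement
of actual surveillance (tubes here are uniform in cells).  Passing tests
therefore demonstrate that the machinery recovers known structure from data
with the assumed form — not that the original study's exact estimates are
reproducible, which would require the unreleased surveillance data.  In the
two-wave design, the half-to-one-year colonisation lag behind land-use
change is represented only implicitly by the wave spacing.

## 6. Result summaries

* `contingency_and_chi2()` cross-tabulates labels by category, reports row
  percentages rounded half-up to one decimal (table-formatting convention;
  base `round()` is round-half-even), and a Pearson chi-square without
  continuity correction.  On the published surveillance counts this
  chi-square is ~173.8; the package reports its own exact computation.
* `distance_threshold()` scans a fitted category's distance-probability
  curve from 0 m in 1 m steps, holding other covariates at reference values
  (the curve's own category; mean training coordinates), and returns the
  largest `d*` with predicted probability at least `p0` on `[0, d*]`,
  refining the crossing by root finding.  The "over 60% of risk within a
  distance band" reading is interpreted as the fitted probability exceeding
  0.6 (consistent with probability-scale figures and the 150 m statement
  for land-use-change areas); a cumulative-share reading is noted but not
  implemented.
* `risk_surface()` evaluates a fit at cell centers with covariates from the
  landscape and decomposes the linear predictor into land-use (including
  intercept), road-distance and spatial components, which sum exactly to
  the total.

## 7. Problem sizes and seeds in the shipped studies

The simulation studies are sized to be decisive yet quick: odds-ratio
recovery uses 200 replicates at the full surveillance size (n = 6918,
GLM only); the AIC-ordering study 50 replicates at n = 2000 with distance
bases of dimension 8 and marginal spatial dimension 5; the threshold
recovery 50 replicates at n = 3000; smooth-test size/power checks use
n = 2000.  All are driven by explicit seeds and run in a few minutes in
total on one CPU.

## 8. Known limitations

* GCV can undersmooth in small samples; no REML option.
* The truncated-rank Wald test for smooths is approximate; its size is
  simulation-checked at the shipped sample sizes only.
* Nearest-road distance is Euclidean to centerlines, not along-network, and
  road width is represented only through the transportation strip.
* The generator's rectangular patches make no attempt at realistic
  landscape shape metrics (perimeter/area, contagion).
* Ordinal severity is used only through the SIRH/USIRL dichotomy; an
  ordinal response model is out of scope.
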