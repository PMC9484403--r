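---
title: "Hindcast-validated distribution modeling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hindcast-validated distribution modeling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hindcastSDM)
```

## The problem and the modeling idea

Coastal ecotones such as the mangrove/salt-marsh transition oscillate on
sub-decadal time scales: cold winters kill mangroves back and salt marsh
expands; warm stretches let mangroves invade marsh. Because those
oscillations are documented independently (aerial imagery, topographic
sheets), they provide something future projections can never have: a
ground truth for a model projected *out of its training window*. The
package's workflow is therefore: fit presence-background niche models on
a present climate window; project them into past windows of known
dominance; accept the model set only if it reproduces the documented
group-level ordering; and only then read its future projections.

## The maximum-entropy model

Presence-only data cannot identify prevalence, so the model contrasts the
environment at `m` presences with `n` background locations sampled
uniformly from the valid landscape. Writing `f(x)` for the feature vector
of a location and `eta(x) = sum_j beta_j f_j(x)`, the fit maximizes the
penalized log-likelihood

```
L(beta) = mean_presences(eta) - log( mean_background(exp(eta)) )
          - sum_j lambda_j |beta_j|
```

which is the Gibbs/maximum-entropy formulation: the exponential density
`exp(eta)/Z` over the landscape that is closest to uniform subject to
matching the presence feature means, with an L1 budget that converts the
match into a confidence interval per feature. The objective is concave;
`maxent_fit()` maximizes it by cyclic coordinate ascent (per-coordinate
Newton step, soft-thresholding for the L1 term, step halving so the
objective never decreases — an invariant the test suite asserts). Feature
screening by the subgradient condition keeps sweeps cheap: a zero
coefficient is touched only when its gradient exceeds its penalty.

Features are built on variables rescaled to [0, 1] by their training
range: linear, quadratic, pairwise products, threshold steps at interior
knots, and forward/reverse hinges (50 knots by default). Penalties follow
the published MaxEnt default schedule — a per-class constant interpolated
in `m`, times the feature's standard deviation over presences, divided by
`sqrt(m)`, times the user's regularization multiplier.

Projection clamps each variable to its training range before the feature
expansion ("fading by clamping" is implemented as hard clamping; the
additional blend toward the training mean that some implementations apply
is deliberately not replicated, because hard clamping is exactly
reproducible and its effect is testable — projections beyond the training
hull equal the hull-corner prediction). The raw density keeps its
training normalization (it sums to 1 over the training background), and
the reported suitability is the cloglog transform
`p = 1 - exp(-exp(H) * raw)` with `H` the entropy of the background raw
distribution, truncated into [0, 1].

## Bioclimatic predictors

`compute_bioclim()` derives BIO1–BIO19 from 12 monthly values of tmin,
tmax and precipitation per cell, with `tmean = (tmax + tmin)/2`.
Conventions that the oracle tests pin down:

* BIO4 and BIO15 use the sample (n − 1) standard deviation.
* BIO15 uses the `sd/(1 + mean)` form so arid cells do not divide by 0.
* Quarters are three consecutive months with December–January wrap; ties
  are broken by the earliest starting month (January first). Quarter
  picks are rotation-invariant, which the suite checks by rotating month
  labels and data together.
* A cell with zero annual temperature range gets nodata isothermality
  (BIO3) with a warning rather than an Inf.

Correlation pruning is a greedy scan in an explicit priority order
(default BIO6, BIO12, BIO2, BIO5, BIO15, BIO18, then the rest): a
variable is kept iff its |r| against every already-kept variable is at
most the threshold (0.7 by default). The priority encodes the
coastal-ecology reading that minimum temperature of the coldest month
and annual precipitation are the anchor drivers of mangrove and
salt-marsh range limits; the published analyses this workflow follows
report the retained *set*, not the algorithm, so the scan order is a
documented package choice.

## Selection and evaluation

* **AICc** uses the landscape-normalized raw likelihood and
  `k` = nonzero coefficients; candidates with `m <= k + 1` are flagged
  non-comparable. The default grid is the six class combinations L, LQ,
  LQH, LQHP, LQPT, LQHPT crossed with multipliers 0.5–4 by 0.5.
* **checkerboard2** assigns points to 4 spatial bins from the parities of
  two nested checkerboards (aggregation factors (2, 2) by default).
  Tuning uses these blocks for spatial omission; fivefold random CV
  evaluates the *selected* configuration — the two procedures are given
  distinct roles because listing both leaves their interaction open.
* **Partial ROC** integrates sensitivity versus fractional predicted area
  over the low-omission region (omission ≤ E = 0.05), divides by the
  random expectation, and bootstraps test points (1000 iterations, 50%
  resampling — the conventions of the partial-ROC literature; E, the
  iteration count and the resample fraction are package defaults, not
  prescribed values). A random predictor scores ≈ 1 (asserted within
  0.05), perfect discrimination approaches 2. Note the restriction to
  the low-omission region makes the statistic insensitive to
  *anti*-predictive signal at small E; the suite demonstrates the
  below-1 behavior at a wide omission window.
* **Percent contribution** credits each accepted coordinate step's
  objective improvement to the stepped feature's variable(s), products
  splitting equally. This mirrors the heuristic of the reference MaxEnt
  implementation in spirit; exact replication of its table is not
  claimed, and with collinear predictors credit is split arbitrarily
  between them — which is precisely why pruning precedes fitting.

## Aggregation and the hindcast decision rule

Total suitable habitat in a region is the sum of cloglog values over
valid cells whose centers fall in the box (inclusive bounds). Group
values are arithmetic means over member species; group percent change is
computed from group-average sums, not as the mean of species-level
changes (the two differ whenever species' present sums differ — the
suite asserts the distinction). Reports round sums to 1 decimal, ratios
to 3, percent changes to 1; all comparisons behind the verdict use
unrounded values.

The validation verdict formalizes an ordinal expectation stated verbally
in the hindcasting literature: in the group's dominance period it should
be relatively favored. Criteria: (A) mangrove group mean lower in the
salt-marsh dominance period than in the mangrove dominance period, (B)
the mirror ordering for the salt-marsh group, (C) the mangrove:salt-marsh
ratio higher in the mangrove dominance period. The verdict is their
conjunction; species-level orderings are reported but deliberately do not
affect it, since individual species are documented to deviate from the
group trend without invalidating it.

## What the synthetic generator emulates — and what it does not

`climate_scenario()` produces monthly grids with a latitudinal
temperature lapse, a sinusoidal seasonal cycle, a *longitudinal*
(coast-to-inland) precipitation gradient, white noise, and named periods
carrying additive offsets. Running the moisture gradient along longitude
is a deliberate design choice: with both gradients latitudinal, BIO6 and
BIO12 are nearly collinear across the landscape and the cold-limited and
moisture-limited truths become statistically inseparable — no fitting
method could attribute the groups' responses. Orthogonal gradients make
the discriminative experiment a test of the pipeline, not of luck.

Default study conditions (fixed once): a 60 × 80 grid of 1° cells
(lon −112..−32, lat −30..30), 6-year windows matching the analysis
windows (present 2013–2018, salt-marsh dominance 1984–1989 with a
−2.5 °C / +50 mm offset, mangrove dominance 2001–2006 with +0.5 °C /
−40 mm), two species per group with exponential truths on BIO6
(coefficients 0.45–0.55 per °C) and BIO12 (0.0065–0.008 per mm), 400
occurrences per species, 2000 background points, and LQ features. These
sizes keep every full-pipeline experiment in single-digit seconds while
leaving hundreds of presences per fit; the test suite runs 20 replicate
worlds of both the true and the inverted scenario.

What the generator does **not** emulate: realistic coastline geometry,
spatial autocorrelation of noise, sampling bias in occurrences (records
are drawn from the truth density itself), climate-model physics, and
sea-level rise. Passing tests therefore demonstrate that the *pipeline*
recovers imposed signal under clean conditions; they do not certify
performance under the sampling biases and spatial dependence of real
archives.

## Numerical choices and degenerate inputs

* Coordinates are WGS84 decimal degrees; cells are addressed by centers;
  boxes include cells whose centers fall inside. Duplicate occurrences
  are exact coordinate matches after rounding to 6 decimals (~0.1 m).
* ASCII grids are written at 6 significant digits — the documented
  round-trip precision. GeoTIFF is not supported in this build; the
  exchange format is the ASCII grid the workflow's tooling natively
  exports.
* The elevation mask is strict (`> 10 m` removed; exactly 10 m kept).
* Constant variables are dropped from the feature expansion with a
  warning; zero-variance bioclim layers are excluded from pruning.
* Convergence: objective change per sweep below `1e-6`; coordinate steps
  are capped and halved until the concave objective does not decrease.
* Model files serialize coefficients at 17 significant digits so
  projections reproduce bit-for-bit after a round trip.

## Known limitations

The fitter is a clean-room implementation of the penalized maximum
entropy objective; it matches a generic convex optimizer on the same
objective to 1e-3 but is not expected to replicate any particular
historical binary's output bit-for-bit (different screening and knot
placements move individual coefficients, not the optimum's value).
Percent contributions are path-dependent under collinearity. The partial
ROC p-value is anti-conservative for weak models, a known property of
the bootstrap construction. Region sums weight all cells equally rather
than by true cell area, which shrinks with latitude; within the
subtropical bands analyzed here the distortion is modest and identical
across the periods being compared.
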