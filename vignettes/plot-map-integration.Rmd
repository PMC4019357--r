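---
title: "Integrating inventory plots with biomass maps: models, error propagation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating inventory plots with biomass maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestAGB)
```

# The problem

A wall-to-wall biomass map and a plot-based forest inventory answer the same
question — how much aboveground tree biomass (AGB) is on the landscape — from
nearly disjoint evidence. The map sees every pixel but is a model prediction;
the inventory measures trees exactly but only on a sparse sample of plots,
and, crucially, only on land that satisfies an administrative *forest*
definition. Where canopies are fragmented, a material share of standing
biomass sits on "nonforest" land and is invisible to the inventory. This
package implements the full chain needed to compare the two observation
systems honestly: allometric biomass with its model-choice and model-error
uncertainty, a spatial prediction model with per-pixel intervals, agreement
statistics at plot scale, and area totals at landscape scale — plus a
synthetic landscape generator so every stage is testable end to end without
confidential plot coordinates.

# Allometric families

Three interchangeable families predict tree AGB (kg, dry weight):

* **Generalized ln–ln group equations**, `AGB = exp(b0 + b1 ln d)` with DBH
  `d` in cm, one equation per species group. These need only a diameter.
* **Volume-based component-ratio chain (CRM)**: combined-variable bole
  volume `v = a + b d² h` (m³) from DBH and bole height `h` (m), bole dry
  weight `v × wood density`, whole-tree AGB by dividing by a bole-to-total
  component ratio. A missing bole height is a hard error, never imputed.
* **Species-specific equations** with a substitution rule: a species with no
  equation of its own falls back to the generalized equation of its group.

Coefficients live in a YAML registry (`default_equation_registry()`), not in
code. The ln–ln block ships the ten generalized group equations with their
published fit statistics (R², n) which drive the error simulation below. The
CRM and species-specific blocks shipped here are *synthetic plausible
defaults* — regionally calibrated coefficient tables are licensed data we do
not redistribute — and are labelled as such in the registry file; analysts
substitute their own registry for production use. DBH outside an equation's
validity range yields a warning flag, not an error, matching inventory
practice of applying equations to every measured tree.

Units are fixed throughout: DBH cm, height m, tree biomass kg, plot density
Mg/ha (`Σ kg / 1000 / (area m²/10⁴)`), county totals Tg (`Mg/ha × ha ×
10⁻⁶`; pixel sums `× 0.09 ha` per 30-m pixel).

# Allometric-error engine

Published equations come with a regression R² and a sample size but not the
residuals. The engine reconstructs an error model in three steps:

1. **Population simulation.** 10,000 DBH values are drawn uniformly over the
   equation's validity range; log-scale Gaussian noise is added to the ln–ln
   prediction and its SD is calibrated by bisection until the refit R²
   matches the published R² within ±0.005. One standard-normal noise vector
   is drawn once and rescaled during the search, making the refit R² a
   deterministic, strictly decreasing function of the noise SD — the
   calibration cannot oscillate. Noise on the log scale keeps biomass
   positive and produces the empirically observed pattern of absolute error
   growing with tree size.
2. **Standard-error functions.** At least 100 subsets of `n_obs` diameters
   (the published sample size) are drawn from a Weibull diameter
   distribution (default shape 2, scale placing the mean at the range
   midpoint — both configurable; no diameter distribution is published),
   matched to nearest population points, and a two-parameter power law
   `SE(d) = a d^b` is fit by least squares to binned absolute residuals (up
   to 20 equal-count DBH bins, half-normal factor √(π/2) converting mean
   absolute residual to an SD estimate). The reported function is the
   parameter-wise mean over subsets. "Standard error" here means *residual
   SD* — the per-tree perturbation scale — not the SE of a mean; only the
   former supports tree-level Monte Carlo.
3. **Plot propagation.** Each Monte Carlo replicate (default 10,000)
   perturbs every tree's prediction by an independent `N(0, SE(d))` draw,
   truncates at zero, and sums to a plot density; the 2.5/97.5 percentiles
   bound the interval. Percentile rather than normal-theory bounds because
   truncation skews small plots. Per-tree errors are independent by
   default; a `shared_error` flag substitutes a common plot-level draw for
   sensitivity analysis, since between-tree error correlation is unknown.

Because the propagation model matches the generating model, the interval is
calibrated by construction: over 500 synthetic plots the 95% interval covers
the realized plot biomass at 95% ± 2% (the tests assert this at 10,000
replicates per plot).

# Spatial prediction model

Plot biomass regressed on canopy metrics leaves spatially correlated
residuals, so the mapping model is

$$y = X\beta + w + \varepsilon,\quad w \sim GP(0,\ \sigma^2 R),\quad
R_{ij} = e^{-\phi d_{ij}},\quad \varepsilon \sim N(0, \tau^2 I).$$

Sampling is a hand-rolled MCMC with the loop in C++ (RcppArmadillo, driven
by R's RNG so `set.seed()` makes the whole chain reproducible draw for
draw): conjugate normal updates for `β` (flat prior) and the latent `w`,
inverse-gamma updates for `σ²` and `τ²`, and a log-scale random-walk
Metropolis step for `φ`. Priors: `σ², τ² ~ IG(2, v/2)` with `v` the OLS
residual variance, so each prior mean is half of `v`; `φ` uniform with
support chosen so the effective range `3/φ` spans one pixel to the domain
diagonal. The proposal is tuned to 25–45% acceptance during burn-in;
defaults 5,000 iterations, 2,500 burn-in, thin 5, which at n ≤ 300 training
plots runs in seconds. Duplicate coordinates are rejected (singular `R`);
an acceptance rate outside (0.10, 0.70) raises a convergence warning rather
than being silently accepted.

Pixel prediction uses composition sampling: for each retained posterior
draw, `w*` at each pixel is drawn from its exact conditional Gaussian given
the training `w` (pixels conditioned on training points only, processed in
blocks — this matches predictive sampling at unobserved locations and keeps
memory linear in the block size), then `y* = X*β + w* + N(0, τ²)`; per-pixel
means and 2.5/97.5 percentiles form the three-band predictive raster.
Prediction at a training location degenerates correctly: the conditional
collapses onto the training effect, so as `τ² → 0` the predictive mean
interpolates the data, and far from all data it collapses to `X*E[β]` with
variance `E[σ²] + E[τ²]` — both limits are asserted against closed forms in
the tests, and 95% credible intervals cover known generating parameters in
≥ 90% of replicate fits.

The ensemble baseline is delegated to `randomForest` (~500 trees,
out-of-bag R² and RMSE reported); tree-ensemble internals are not this
package's contribution. `variogram_check()` provides the standard empirical
semivariogram for residual diagnostics, reporting empty lag bins as `NA`.

# Comparison and county estimators

Map values for a plot are the mean of the pixels containing the four
subplot centers (one pixel in single-plot mode). Pixel membership uses a
half-open convention — `[x, x+s)` across, `(y−s, y]` down, north-up — so
boundary points are assigned deterministically. Pairs hitting no-data
pixels are excluded and logged, never zero-filled.

The agreement regression puts the *map* on the y-axis (a slope above 1
means an over-predicting map). RMSE defaults to raw pair differences
(`√mean((mapped − field)²)`) because that measures map error directly; a
flag gives the regression-residual variant. Distributional agreement is the
two-sample Kolmogorov–Smirnov sup-distance computed exactly over the pooled
jump points (ties are common in zero-inflated biomass samples, so the
generic no-ties shortcut is not used); no p-value is attached — sample
sizes here make any difference "significant", only the distance is
informative. Interval agreement is the fraction of plot/pixel 95% CI pairs
whose closed intervals intersect, touching endpoints included.

County (area) estimates come three ways: the design-based sample mean of
plot densities with a t-interval on n−1 degrees of freedom (the estimator
behind printed inventory intervals; a bootstrap-percentile option exists),
the same estimator applied to pixels sampled at the plot locations (which
isolates map–plot disagreement from sampling design), and the full pixel
sum (which adds the map's view of land the sample missed). The nonforest
decomposition is pure arithmetic on an all-tree vs forest-only pair of
totals, and `estimate_gap()` reports signed difference, percent difference,
and CI containment. Unweighted regression and unweighted means are used
throughout; plot-area vs extracted-pixel-area mismatch (670 m² sampled vs
3,600 m² of pixels under a cluster) is acknowledged but not corrected — no
defensible correction exists without modeling within-pixel heterogeneity.

# The synthetic landscape

The generator's defaults *are* the study conditions the rest of the package
assumes:

* **Surface**: Gaussian random field on pixel centers with covariance
  `sill·exp(−decay·d)`, mean-shifted and clipped at zero. Defaults sill
  2,500 (Mg/ha)² (pixel SD 50), decay 0.01/m (effective range ≈ 300 m),
  mean 70 Mg/ha — a mid-Atlantic urbanizing county. The clipping creates
  the realistic zero-inflation that drives KS distances.
* **Nonforest**: contiguous rectangular blocks carved until 40% of pixels
  are nonforest. With the scattered-tree flag (default on), nonforest
  pixels keep thinned tree biomass rescaled so their share of total biomass
  is exactly the configured value (default 25%, the middle of the observed
  21–27% range); with it off they are bare, giving the degenerate all-zero
  case.
* **Plots**: systematic lattice with a common random start, clamped a
  subplot-spacing inside the boundary. Clustered plots have four 168 m²
  subplots, center plus three satellites at 7 m and azimuths 0/120/240° —
  the published description of the design is followed verbatim even though
  operational subplot spacing is larger (36.6 m); both are one `spacing`
  argument away. Single-plot mode uses one 400 m² plot. Forest-restricted
  placement snaps to the nearest forest pixel.
* **Trees**: per subplot, stem count is Poisson with mean equal to the
  pixel's biomass mass divided by the closed-form expected single-tree
  biomass `E[exp(b0+b1 ln D)] = exp(b0)·scale^{b1}·Γ(1+b1/shape)` under the
  Weibull DBH distribution; each tree gets a species from the stand
  mixture, a true biomass from its group equation, a bole height from a
  saturating height–diameter curve with lognormal noise, and the condition
  label of its pixel. Condition is per pixel, not per the full
  condition-mapping protocol — sufficient to reproduce the censoring
  mechanism, which is what the downstream analysis consumes.
* **Canopy metrics**: shared monotone power link of biomass
  (`b_k·AGB^0.5`) plus Gaussian noise, mutually correlated through the
  common base; a bisection calibrates the noise SD to a target linear-fit
  R² (0.67 by default, the accuracy regime of regional canopy-metric
  models).

What the generator does **not** emulate: point-cloud processing and
canopy-height modeling (metrics are generated directly from truth), GPS
plot-location error, temporal mismatch between acquisition and field dates,
multi-condition plots, and measurement error in DBH itself. Passing tests
therefore certify the estimators and the error propagation — not the
upstream remote-sensing chain.

# Numerical choices and degenerate inputs

* GRF simulation adds `1e-8·sill` to the covariance diagonal before
  Cholesky; the MCMC adds `1e-10` to correlation matrices. Landscape grids
  are dense-Cholesky simulated, practical to ~60×60 pixels.
* R² calibration bisects on a fixed noise vector (deterministic,
  monotone); an unreachable target is a hard convergence error.
* SE-function fits drop near-zero bins; an all-zero residual population
  returns `SE ≡ 0` exactly (a = b = 0).
* Empty tree lists are measured zeros: density 0, zero-width CI.
* Percentile CIs use `quantile(type = 7)`; determinism everywhere comes
  from explicit seeds, with per-stage seeds hashed from the master seed so
  any stage can be re-run in isolation.
* Problem sizes in the shipped demo configuration (40×40 grid, 60 plots,
  4,000 MCMC iterations, 200 predictive draws) are chosen so a full
  pipeline runs in seconds on one CPU; the validation suites use the
  prescribed analysis scales (n = 200 × 20 replicate spatial fits, 500
  plots × 10,000 replicates for CI coverage).

# Known limitations

* The spatial model is isotropic exponential only — no Matérn smoothness or
  anisotropy; metric selection (e.g. model averaging over candidate metric
  sets) is out of scope, a single configured design matrix is used.
* Sapling-specific CRM adjustments are not applied; the same volume chain
  covers all diameters.
* Allometric and sampling errors are propagated independently; their
  covariance, and DBH measurement error, are not modeled.
* The plot-level agreement slope on synthetic data sits below 1 even
  against a perfect map: plot densities carry within-plot sampling noise,
  which attenuates a regression of map on field. That attenuation is a
  property of the comparison design itself and is visible in the demo
  output.
* `nonforest_share` recovery from a plot sample is Monte Carlo noisy; with
  80 systematic plots the tests allow ±8 percentage points around the
  configured share.
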