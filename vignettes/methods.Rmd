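---
title: "Methods: estimators, scale transfer and the synthetic landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimators, scale transfer and the synthetic landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`forestscale` compares three routes to a mean aboveground biomass density
(AGBD, Mg ha⁻¹) for a reporting scope — a forest stratum, an administrative
domain, or their intersection — and measures how the *support size* of
canopy metrics biases the model-based route. This vignette records the
models, the conventions that had to be pinned down, what the synthetic
generator does and does not emulate, and the design choices that were
genuinely open.

## The three estimators

**Design-based (DB).** The sample mean of plot biomass with the
simple-random-sampling variance `s²/n`, a Student-t half-width
`ε = t_{n−1} · SE`, and relative SE `100·ε/mean`. Inventory grids are
systematic, not SRS; the SRS variance is the standard conservative
convention for them and is what we implement. No finite-population
correction is applied (sampling fractions in the emulated setting are
≈ 0.1%).

**Model-based (MB).** Per-stratum calibration models
`AGBD = a·h₁ᵇ` or `a·h₁ᵇ·h₂ᶜ` (height percentile or mean height as `h₁`,
canopy cover fraction as `h₂`) are applied to every window of a metric
grid; the scope mean is the average prediction over its N windows. The SE
is the delta method driven purely by the parameter covariance
`Σ̂_β = s²(JᵀJ)⁻¹` from the nonlinear fit:
`SE = √((ΣZᵢ)ᵀ Σ̂_β (ΣZⱼ))/N` with gradients
`∂f/∂a = h₁ᵇh₂ᶜ`, `∂f/∂b = f·ln h₁`, `∂f/∂c = f·ln h₂`. This factorized
form is algebraically identical to the full double sum over window pairs;
the O(N²) version survives as a test oracle (`mb_se_bruteforce`). Windows
whose required predictor is ≤ 0 predict exactly 0 and contribute a zero
gradient — the power model is undefined at 0, and treeless windows carry no
parameter uncertainty. Residual (within-model) prediction error is *not*
part of this SE; it reflects parameter uncertainty only, which is the
convention the estimator family uses. When a scope spans several strata,
each stratum's quadratic form is summed: the models are fitted on disjoint
plot sets and treated as independent.

**Small-area (SAE).** A two-phase regression estimator with an exhaustive
first phase. One OLS working model (intercept + top-of-canopy height h99 +
mean height + cover) is fitted on the *full* plot set — that is where the
strength is borrowed — and every scope G gets
`mean = X̄_Gᵀβ̂ + mean(residuals of G's own plots)`. The variance sums a
coefficient term `X̄_Gᵀ Σ̂_β X̄_G`, an auxiliary-mean term (zero here: the
first phase is a census of the scope's windows), and a residual term. Two
notational ambiguities in the published formulations of this estimator
family were resolved as follows and exposed nowhere else: the correction term is read as the *mean*
residual over G's plots, and the third variance term as
`var(residuals_G)/n_G` (the sample variance of G's residuals over the local
n), which is the residual-variance term of the standard two-phase
framework. With an intercept-only working model the estimator collapses to
the local sample mean exactly — a reduction the acceptance suite asserts.
Scopes with zero (one) local plots return the synthetic mean flagged
without (with) a point estimate but no variance, never a silent drop.

## Scale transfer

Calibration happens at the plot-native support: a 25-m-radius plot
(1963.5 m²) is treated as equivalent to a 44-m square window (1936 m²; the
1.4% area mismatch is accepted, as in the tradition this follows). The
experiment then applies the *same* fitted model to metric grids at 10, 25,
44 and 100 m — refitting per resolution would answer a different question.
Because percentiles do not aggregate linearly and the model is convex in
its height input when `b > 1`, the map mean drifts with resolution: finer
support spreads the height distribution and Jensen's inequality pushes the
mean up; coarser support smooths it and pushes the mean down. With a
*linear* model in mean height the drift vanishes identically, which is the
package's null control. Reproducing any particular real-landscape
magnitude of this drift is explicitly out of reach on synthetic data, so
the acceptance criteria pin the sign structure and the monotone trend
instead.

## Canopy metrics: pinned conventions

* Percentiles (h10…h99) are computed over cells ≥ 2 m (the
  vegetation-return convention implied by using a 2-m cover threshold as a
  predictor); a window with no vegetation cell reports 0. Implementations
  differ on the percentile support; this choice is fixed and documented.
* Percentile rule: linear interpolation between order statistics
  (type-7), pinned for bit-reproducibility.
* `h_mean` averages over *all* cells, not only vegetation cells. This is
  required for the mean to aggregate linearly across nested windows (the
  null control above) and makes `h_mean` the one metric that is exactly
  scale-free.
* Two cover fractions are maintained: `fc` (≥ 2 m, the model predictor) and
  `fc4` (≥ 4 m, the plot-retention filter) — the two thresholds play
  different roles and are never merged.
* Windows tile from the raster origin; partial edge windows are dropped.
  Experiments that compare resolutions exactly therefore use extents
  divisible by every resolution in play (lcm(10,25,44,100) = 2200 m).
* Circular footprint membership is cell-centre-in-circle, the simplest
  unambiguous rule.
* A 44-m window is 22×22 cells on the default 2-m grid. A 25-m window is
  *not* representable at 2 m (12.5 cells) and `window_metrics` refuses it;
  runs that need the full resolution set use a 1-m fine grid. No specific native lidar
  gridding resolution is assumed.

## The synthetic landscape

The generator stands in for a lidar CHM + NFI-plot study region (none is
deposited) and emulates exactly the features the estimators are sensitive
to:

* **Height field.** Per stratum, a stationary Gaussian random field
  (spectral synthesis: white noise filtered with a Gaussian kernel, torus
  topology) transformed lognormally and moment-matched to the stratum mean
  and CV. The kernel is calibrated so the semivariogram reaches ~95% of
  sill at the stated practical range (`ρ(h) = exp(−3h²/range²)`). The
  lognormal transform gives the right-skewed height distributions typical
  of area-based inventories.
* **Gaps.** An independent field thresholded at the stratum's gap fraction
  forces cells to height 0 — spatially clumped treeless patches, the
  feature that drives DB > MB when samples require minimum cover.
* **Biomass truth.** Per cell, `AGBD = a₀·h^b₀` with stratum-specific
  coefficients; plot-scale measurement error is mean-one multiplicative
  lognormal (`exp(σZ − σ²/2)`), so a plot is unbiased for its footprint
  truth and coverage tests probe the estimator, not a noise offset.
* **Geometry.** Strata are contiguous nearest-seed-point patches; domains
  are a rectangular tiling. Plots sit on a systematic grid with a uniform
  `[0, spacing)` random offset — the uniform offset keeps every cell's
  inclusion probability constant, which design-based unbiasedness rests on
  (an offset restricted away from the boundary provably biases stratum
  means by several percent on a correlated field; the package clips
  boundary footprints instead). Retention requires ≥ 10% of footprint
  cells ≥ 4 m.

Defaults portray a heterogeneous 6-stratum, 10-domain, 6×6 km mosaic at 2-m
resolution: stratum mean heights 7–14 m, CV 0.45, correlation range 150 m
(well below the 1-km plot spacing, so plots are effectively independent and
the SRS variance convention is nearly exact), gap fractions 0.15–0.35,
biomass exponents 1.40–1.60 with a₀ chosen to put stratum means at
realistic 25–90 Mg ha⁻¹, and 30% relative plot noise — the middle of the
27–52% relative-RMSE band typical of per-stratum calibrations of this form.

What the generator does **not** emulate: species mixtures and tree-level
allometry, terrain and occlusion effects on the CHM, geolocation error,
temporal mismatch, and non-stationary trends within strata. A green test
therefore establishes that the estimators and the scale experiment behave
correctly on a world with the assumed statistical structure — not that any
particular real-world magnitude is reproduced.

## Calibration details

Starting values for the nonlinear fit come from OLS on the log-log
linearisation; plots with a non-positive response or predictor are excluded
(the training domain mirrors the ≥ 10%-cover inventory rule; prediction at
such cells is defined as 0). `nls` runs Gauss–Newton with `scaleOffset = 1`
so noiseless fixtures converge instead of tripping the relative-offset
criterion. Predictor search is exhaustive over (height, cover) pairs on the
log scale with a VIF > 10 screen; if every pair is collinear the best
single height model is kept — the fallback pattern real calibrations
exhibit. Fit statistics follow the conventional formulas
(`RMSE = √(SSE/n)`, relative values against the observed mean, adjusted
pseudo-R²); the bias sign convention — positive = overprediction — is not
universal and is therefore fixed and documented. The covariance `s²(JᵀJ)⁻¹`
assumes additive homoscedastic errors; under multiplicative noise of
inventory-typical magnitude it understates the sampling variance of the
scale and exponent parameters by 30–90% (measured by Monte-Carlo), because
high-biomass plots then carry most of the error variance and most of the
leverage at once. The Monte-Carlo covariance check and the
parameter-recovery criterion therefore run in the homoscedastic regime the
formula is specified for — "27.5% relative noise" implemented as additive
error with sd = 27.5% of the mean response, which is also exactly the
regime in which the fitted model reports 27.5% relative RMSE. Weighted or
heteroscedastic NLS, the remedy a real calibration would reach for, is
deliberately out of scope.

## Numerical and degenerate-input choices

* t critical values always come from the Student t at the estimator's df;
  1.96 emerges automatically for large N.
* `relative SE %` is defined for positive means only; degenerate scopes are
  flagged (`insufficient sample`, `no local plots`, …) and propagate as
  flagged rows in experiment tables.
* Rasters never resample silently: any origin/cell-size/shape mismatch is a
  hard error before computation.
* Raster files are plain-text ESRI ASCII grids written with 17 significant
  digits, so doubles round-trip bit-exactly; GeoTIFF was not an option in
  the dependency budget and the `.asc` format is readable by standard GIS
  tooling.
* Determinism: every stochastic entry point takes a seed; a manifest (seed
  + config hash + version) accompanies every output directory, and rerunning
  an experiment reproduces its CSV byte-identically.

## Test-scale choices

The acceptance criteria run on deliberately scaled-down worlds so the suite
stays within minutes on one CPU: coverage uses the default 6×6 km landscape
with 200 replicate offsets (design-based replication against one fixed
truth, exactly the empirical-coverage procedure the estimators are assessed
with); the scale-ordering criterion uses fifty 2.2×2.2 km single-stratum
landscapes with 200-m plot spacing so each replicate refit has ~100 plots;
the cross-resolution identity uses a 1.1-km, 1-m world where all four
resolutions tile exactly. The sampling-validity check uses two large
contiguous strata because footprints straddling a stratum boundary mix
neighbouring biomass into the plot value — a support effect that shrinks
with stratum size and is negligible at the km²-scale strata the defaults
emulate, but would dominate a toy landscape.

## Known limitations

* The MB standard error ignores residual prediction variance and spatial
  correlation of model errors; it is a parameter-uncertainty measure, as in
  the estimator family it implements.
* SAE variance omits the covariance between the fitted coefficients and the
  local residual mean (small when the scope's plots are a small share of
  the fit).
* The SRS variance for systematic samples is conservative when the field is
  correlated at the plot spacing; with the default 150-m range and 1-km
  spacing the effect is negligible.
* No real CRS handling: coordinates are planar metres with a lower-left
  origin throughout.
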