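# forestscale

Scale-aware estimation of forest aboveground biomass density (AGBD, Mg/ha)
from area-based canopy height metrics.

## The problem

Jurisdictional carbon reporting increasingly leans on wall-to-wall canopy
height products — lidar grids, satellite CHMs — pushed through biomass
models calibrated on national forest inventory (NFI) plots. Three things go
wrong quietly:

1. **Sparse plots.** NFI grids (1 plot per km²) give reliable means for a
   province, but municipalities or individual forest strata may contain a
   handful of plots; the design-based (DB) estimate there is wildly
   uncertain.
2. **Model-based shortcuts.** Applying a fitted model to every map cell
   (model-based, MB, inference) gives tight-looking errors, but its validity
   rests entirely on the calibration model and the scale it was fitted at.
3. **Scale transfer.** Canopy metrics are nonlinear aggregates: the 99th
   height percentile of a 10-m cell is not the 99th percentile of the 100-m
   cell containing it, and a power-law model `AGBD = a·h₁ᵇ·h₂ᶜ` is convex in
   its inputs. Predicting at a resolution different from the plot-native
   support (a 25-m-radius plot ≈ a 44-m square cell) therefore *biases* the
   map mean — finer grids overestimate, coarser grids underestimate — even
   though the model itself is unchanged.

`forestscale` implements the three inference engines and the
multi-resolution experiment that quantifies the scale effect, plus a
synthetic-landscape generator so the whole pipeline is testable end to end
without any proprietary inventory or lidar data.

## Estimators

With plot biomass `y_i` (n plots in scope), the **design-based** estimate is
the sample mean with the simple-random-sampling variance (conservative for
systematic grids):

    Ȳ_DB = Σy_i/n,  Var = s²_y/n,  ε = t_{n−1} · SE,  relSE% = 100·ε/Ȳ

The **model-based** estimate averages per-cell model predictions μ̂_i over
all N population units, with a delta-method SE built from the calibration
parameter covariance Σ̂_β and per-cell gradients Z_i = ∂f(X_i, β)/∂β:

    Ȳ_MB = Σμ̂_i/N,  SE = √( (ΣZ_i)ᵀ Σ̂_β (ΣZ_j) ) / N

(the factorized form of the full double sum over unit pairs; the O(N²)
brute-force version is kept as a test oracle).

The **small-area** (SAE) estimate is a two-phase regression estimator with
an exhaustive first phase: an OLS working model on height/cover metrics,
fitted on *all* plots, evaluated at the scope's exhaustive auxiliary mean
X̄_G and corrected by the scope's own mean residual:

    Ȳ_SAE = X̄_Gᵀ β̂ + R̄_G,
    Var   = X̄_Gᵀ Σ̂_β X̄_G + s²_{e,G}/n_G

## Worked example

```r
library(forestscale)

cfg <- landscape_config(extent_m = 2200, fine_cell_m = 2, n_strata = 2,
                        n_domains = 4, plot_spacing_m = 200, seed = 11)
ls <- generate_landscape(cfg)
plots <- sample_nfi_plots(ls$chm, ls$strata, ls$domains, ls$truth,
                          spacing_m = 200, radius_m = 25,
                          cover_min = 0.10, noise_sdlog = 0.3, seed = 12)
plots <- add_plot_metrics(plots, ls$chm, 25)
models <- calibrate_all_strata(plots)
models[["1"]]
#> <biomass_model> stratum 1: AGBD = 1.458 * h50^1.607 * fc^1.027
#>   n = 74, RMSE = 19.89 Mg/ha (27.0%), bias = -0.20%, adj.R2 = 0.872

spec <- experiment_spec(resolutions = c(10, 44, 100), baseline_m = 44)
res <- run_full_experiment(spec, ls, plots, models)
subset(res$comparison, scope_type == "stratum" & scope_id == "1",
       select = c(method, scale_m, mean, rel_se_pct, total_mg, rel_change_pct))
#>   method scale_m     mean rel_se_pct total_mg rel_change_pct
#> 1     DB      NA 73.65987  17.958823 23943.67      26.180446
#> 2    SAE      NA 60.59965  14.920190 19698.35       3.808091
#> 3     MB      10 59.28786   5.975162 19272.11       1.560976
#> 4     MB      44 58.37662   6.149789 18930.37       0.000000
#> 5     MB     100 56.44851   7.883222 18345.77      -3.302875
```

Read: the design-based mean for this stratum sits 26% above the baseline MB
estimate (the cover-filtered sample lands preferentially on stocked
conditions, while the map averages in gaps and low-stature cells), the SAE
mean falls between DB and MB with a tighter interval than DB, and the same
fitted model applied at 10-m / 100-m support drifts +1.6% / −3.3% against
its 44-m native scale — the Jensen-type scale-transfer bias. Exact numbers
vary with the seed; DB and SAE totals use mean × area, MB totals sum
per-pixel biomass weights (hence the DB total column is not mean × the MB
map area).

A subcommand CLI wraps the same stages (`simulate`, `metrics`, `calibrate`,
`estimate`, `experiment`, `report`):

```sh
Rscript inst/cli/forestscale experiment --config config.json --seed 7 --out runs/demo
```

Rasters travel as plain-text ESRI ASCII grids (`.asc`), plot tables and
comparisons as CSV, models and manifests as JSON; every output directory
carries a manifest (seed + config hash) sufficient to re-run bit-identically.

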