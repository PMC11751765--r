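# smvpd

Quantifies the coupling between soil moisture (SM) and vapor pressure
deficit (VPD) from daily gridded series, and attributes its temporal
variation to vegetation structure (leaf area index, LAI) and physiology
(transpiration per unit leaf area, Tr/LAI) alongside hydro-meteorological
drivers. When soils dry, VPD tends to rise in the following days; a strong
negative SM-VPD association marks drought propagating from land to
atmosphere, and vegetation modulates that pathway. The package is aimed at
land-atmosphere interaction and ecohydrology researchers who want a tested,
reproducible implementation of this analysis chain, exercised end to end on
synthetic data with a known planted truth.

## The statistic and the attribution model

Daily series become anomalies by removing a per-calendar-month climatology
and a LOWESS trend (f = 0.4), estimated jointly by backfitting. The
coupling on day *t* is the partial correlation, in a 30-day moving window,

ρ(SM<sub>t−ℓ</sub>, VPD<sub>t</sub> · VPD<sub>t−ℓ</sub>) =
(r<sub>xy</sub> − r<sub>xz</sub> r<sub>yz</sub>) /
√((1 − r<sub>xz</sub>²)(1 − r<sub>yz</sub>²)),

with x = SM anomaly at t−ℓ, y = VPD anomaly at t, z = VPD anomaly at t−ℓ
(lag ℓ ∈ {1, 7, 14} days; 7 by default). Daily values aggregate to months
and are retained only for months with < 20% missing days, mean temperature
≥ 5 °C (growing season) and negative mean SM anomaly (dry conditions).

Per grid cell, a regression random forest (100 trees, max features 0.3,
bootstrap, random state 42) trained on the cell's 3 × 3 neighborhood
predicts monthly coupling from seven monthly predictors (absolute values):
LAI, Tr/LAI, precipitation, temperature, VPD, surface SM, wind. Cells need
≥ 20 samples and out-of-bag R² ≥ 0.2. Exact TreeSHAP decomposes
predictions; drivers are ranked by mean |SHAP|, and the Theil–Sen slope of
SHAP values against each driver (Kendall-tau test, p < 0.01) is the
coupling *sensitivity* to that driver. Sensitivities are then summarized
over climate zones and aridity × temperature bins, with partial Spearman
covariate tests (biodiversity, root-zone water storage; controlling
aridity and temperature) under Benjamini–Hochberg FDR control.

The random forest, TreeSHAP, Theil–Sen, partial correlation and partial
Spearman are implemented in the package (C++ via Rcpp for the forest and
the moving-window statistic); tests verify them against brute-force
oracles (residual correlation, Shapley enumeration, pairwise-slope
enumeration, step-up FDR).

## Worked example

A 5 × 5 synthetic grid, 12 years of daily data, with a planted negative
vegetation modulation of the coupling:

```r
library(smvpd)
cfg <- synthetic_config(n_lat = 5, n_lon = 5, n_years = 12, seed = 7)
ds  <- generate_dataset(cfg)
cp  <- compute_coupling(ds, lag = 7)
summary(cp$pcor_monthly[cp$retained])
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#> -0.9340 -0.5973 -0.4729 -0.4678 -0.3399  0.2168
```

Retained growing-season, dry-anomaly months show a clearly negative
coupling (median −0.47): dry soil anomalies are followed by elevated VPD a
week later. Attribution then recovers the planted vegetation effect:

```r
at  <- attribution_sweep(cp, ds$predictors_monthly, ds$grid)
at
#> <smvpd_attribution> 24 cells, 11 passed screens
veg <- subset(at$drivers, predictor %in% c("lai", "transpiration_norm") & significant)
aggregate(theil_sen_slope ~ predictor, veg, function(s) c(n = length(s), median = round(median(s), 3)))
#>            predictor theil_sen_slope.n theil_sen_slope.median
#> 1                lai            11.000                 -0.052
#> 2 transpiration_norm            11.000                 -0.110
```

Of 24 unmasked cells, 11 pass both screens; in all of them the Theil–Sen
sensitivity of coupling to LAI and to normalized transpiration is negative
(medians −0.052 and −0.110 per predictor unit): greener, more freely
transpiring vegetation strengthens the negative SM–VPD coupling, which is
the behavior planted in the generator (b_lai = −3, b_phys = −5).
`run_pipeline(pipeline_config(...), out_dir = "...")` executes the whole
chain including the spatial summaries and writes CSV/JSON outputs whose
first line embeds the config hash and seed; identical configurations
reproduce outputs byte for byte.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the pipeline's main computation from scratch — generating the
default 15 × 15, 12-year synthetic world from the given seed, computing
anomalies, moving-window coupling, the per-cell forest/SHAP/Theil–Sen
attribution and the screens — prints a short summary of screened cells and
recovered sensitivity signs, and writes the acceptance JSON to `--out`.

The methods vignette (`vignettes/smvpd-methods.Rmd`) documents the model,
the synthetic world and its limits, and every numerical convention.
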