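# transectdsm

Model-based abundance estimation for aerial line-transect surveys of
cetaceans — the full chain from raw sightings to a CV-masked abundance
map, with a synthetic-survey simulator so every stage can be validated
against known truth.

The package targets the standard workflow for estimating whale abundance
from single-platform aerial surveys on, e.g., Antarctic feeding grounds:

1. **Detection functions (MCDS).** Half-normal or hazard-rate keys, an
   optional cosine adjustment series, and sighting covariates (sea state,
   subjective conditions) acting on log σ. Detection at distance x is
   `g(x)` with `g(0) = 1`; fitting maximizes the conditional likelihood
   `∏ g(x_i|z_i)/μ_i`, `μ_i = ∫₀ʷ g`, after right truncation at
   w = 1750 m. The effective strip width `esw = ∫₀ʷ ĝ` and average
   detectability `p0 = esw/w` come with delta-method SEs; model choice is
   by AIC with Cramér–von Mises goodness of fit.
2. **Group size.** Size-bias correction by regressing `log s` on `ĝ(x)`,
   falling back to the arithmetic mean when the slope is not significant.
3. **Segments.** On-effort track is cut into ≤ 5-km segments (< 1 km
   discarded), each with effective area `A_seg = esw × L_seg` (one-sided
   coverage — the observers search one side of the line).
4. **Terrain covariates.** TPI, TRI, slope, aspect from a depth raster
   (3×3 neighbourhood, Horn's method) plus distances to shelf break and
   coastline, averaged along each segment.
5. **Density surface model.** Per-segment group counts with a
   `log(A_seg)` offset, thin-plate regression-spline smooths, Tweedie
   errors (power profiled on the exact series likelihood), smoothing
   parameters by GCV; candidates ranked by AIC/GCV/deviance explained.
6. **Prediction.** 2.5 × 2.5 km grid, per-cell SE and CV from the
   coefficient covariance, cells with CV ≥ 100 discarded, groups × group
   size → individuals with a delta-method 95% CI.
7. **Synthetic surveys.** `survey_config()` / `simulate_population()` /
   `simulate_survey()` generate inhomogeneous group processes,
   zero-truncated group sizes, ad-hoc transects and one-sided
   covariate-scaled detection with known truth.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()`,
`glance()`, `autoplot()` and `plot_prediction()` for the fitted objects.

## Worked example

Simulate a survey with known truth and run the full pipeline:

```r
library(transectdsm)

cfg <- survey_config(seed = 4)
sv  <- simulate_survey(simulate_population(cfg), cfg)

res <- run_pipeline(
  sv$sightings, sv$effort,
  det_configs  = list(detection_config(label = "hn1"),
                      detection_config(adjustment = "cosine", label = "c1")),
  dsm_formulas = list(g1 = n_groups ~ s(x, y, k = 20)),
  quiet = FALSE)
```

which prints

```
stage detection: 2 candidates, 100 sightings, w = 1750 m
selected hn1: esw = 803 m, E[s] = 1.46
stage segmentation: 162 segments, 794 km effort, 100 groups assigned
selected DSM g1: AIC 315.6, deviance explained 15.6%
stage prediction: 2177/2501 cells retained (13606 km^2); N_ind = 3716 [2540, 4891]
```

Reading this: 100 simulated sightings support a half-normal detection
function with an 803-m effective strip width; effort becomes 162 segments
whose counts drive a spatial Tweedie DSM; after discarding cells with
CV ≥ 100, the model predicts 3716 individuals (95% CI 2540–4891) over
13,606 km². The generating truth for this replicate was 3355 individuals
— inside the interval. The ranked detection table, segment table, cell
predictions and abundance summary are in `res$detection_table`,
`res$segments`, `res$cells` and `res$abundance`; `autoplot(res$detection_fit)`
shows the fitted detection function over the distance histogram and
`plot_prediction(res$retained)` maps the density surface.

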