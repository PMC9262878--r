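---
title: "Methods: line-transect detection functions, density surface models and abundance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: line-transect detection functions, density surface models and abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transectdsm)
```

`transectdsm` implements the model-based abundance-estimation chain used for
aerial line-transect surveys of cetaceans: covariate detection functions,
effort segmentation with effective-area offsets, terrain covariates, a
Tweedie density surface model (DSM) on thin-plate regression splines, and
CV-masked grid prediction. This vignette is the package's account of the
underlying statistics, the tunable parameters, the numerical choices, and
what the synthetic-survey validation does and does not demonstrate.

## The detection model

A group of whales at perpendicular distance $x$ from the track line is
detected with probability $g(x)$, with certain detection on the line,
$g(0) = 1$. Two key functions are supported:

* half-normal: $g(x) = \exp(-x^2 / 2\sigma^2)$;
* hazard-rate: $g(x) = 1 - \exp(-(x/\sigma)^{-b})$, shape $b > 1$.

A cosine adjustment series (order 2 by default, half-normal key only)
multiplies the key by $1 + \sum_j a_j \cos(j\pi x / w)$ and the curve is
rescaled so $g(0) = 1$ exactly. Sighting covariates (Beaufort sea state,
subjective sighting conditions coded as an unordered three-level factor
with reference level *good*) act on the scale through
$\sigma = \exp(\beta_0 + \beta^\top z)$, the multiple-covariate distance
sampling (MCDS) convention.

Fitting maximizes the conditional likelihood
$\prod_i g(x_i \mid z_i) / \mu_i$ with
$\mu_i = \int_0^w g(u \mid z_i)\,du$ after right truncation at
$w = 1750$ m (the survey's truncation distance; left truncation is zero).
The integral uses 64-point Gauss–Legendre quadrature, which is exact to
machine precision for these smooth integrands; the closed-form half-normal
strip width $\sigma\sqrt{\pi/2}\,\mathrm{erf}(w/\sigma\sqrt{2})$ is used as
an independent oracle in the tests. Optimization is bounded quasi-Newton
(`nlminb`) on transformed parameters ($\log\sigma$, $\log(b-1)$,
unconstrained $a_j$) from five deterministic perturbed starts; parameter
vectors that make the adjusted $g$ negative anywhere on $[0, w]$ are
penalized and can never be returned. The survey covers **one side** of the
track line only, so no factor of two appears anywhere in the covered-area
arithmetic.

The effective strip width is $\mathrm{esw} = \int_0^w \hat g(u)\,du$,
pooled as the arithmetic mean of per-sighting integrals when covariates
are present, and average detectability is $\bar p = \mathrm{esw}/w$
(reported as `p0`). Standard errors come from the delta method on the
inverse observed information. The identity
$\mathrm{esw} = \bar p \cdot w$ holds to numerical precision by
construction and is asserted in the tests.

Goodness of fit uses the Cramér–von Mises statistic on the fitted
probability-integral transforms,
$W^2 = 1/(12n) + \sum_i (u_{(i)} - (2i-1)/2n)^2$, with p-values from the
asymptotic null distribution (evaluated by the classical Bessel-function
series). The parameter-estimation effect is ignored, as in common
distance-sampling practice, so same-data p-values are conservative; the
test suite calibrates the type-I error with reference parameters estimated
from an independent sample, where the nominal level applies.

Hazard-rate fits are not excluded automatically. The ranking table carries
a near-zero diagnostic (fitted detection density in the first tenth of the
strip relative to the empirical histogram bin) so the caller can apply the
visual-inspection exclusion that aerial-survey analysts use when the
hazard-rate spike under-covers the line.

## Group size

Detected group sizes over-represent large groups at large distances. The
regression method regresses $\log s_i$ on $\hat g(x_i)$; if the slope is
significant at $\alpha = 0.15$ (the conventional distance-sampling
threshold, exposed as a parameter because conventions differ), the
expected group size is the back-transformed prediction at $g = 1$,
$E[s] = \exp(\hat a + \hat b + \mathrm{MSE}/2)$. Otherwise the arithmetic
mean of observed sizes is used. Both quantities are always reported, since
a survey report typically quotes the observed mean alongside the corrected
value.

## Segments and effective area

Each contiguous on-effort run of GPS fixes is cut into consecutive 5-km
segments, with terminal remainders kept when at least 1 km and discarded
otherwise; segments never span an off-effort gap. The effectively searched
area of a segment is $A_{seg} = \mathrm{esw} \times L_{seg}$ (one-sided).
Covariates are averaged over sample points spaced 0.5 km along the actual
track path (the spacing is a package choice; the averaging rule, not the
step, drives the result at these raster resolutions, and halving the step
changes segment covariates only at the third decimal on the test rasters).
Sightings are assigned to segments by their recording time within the
segment's time span, falling back to the nearest segment midpoint on the
same transect when no usable timestamp exists.

## Terrain covariates

From a depth raster (negative below sea level, used as-is) the package
derives the standard 3×3-neighbourhood metrics: TPI (centre minus the mean
of the eight neighbours), TRI (mean absolute difference to the eight
neighbours), and slope/aspect by Horn's weighted finite differences, with
aspect in degrees clockwise from north and undefined (no-data) on flat
cells. The 3×3 neighbourhood is the common default for these indices;
multi-scale variants are out of scope. Distances to the shelf break and
coastline are planar distances to polyline features in the projected
coordinate system. Geographic coordinates are projected with a spherical
Lambert azimuthal equal-area projection centred on the data bounding box,
adequate for a regional survey domain. Aspect enters models as a plain
smooth — its circularity (0° = 360°) is not encoded, a documented caveat
rather than a modelling choice we defend.

## The density surface model

Per-segment group counts $n_j$ (groups, not individuals — individuals
enter only at prediction time) are modelled as

$$ n_j \sim \mathrm{Tweedie}(\mu_j, p, \phi), \qquad
   \log \mu_j = \log A_{seg,j} + \beta_0 + \textstyle\sum_k f_k(z_{jk}), $$

with thin-plate regression-spline smooths $f_k$. For $1 < p < 2$ the
Tweedie law is a compound Poisson–gamma distribution with positive mass at
zero, which suits zero-heavy segment counts better than the Poisson and
absorbs overdispersion through $\phi$.

**Basis.** Each smooth uses the low-rank eigen-approximation of the full
thin-plate spline: the radial basis ($r^3$ in 1-D, $r^2\log r$ in 2-D) on
the data points is eigen-decomposed, truncated to the `k` leading
eigenvalues, and the polynomial null space is appended unpenalized; the
penalty is the truncated bending-energy matrix, and each smooth is centred
(sum-to-zero) for identifiability against the global intercept. Defaults
are `k = 30` for the 2-D spatial smooth and `k = 10` for 1-D terms,
matching common practice for regional survey data; both are arguments.

**Fitting.** Penalized IRLS with step-halving; smoothing parameters
minimize the deviance-scale GCV score $n D / (n - \mathrm{edf})^2$ with
$\mathrm{edf}$ the trace of the influence matrix, by golden-section search
per term with outer iteration over terms. The Tweedie power is profiled on
the grid $1.05, 1.10, \ldots, 1.95$, maximizing the exact series
log-likelihood, after which the smoothing parameters are re-selected at
the chosen power; $\phi$ is the Pearson estimator. The series density is
summed in a window around its largest term (relative accuracy ~1e-10);
in the tiny-dispersion regime where the series peak runs past $10^6$
terms, the saddlepoint density — essentially exact there — is used. The
reported AIC is $-2\ell + 2(\mathrm{edf} + 1)$ on the series likelihood,
counting the dispersion; deviance explained is relative to the
intercept-plus-offset null model at the same power, and the reported $R^2$
is the adjusted variance-based measure (whether published survey tables
use the adjusted form is ambiguous; ours is stated here so comparisons
are well-defined). The whole procedure is deterministic: identical data
give identical fits. Everything above is validated in the tests against
`mgcv` as an independent implementation; `mgcv` is never used in the
fitting path.

**Model choice.** Candidate models are ranked by AIC with GCV and deviance
explained reported alongside; when models sit within 2 AIC units the table
prefers the one with fewer covariates, the parsimony rule used in survey
practice.

## Prediction and abundance

Predictions are made on a grid of 2.5 × 2.5 km cells carrying the model
covariates: $\mu_c = \exp(\eta_c + \log(\text{area}_c))$, with link-scale
standard errors from the Bayesian posterior covariance of the coefficients
and $\mathrm{CV}_c = 100\,\mathrm{SE}_c/\mu_c$. Cells with
$\mathrm{CV} \ge 100$ are discarded, restricting the estimate to the area
the data support. Over retained cells,
$\hat N_{groups} = \sum_c \mu_c$ with
$\mathrm{SE}^2 = v^\top V_\beta v$, $v = X^\top \mu$ — the full-covariance
delta method, which accounts for the correlation of cell predictions
(how published analyses aggregate per-cell errors is not always stated;
this choice is exact under the fitted model and is a possible source of
divergence from printed intervals). Individuals are groups times the
expected group size; the default 95% interval is $N \pm 1.96\,\mathrm{SE}$
on the individual scale, with a log-normal interval as an option.
Detection-function and group-size uncertainty are **not** propagated by
default, matching the model-based convention of reporting the model's own
standard error; estimates are therefore minimum-variance statements
conditional on the selected detection function, and — with no
availability or perception bias correction — minimum estimates of true
abundance.

## The synthetic survey generator

`survey_config()` defines the generating conditions; its defaults emulate
the aerial-survey setting the package targets and are fixed once:

* domain 150 × 100 km; mean group density 0.17 groups/km², log-linear
  spatial trend (`surface_beta = c(1, -0.6)` on scaled coordinates), so the
  surface is inhomogeneous but smooth; optional Gaussian-random-field noise
  and a cluster process for feeding aggregations (≥ 15 animals) are off by
  default, since aggregations were excluded from the line-transect analysis
  they would otherwise contaminate;
* zero-truncated Poisson group sizes with $\lambda = 0.55$, mean ≈ 1.30
  animals, matching the observed scale of fin whale groups on feeding
  grounds;
* 12 ad-hoc transects of nominal 100 km at random anchors and orientations
  (~1000 km of effort after clipping), GPS fixes every 1 km;
* one-sided half-normal detection with $\sigma = 600$ m, truncation
  1750 m, flight altitude 600 ft = 182.88 m (sightings carry the
  equivalent inclinometer declination), optional sea-state effect on
  $\log\sigma$.

These values give on the order of 100–130 detections per replicate —  the
sample-size regime of a real single-season aerial survey — and make the
expected detections analytically checkable as $D \times \mathrm{esw}
\times L$ on a homogeneous surface. The generator reproduces the
statistical structure the estimator assumes (inhomogeneous Poisson groups,
i.i.d. sizes, distance-dependent one-sided thinning); it deliberately does
**not** simulate animal movement, responsive movement, availability or
perception processes, observer heterogeneity, or measurement error in
angles and distances. Passing end-to-end tests therefore demonstrate the
estimator's correctness under its own assumptions, not robustness to their
violation in real data.

## Validation experiments

The test suite runs, at desk scale, the experiments that justify each
stage (sizes chosen as the package's standard validation set):

* 200 simulated surveys of ~300 distances: median $|\hat\sigma -
  \sigma|/\sigma$ below 5%, and the quadrature strip width against the
  closed form to 1e-6 relative;
* the esw–p0 identity for every fitted model class, and the printed-table
  consistency $0.3292 \times 1750\,\mathrm{m} = 576.1\,\mathrm{m}$;
* 500 goodness-of-fit replicates with independently estimated reference
  parameters: type-I error within [0.03, 0.08] at $\alpha = 0.05$;
* Tweedie deviance converging to the Poisson deviance at $p \to 1$ and the
  series density integrating to one within 1e-4;
* 100 full pipeline replicates (simulate → fit detection → segment → fit
  DSM → predict → mask → summarize): median relative bias of individual
  abundance below 10% and 95% CI coverage of the realized truth at least
  85%, where "truth" is the simulated individuals inside the CV-retained
  cells;
* terrain metrics identical to brute-force 3×3 computation on 50 random
  rasters.

`scripts/acceptance.R` re-runs these experiments from scratch (the
end-to-end experiment at 50 replicates, its standard reporting size) at a
seed supplied on the command line and writes the resulting quantities as
JSON.

## Known limitations

* g(0) = 1 is assumed; no mark–recapture correction for perception bias
  and no availability correction, so real-data abundances are minima.
* The CvM p-value ignores the parameter-estimation effect (conservative
  when testing the fitting data).
* Smoothing-parameter selection is GCV, not REML; GCV can undersmooth in
  small samples, which is visible as slightly liberal edf in the
  simulation experiments.
* The spatial model ignores residual spatial autocorrelation beyond the
  smooth; interval coverage in the end-to-end experiment reflects the
  correctly-specified case.
* Aspect's circularity is not encoded; grids extrapolate only as far as
  the CV mask allows, and no soap-film or tensor alternatives are offered.
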