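---
title: "Mapping seagrass meadows from shallow-water reflectance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping seagrass meadows from shallow-water reflectance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SeagrassDyn)
```

## The problem

Seagrass meadows grow in the infralittoral — the permanently submerged
coastal belt — typically between 1 and 11 m of depth on sedimentary
bottoms. Mapping them from multispectral satellite imagery is attractive
because the visible bands (blue, green, red) penetrate the water column, but
the water itself attenuates and contaminates the bottom signal: the deeper
the pixel, the more the spectrum converges to that of open water. Any
classification of raw surface reflectance therefore confounds substrate with
depth. SeagrassDyn implements the standard remedy — an analytical correction
for optically shallow water — followed by two-class supervised
classification, confusion-matrix accuracy assessment and two-epoch change
analysis.

## The optical model and its assumptions

Per band, surface reflectance over shallow water is modelled as

$$R_w = R_\infty + (R_b - R_\infty)\, e^{-2 K_d Z},$$

where $R_\infty$ is the asymptotic reflectance of an infinitely deep water
column, $R_b$ the bottom reflectance, $K_d$ the diffuse attenuation
coefficient (m⁻¹) and $Z$ the depth (m, positive down). The factor 2
accounts for the two-way path of light through the column. The model
assumes horizontally homogeneous water (one $K_d$ per band for the whole
scene), a Lambertian bottom, and reflectance already corrected to
bottom-of-atmosphere; it ignores scattering phase functions and the
air–water interface. Within this package that simplification is a feature:
the model is exactly invertible, and the inversion

$$R_b = R_\infty + (R_w - R_\infty)\, e^{+2 K_d Z}$$

is what `correctWaterColumn()` computes per pixel.

### Estimating $R_\infty$

`estimateDeepWaterReflectance()` takes the per-band **median** over valid
pixels deeper than a threshold (default 40 m). At such depths
$e^{-2K_dZ}$ has extinguished any realistic bottom contrast, so the residual
signal is $R_\infty$ plus noise; the median is robust against stray bright
pixels. A minimum of 100 qualifying pixels (overridable) guards against
meaningless estimates; failing that the function refuses with the observed
count, and the caller can widen the scene or supply $R_\infty$ directly.

### Estimating $K_d$

Taking logs of the contrast linearizes the model exactly:

$$\ln(R_w - R_\infty) = \ln(R_b - R_\infty) - 2 K_d Z .$$

Over a substrate with *constant* $R_b$ — a uniform bright sandy area with a
gradual depth increase from 1 to 5 m — the left side is linear in $Z$ with
slope $-2K_d$, so `fitAttenuation()` runs per-band ordinary least squares
and reports $K_d = -\mathrm{slope}/2$ with $R^2$ and the cell count.

Two design points deserve note:

* **Transform.** The default regresses $\ln(R_w - R_\infty)$, the exact
  linearization above. Some workflows regress raw $\ln R_w$ instead; that
  variant is available as `transform = "log_raw"` for literal replication,
  but only the contrast form makes the slope exactly $-2K_d$ under the
  model itself, which is why it is the default. Natural logarithms are used
  throughout; the slope-to-$K_d$ conversion assumes them.
* **Cells without bottom signal.** Where $R_w \le R_\infty$ the log is
  undefined — physically, no measurable bottom contrast. Such cells are
  dropped from the fit with a reported count; if more than half the
  candidate cells drop, the zone is rejected as unsuitable rather than fit
  on a biased remainder. During correction the same cells are set to
  $R_b = R_\infty$, again with a reported count.

### Depth clip

The inversion multiplies sensor noise by $e^{+2K_dZ}$: at $K_d = 0.1$ m⁻¹
and 20 m this is a factor of ~55. Bottom-reflectance composites are
therefore clipped to depths ≤ 20 m by default (`maxDepth`), the
conventional working limit for quantitative seafloor estimates in visible
bands; output values are clipped to [0, 1.5] with a reported count.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `depthThreshold` (deep water) | 40 | m | bottom contrast is negligible below it |
| `minDeepPixels` | 100 | px | guard for a meaningful median |
| `depthMin`, `depthMax` (calibration) | 1, 5 | m | uniform sandy zone with gradual depth change |
| `maxDepth` (clip) | 20 | m | noise amplification beyond is prohibitive |
| `trainFraction` | 0.40 | — | common 40/60 training/assessment convention |
| `regularizationEpsilon` | 1e-8 | — | keeps class covariances positive-definite |
| `pixelSize` | 10 | m | visible-band resolution of Sentinel-2 |

Optical defaults in the synthetic generator — $R_\infty$ =
(0.0200, 0.0136, 0.0045) and $K_d$ = (0.0197, 0.0303, 0.1046) m⁻¹ for the
blue/green/red bands — are the study-area estimates for a clear-water
northern-Adriatic coastal scene and give the generator realistic magnitudes.

## Classification

Two benthic categories are distinguished: **seagrass** and **other** (a
mosaic of bare sediment and non-seagrass vegetation types that cannot be
separated at 10 m resolution). Three classifiers share one contract:

* **Maximum likelihood (MLC)** — implemented from first principles: per
  class, sample mean $\mu_i$, sample covariance $\Sigma_i$ (denominator
  $n-1$) regularized by $\epsilon I$, and prior $p_i$ (class frequencies by
  default; an equal-priors switch mirrors common GIS defaults). A pixel $x$
  is assigned to the class maximizing
  $g_i(x) = -\tfrac12\ln|\Sigma_i| - \tfrac12 (x-\mu_i)^T \Sigma_i^{-1}
  (x-\mu_i) + \ln p_i$.
* **SVM** — an RBF-kernel support vector machine trained with simplified
  sequential minimal optimization. No SVM library is available in this
  toolchain, so the optimizer is implemented here; defaults ($C = 10$,
  kernel width scaled to feature variance, training subsample cap of 800)
  are pragmatic, reported at run time, and overridable.
* **Random trees** — bagged CART trees (Gini impurity) with a random
  feature subset per split (defaults: 100 trees, mtry 2, depth ≤ 12),
  likewise implemented in-package and seeded for determinism.

**Tie-break rule.** Exact discriminant or vote ties go to *other*. This is
deliberately conservative: it can only understate, never inflate, seagrass
area claims. The same asymmetry appears at the SVM decision boundary.

The 40/60 split (`splitSamples()`) is stratified per class at pixel level,
with `roundHalfAwayFromZero(fraction × n)` training samples per class so
counts are exactly predictable. Stratifying per polygon instead would avoid
spatial-autocorrelation leakage between training and assessment pixels from
one polygon; pixel-level stratification was chosen because ground truth may
arrive as points as well as polygons, and the synthetic sampler draws
points. Users with large polygons should split by polygon upstream.

## Accuracy assessment

`metricsFromCounts()` computes, from a k×k table with **rows = classified,
columns = reference**: user accuracy (1 − commission) per row, producer
accuracy (1 − omission) per column, overall accuracy (trace/N) and Cohen's
kappa $\kappa = (p_o - p_e)/(1 - p_e)$ with
$p_e = \sum_i \text{row}_i\,\text{col}_i / N^2$. Metrics are stored at full
precision; `paperRound()` provides the 2-dp display convention of published
accuracy tables, and reports show both — full precision keeps any rounding
inconsistency in a published table auditable. Per-class metrics with a zero
denominator are reported as undefined (`NA`), never as 0.

## Change analysis

`overlayChange()` maps the pixel pair (baseline, current) to stable
seagrass (1,1), loss (1,0), gain (0,1) and stable other (0,0), propagating
nodata. It **refuses** inputs on different grids rather than resampling
silently: temporal comparisons are only meaningful over the same
co-registered area, and silent resampling would bias surface-cover
estimates. `summarizeChange()` converts counts to hectares
(`pixelSize²/10⁴`; 0.01 ha per 10 m pixel) and derives the exact epoch
totals stable + loss and stable + gain.

## The synthetic world

`generateScene()` emulates the structure of a shallow coastal study area:

* bathymetry as a linear shore-to-offshore gradient spanning 0–45 m plus
  low-amplitude spatially correlated noise (smoothed Gaussian noise; real
  terrain is autocorrelated, and white noise would make depth gradients
  locally absurd);
* a contiguous sandy calibration strip where the gradient sits at 1.3–4.7 m,
  with depths held inside 1–5 m and the class forced to bare sand, exported
  as a polygon;
* seagrass patches grown as contiguous blobs in the 1–11 m belt outside the
  strip, region-grown to the requested area fraction (default 0.2 of the
  belt, 6 patches);
* a deep zone (> 40 m). Beyond 40 m the seafloor is rendered **optically
  dark** (bottom reflectance = $R_\infty$, i.e. zero contrast): deep bottoms
  contribute no measurable signal in reality, whereas extrapolating bright
  sand to 45 m under the two-parameter model would leave a residual bottom
  term of ~0.02 in the blue band and bias the deep-water estimator. This is
  the modelling choice that makes the >40 m zone usable for estimating
  $R_\infty$, exactly as deep water is used in practice;
* surface reflectance via the forward model plus additive Gaussian noise
  (default sd 0.002, a plausible per-band surface-reflectance noise level
  for atmospherically corrected 10 m imagery), clipped at 0;
* balanced labelled samples (default 600) drawn from cells shallower than
  20 m.

Default bottom spectra — sand (0.12, 0.10, 0.08), seagrass
(0.035, 0.045, 0.020) — give the green/blue contrast of dense vegetation
against bright sediment; they are configuration defaults, not measured
values. `generateEpochPair()` derives a second epoch by removing
`roundHalfAwayFromZero(loss × n₁)` seagrass cells as contiguous blocks and
growing the analogous number of gain cells elsewhere in the belt (fractions
are relative to the epoch-1 seagrass count), so planted stable/loss/gain
counts are known exactly. All outputs are deterministic under the config
seed.

**What a green test does not establish.** The generator's classes are
spectrally homogeneous (one spectrum per class), its noise is white and
Gaussian, its water column is horizontally uniform and its bathymetry is
error-free. Real scenes have within-class spectral mixtures, spatially
structured noise (waves, sun glint), patchy turbidity and bathymetry error —
all of which degrade accuracy in ways the synthetic tests cannot measure.
Tests on this world validate the *machinery* (estimators, inversion,
classifiers, bookkeeping), not real-scene accuracy, which is why published
real-scene accuracies (~84% overall) are far below the near-perfect scores
on synthetic scenes.

## Numerical choices and edge cases

* Nodata is `NA` internally; the on-disk sentinel (default −9999) is
  configurable. Rasters are plain-text ESRI ASCII grids written with 17
  significant digits, so write→read round-trips are exact in double
  precision; no GeoTIFF-capable R library is available in the supported
  toolchain, and `.asc` is readable by every GIS.
* All vector-on-raster membership uses the **pixel-centre rule**
  (even-odd ray casting): symmetric, standard in land-cover work, and
  trivially auditable per pixel.
* Depths are stored positive-down; negative-down sources must be negated at
  ingest. Bilinear is the default for resampling continuous depth, nearest
  for categorical grids.
* Degenerate regressions (constant depth in the calibration zone) are
  refused, not returned as `NaN`.
* Integer counts from fractions always use round-half-away-from-zero so
  split and change tests can assert exact counts.
* Seeds: every stochastic function takes a `seed` and restores the caller's
  RNG state; derived stage seeds stay below 2³¹.
* The Monte-Carlo check on the deep-water estimator bounds the *mean
  absolute* deviation of the median by $2\sigma/\sqrt{n}$ across seeds: the
  sampling sd of a Gaussian median is $1.25\sigma/\sqrt{n}$, so a per-seed
  bound at $2\sigma/\sqrt{n}$ (~1.6 sigma) would fail by construction in
  ~11% of draws; the mean-deviation reading is the attainable one.

## Known limitations

* One $K_d$ per band per scene: horizontally varying turbidity is not
  modelled.
* No reprojection: all inputs must share a CRS; no atmospheric or sun-glint
  correction (a bottom-of-atmosphere product is assumed given).
* Two classes only; seagrass species cannot be separated at this resolution
  and are out of scope.
* Classification uncertainty is not propagated into change-area confidence
  intervals; the confusion matrix quantifies it per epoch, and change areas
  should be read with that uncertainty in mind.
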