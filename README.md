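# SeagrassDyn

Seagrass meadows are declining worldwide, and mapping their extent over time
is a prerequisite for assessing the status of coastal ecosystems.
**SeagrassDyn** is an R package for mapping seagrass from shallow-water
multispectral imagery (three visible bands at 10 m resolution, e.g.
Sentinel-2 B2/B3/B4 surface reflectance) and for quantifying meadow dynamics
between two epochs. It is aimed at marine ecologists and remote-sensing
practitioners who have a surface-reflectance scene, a bathymetry layer and
some field-mapped ground truth.

## The model

Over optically shallow water, the surface reflectance recorded per band is

```
R_w = R_inf + (R_b − R_inf) · exp(−2 · K_d · Z)
```

where `R_inf` is the reflectance of an infinitely deep water column, `R_b`
the bottom reflectance, `K_d` the band-specific diffuse attenuation
coefficient (m⁻¹) and `Z` the water depth (m, positive down). The package

1. estimates `R_inf` as the per-band **median over pixels deeper than
   40 m** (where the bottom signal is negligible);
2. estimates `K_d` from an ordinary least-squares regression of
   `ln(R_w − R_inf)` on depth over a **uniform sandy calibration zone at
   1–5 m**, whose slope is exactly `−2 K_d` under the model;
3. inverts the equation per pixel to a **bottom-reflectance composite**
   `R_b = R_inf + (R_w − R_inf) · exp(+2 K_d Z)`, clipped to depths ≤ 20 m
   where the inversion is reliable;
4. classifies the composite into **seagrass / other** with a from-scratch
   Gaussian maximum-likelihood classifier, an RBF-kernel SVM or a bagged
   random-trees ensemble, using a stratified 40/60 training/assessment
   split;
5. assesses each map with a **confusion matrix** (user/producer/overall
   accuracy, omission/commission, Cohen's kappa); and
6. overlays a baseline map with the classification into
   **stable / loss / gain** categories with hectare areas
   (1 px = 0.01 ha at 10 m).

A synthetic coastal-scene generator (`generateScene()`,
`generateEpochPair()`) produces fully specified worlds — depth gradient
0–45 m, sandy calibration strip, seagrass patches at 1–11 m, sensor noise —
so the entire pipeline is testable without external data.

## Worked example

```r
library(SeagrassDyn)

cfg <- ScenarioConfig(seed = 1)            # default synthetic coastal world
gen <- generateScene(cfg)

rInf <- estimateDeepWaterReflectance(gen$scene)
rInf
#> DeepWaterEstimate: R_inf = (0.0200, 0.0136, 0.0045) from 2252 pixels > 40 m

fit <- fitAttenuation(gen$scene, gen$calibrationZone, rInf)
fit
#> AttenuationFit (log_contrast, n = 1440):
#>   B2_490: Kd = 0.0197 m^-1 (slope -0.0394, R^2 0.745)
#>   B3_560: Kd = 0.0301 m^-1 (slope -0.0601, R^2 0.830)
#>   B4_665: Kd = 0.1046 m^-1 (slope -0.2092, R^2 0.946)

rb    <- correctWaterColumn(gen$scene, rInf, fit)     # bottom reflectance
s     <- samplesFromGrids(gen$samples, rb)
split <- splitSamples(s, 0.4, seed = 1)
map   <- predictMLC(trainMLC(split@train), rb)
buildConfusion(map, split@test)
#> ConfusionSummary (rows = classified, columns = reference)
#>           reference
#> classified seagrass other
#>   seagrass      180     0
#>   other           0   180
#> User accuracy:      seagrass 1.0000, other 1.0000
#> Producer accuracy:  seagrass 1.0000, other 1.0000
#> Overall accuracy:   1.0000 (1.00)
#> Kappa:              1.0000 (1.00)
```

The deep-water medians and regression slopes recover the optical constants
the scene was generated with (`R_inf` = 0.0200/0.0136/0.0045, `K_d` =
0.0197/0.0303/0.1046 m⁻¹), and on this low-noise world the classifier
reproduces the truth map. For two-epoch dynamics:

```r
pair <- generateEpochPair(cfg, lossFraction = 0.15, gainFraction = 0.15)
summarizeChange(overlayChange(classMap(pair$t1), classMap(pair$t2)))
#> ChangeSummary (pixel size 10 m):
#>   stable_other        18556 px      185.56 ha
#>   stable_seagrass       476 px        4.76 ha
#>   loss                   84 px        0.84 ha
#>   gain                   84 px        0.84 ha
#>   epoch-1 seagrass       5.60 ha; epoch-2 seagrass       5.60 ha
```

Stable + loss always equals the epoch-1 seagrass area and stable + gain the
epoch-2 area, exactly.

A thin command-line wrapper is installed as `exec/seagrassdyn` with
subcommands `simulate`, `correct`, `classify`, `assess`, `change` and
`run-all` (exit codes: 0 success, 2 validation error, 3 data error).

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch on the default
synthetic world — scene simulation, water-column correction, all three
classifiers with confusion-matrix assessment, and the two-epoch change
summary — printing the recovered optical constants, accuracies and areas,
and writes its JSON report to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/seagrass-mapping-methods.Rmd` describes the model and its
assumptions, every tunable parameter with its default and rationale, what
the synthetic generator does and does not emulate, numerical edge cases and
known limitations.
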