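# saviopt

Calibrating the SAVI soil adjustment factor for leaf area index estimation
in dense canopies.

## The problem

Leaf area index (LAI) — one-sided green leaf area per unit ground area — is
routinely estimated from vegetation indices (VIs) built on red and
near-infrared (NIR) surface reflectance.  Over dense canopies every such
index *saturates*: the red band stops responding to additional leaf layers,
the derivative dVI/dLAI collapses, and linear LAI–VI regressions degrade or
even flip sign.

The soil-adjusted vegetation index

```
SAVI = (N − R) (1 + X) / (N + R + X)
```

carries an additive soil adjustment factor `X`, classically recommended at
0.5 and assumed to live in [0, 1].  Geometrically, SAVI's level sets form a
pencil of lines through the point `(−X/2, −X/2)` of the red–NIR plane, and
`X` is well chosen when that point matches where the actual vegetation
isolines (constant-LAI loci under varying soil background) converge.  In
dense canopies the isolines intersect the soil line `N = a·R + b` in the
**first quadrant**, so the matching `X` is **negative**.  This package
estimates that optimum by exhaustive search: for every `X` on a grid
(default `[−0.3, 1]` in steps of 0.001, 1301 points) it fits

```
LAI = c · SAVI(X) + d
```

by OLS and reports the signed coefficient of determination
`R²s = sign(c) · r²` together with the two-sided Wald-t P of the slope; the
calibrated factor `x_opt` maximises `R²s`.  The signed convention keeps
saturation-driven negative associations visible instead of hiding them in
an always-positive `R²`.

Around the estimator the package provides the supporting stages of the
analysis: the five index formulas (NDVI, SAVI, TSAVI, EVI, GRVI), pixel and
scene screening (cloud mask, NDVI/GRVI vegetation mask, ±8/±16-day temporal
matching of LAI composites, same-day merging, field-record cleaning),
quarterly aggregation with classical multiplicative seasonal decomposition,
an augmented Dickey–Fuller stationarity test with MacKinnon response-surface
critical values and p-values, and a Beer–Lambert canopy simulator that
reproduces soil-line/isoline geometry so everything is testable offline.

## Worked example

```r
library(saviopt)

lai    <- simulate_lai_series(mean_lai = 5.5, noise_sd = 0.3,
                              missing_prob = 0, cadence_days = 8, seed = 21)
scenes <- simulate_scenes(lai, seed = 22)
fit    <- savi_search(data.frame(red = scenes$red, nir = scenes$nir,
                                 lai = lai$lai))
summary(fit)
#> Exhaustive SAVI soil-adjustment-factor search
#>   grid: [-0.3, 1] by 0.001 (1301 points), n = 344
#>   x_opt = -0.055  (signed R-squared 0.8013, P 4.601e-122)
#>   regression at optimum: LAI = 119.0723 * SAVI + -86.9101
#>   reference: X = 0 gives R2s = 0.7633; X = 0.5 (classical) gives R2s = 0.5927
```

A canopy with mean LAI 5.5 is simulated over varying soil background and
the search calibrates `X`.  The optimum lands at `x_opt = −0.055` —
negative, as the first-quadrant isoline geometry predicts — and clearly
beats the classical `X = 0.5` (signed R² 0.80 vs 0.59).  The large slope at
the optimum reflects how small the SAVI dynamic range becomes once the
soil signal is cancelled.  The geometry behind the sign:

```r
isoline_geometry(5.5)
#> Vegetation isoline: NIR = 18.77 * red + -0.8556
#>   intersects soil line at (0.05097, 0.1012) [first quadrant]
```

`predict(fit, newdata)`, `residuals(fit)` and `plot(fit)` give LAI
predictions at the calibrated factor, their errors (RMSE 0.35 LAI here),
and the R²/slope/P curves against `X`.  `run_pipeline(pipeline_config())`
executes the whole workflow — simulation, indices, screening, temporal
matching, decomposition, stationarity test, search — and writes stage CSVs
plus a JSON manifest.

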