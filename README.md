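# defoCarbon

Biophysical carbon costs of tropical deforestation: how much *extra*
aboveground biomass (AGB) do the forests left standing lose because
deforestation itself warms and dries the regional climate?

Large-scale forest clearing reduces evapotranspiration and surface
roughness, which lowers rainfall and raises air temperature across the
remaining tropical forest. Since tropical AGB increases with mean annual
precipitation (MAP) and decreases with mean annual temperature (MAT), this
climate shift is an additional, usually uncounted, carbon loss on top of
the carbon removed with the cleared trees. `defoCarbon` implements the full
estimation chain for ecosystem and climate scientists who want to quantify
that cost, its uncertainty, and the implied carbon–climate feedback — and
ships a synthetic-data generator so every stage runs and is testable
offline.

## The model

* **Climate response.** Per-model deforestation-minus-control deltas over
  the last 30 simulated years; multimodel mean, cross-model SD (n−1), and a
  sign-agreement mask (≥ 6 of 8 models). Absolute rainfall change is the
  relative change times the *observed* climatology, which keeps simulated
  rainfall biases out of the result.
* **Biomass–climate sensitivity.** Spatial OLS across the tropical belt,

  `AGB = a·MAP + b·MAT + ε`,

  fitted globally and in moving rainfall windows (±500 mm yr⁻¹ at levels
  600…3100 mm yr⁻¹) with per-coefficient significance at *P* < 0.001.
* **Carbon cost.** Per cell, `ΔAGB = s_P·ΔP + s_T·ΔT`, with sensitivities
  looked up at each cell's post-deforestation background rainfall (zero
  where the windows are not significant — no predicted loss in the wettest
  areas). Direct loss = tree-cover change × the observed cover–biomass
  slope (≈ 20 Mg C ha⁻¹ per 10% cover). Percent additionality =
  100·biophysical/direct. Uncertainty by quadrature:
  `σ = sqrt((a·σ_ΔP)² + (b·σ_ΔT)²)`.
* **Feedback and history.** `γ = ΔC/ΔT` (Mg C ha⁻¹ °C⁻¹; ×0.1 for
  kg C m⁻² °C⁻¹) for CO₂-driven vs deforestation-driven warming, and a
  linear-in-deforestation scaling that attributes historical forest loss to
  cumulative regional carbon losses in Tg C.

## Worked example

Published regional inputs are printed numbers, so the headline arithmetic
is reproducible directly:

```r
library(defoCarbon)

## Amazon: uncertainty of the biophysical loss by quadrature propagation
propagateUncertainty(a = 0.034, b = -0.32, sigmaP = 105, sigmaT = 0.5)
#> [1] 3.574972          # Mg C ha-1, prints as 3.6

## additionality: biophysical relative to direct loss
round(percentAdditionality(-5.0, -98.3), 1)
#> [1] 5.1               # percent

## historical attribution, Amazon basin 1850-2015
sc <- scaleHistoricalResponse(11.5, -44.7, -150, -6.7, 0.5)
cumulativeRegionalLoss(sc, sP = 0.034, sT = 0.32, areaKm2 = 5.84e6,
                       region = "amazon", histLoss = 11.5,
                       refCoverChange = -44.7)
#> HistoricalScenario "amazon": 11.5% historical forest loss (factor 0.257)
#>   scaled deltas: -38.6 mm yr-1 (-1.72%), 0.129 degC
#>   per-ha: rain -1.312 + warm 0.041 = -1.271 Mg C ha-1; total -742.2 Tg C
```

The scaled deltas (−38.6 mm yr⁻¹, +0.13 °C), the per-hectare rainfall loss
(−1.3 Mg C ha⁻¹) and the basin total (≈ 740 Tg C) are the published
attribution chain. The full pipeline on the synthetic world:

```r
cfg <- syntheticConfig(seed = 1, nYears = 40, rampYears = 10)
res <- runPipeline(cfg, outDir = "artifacts")
round(res$table2[, c("dPrel", "dPmm", "dT", "direct", "biophys", "percent")], 2)
#>   dPrel    dPmm    dT direct biophys percent
#> 1 -7.13 -159.83  0.35 -77.54   -4.85    6.25
#> 2 -0.36   -5.60  0.01 -45.86   -0.19    0.41
#> 3 -1.21  -30.83 -0.15 -81.91   -0.37    0.46
```

Row 1 is the Amazon analog: an ensemble-drawn 7.1% rainfall decline
(−160 mm yr⁻¹) and 0.35 °C warming produce a biophysical loss of
4.9 Mg C ha⁻¹ — 6.3% on top of the direct loss. The wet maritime-continent
analog (row 3) shows essentially no additional loss: its background
rainfall sits in the saturated regime where the windows lose significance.
`runPipeline()` also writes the sensitivity curve, regional tables, gamma
maps, historical scenarios and a manifest as plain-text artifacts;
`inst/scripts/defocarb.R` is a command-line wrapper over the same calls.

## Package layout

* `R/` — S4 classes (`Field`, `FieldStack`, `RegionMask`, `EnsembleDelta`,
  `SensitivityCurve`, `RegressionFit`, `GammaField`, `HistoricalScenario`,
  `SyntheticConfig`) and the stage functions.
* `vignettes/biophysical-carbon-cost.Rmd` — the methods vignette: model,
  assumptions, synthetic-world design, numerical choices, limitations.
* `tests/testthat/` — unit, property and acceptance tests.
* `scripts/acceptance.R`, `inst/scripts/defocarb.R` — entry points.
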