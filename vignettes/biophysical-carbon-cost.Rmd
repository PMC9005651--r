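---
title: "Estimating the biophysical carbon cost of tropical deforestation"
author: "defoCarbon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the biophysical carbon cost of tropical deforestation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(defoCarbon)
```

## The problem

Clearing tropical forest removes the carbon stored in the cleared biomass
(the *direct* loss), but it also changes the regional climate: less
evapotranspiration and surface roughness mean less rainfall and higher air
temperature over the remaining forest. Because tropical aboveground biomass
(AGB) increases with mean annual precipitation (MAP) and decreases with mean
annual temperature (MAT), this deforestation-induced climate change imposes
an *additional* carbon loss on the forests left standing — a biophysical
carbon cost that carbon-accounting schemes built around project boundaries
miss. `defoCarbon` implements the estimation chain for that cost:

1. **Climate response.** Per-model deforestation-minus-control deltas of
   precipitation and temperature (last-30-year means), summarized across an
   ensemble with cross-model SDs and sign-agreement masks.
2. **Biomass sensitivity.** A spatial regression of observed AGB on climate,
   `AGB = a * MAP + b * MAT + e`, fitted globally and within moving rainfall
   windows (±500 mm yr⁻¹ around levels 600…3100 mm yr⁻¹) because the
   sensitivity depends on the rainfall regime.
3. **Carbon cost.** Per-cell biophysical change
   `dAGB = s_P * dP + s_T * dT`, with `(s_P, s_T)` looked up from the window
   curve at each cell's post-deforestation background rainfall; direct loss
   from the observed tree-cover–biomass slope; percent additionality as
   their ratio; uncertainty by quadrature,
   `sigma = sqrt((a sigma_P)^2 + (b sigma_T)^2)`.
4. **Feedback and history.** Carbon–climate feedback parameters
   `gamma = dC / dT` for both CO₂-driven and deforestation-driven warming,
   and a linear-scaling attribution of historical forest loss to cumulative
   regional carbon losses.

Everything runs offline on a synthetic world that reproduces the
*statistical* structure the analysis relies on; no archive downloads are
needed.

## The estimation chain and its assumptions

**Deltas.** For each ensemble member the deforestation effect is the
difference of the last-30-year means between the deforested and the control
run (`deforestationDelta()`). Relative precipitation change uses each
model's own control climatology as denominator; absolute changes are the
product of the multimodel-mean relative change with the *observed*
climatology (`absolutePrecipChange()`), which stops simulated rainfall
biases from leaking into the absolute numbers. Cross-model statistics use
the n−1 denominator; a cell is "robust" when at least `ceiling(0.75 n)`
models (six of eight) share the sign of the multimodel mean, with exact
zeros agreeing with neither sign — a deliberately conservative tie rule.
Regional rows summarize *per-model regional means* across models, the only
construction consistent with using the cross-model SD in the quadrature
propagation later.

**Sensitivity.** The regression is plain OLS, unweighted (no cos-latitude
weights; near the equator the difference is negligible) and includes an
intercept by default: the zero-intercept form makes R² and RMSE
non-comparable across models and data sets. The analysis domain is
23°S–23°N, MAP ≥ 100 mm yr⁻¹, land fraction ≥ 0.5. Windows are closed
intervals, cells may belong to several windows (inherent to the method),
and windows with fewer than 30 cells are reported but flagged not
significant; 30 cells is our floor, chosen so a three-parameter fit never
rests on a handful of points. Each climate coefficient carries its own
two-sided t-test; the package flags both per-coefficient significance
(`sigA`, `sigB`) and the joint rule. The lookup (`sensitivityLookup()`)
zeroes non-significant coefficients before interpolating linearly between
window levels, so cells bracketed by two non-significant levels get exactly
zero sensitivity — no additional loss is predicted for the wettest areas —
and cells at the edge of the significant range are interpolated toward
zero. *Why per-coefficient masking is the default:* with a temperature
coefficient of −0.32 Mg C ha⁻¹ °C⁻¹ against a residual scale of roughly
30 Mg C ha⁻¹, no realistic sample size makes the temperature term
t-significant at 0.001 inside a window; a joint rule would therefore zero
the precipitation sensitivity everywhere and the entire cost stage with it.
The rainfall coefficient, which carries the signal, is masked by its own
test instead.

**Cost.** Per-region direct loss multiplies the simulated tree-cover change
by a region-specific cover–biomass slope fitted on the region's own cells;
its SD is the cover-change SD times the same slope. Regional biophysical
loss is the area-weighted mean of the per-cell product (not the product of
regional means); its SD is the quadrature propagation with regional climate
SDs, assuming independent precipitation and temperature errors. All losses
are carried as signed changes (negative = loss).

**Feedback.** Gamma maps divide the carbon change by warming per cell and
mask |dT| < 0.1 °C — the threshold is ours; without it near-zero
denominators dominate the map. Regional gamma divides regional aggregates,
never averages cellwise ratios.

**History.** The deforestation–climate relationship is assumed linear in
the deforestation level, so a historical primary-forest fraction loss
scales the idealized deltas by `hist / |ref|`. The sign of the warming term
is genuinely ambiguous: at the Amazon's background rainfall the local
window fit gives a (small) positive temperature coefficient — warming as a
slight gain — while the tropics-wide coefficient is negative. The pipeline
computes both variants (`global`, `localWindow`) and reports both; the
basin totals printed in the literature correspond to the warming-as-gain
convention.

## The synthetic world

`syntheticConfig()` fixes the study conditions; `generateObservationBundle()`,
`generateRegionMasks()`, `generateEnsemble()` and `generateCo2Runs()` build
the data. The generator emulates exactly the features the pipeline
exploits, and nothing else:

* **Climate fields.** Idealized continental blocks (a tropical America with
  an east–west rainfall gradient, an Africa with dry subtropical belts, a
  sparse maritime-continent island pattern, monsoon-type and semi-arid
  blocks) give MAP a realistic span (~40–3600 mm yr⁻¹, including desert
  cells below the 100 mm filter) with regional climatologies near the
  observed ones (Amazon-box ≈ 2240, Congo-box ≈ 1550, maritime ≈
  2550 mm yr⁻¹). MAT decreases with MAP (correlation ≈ −0.7) and is more
  variable where it is dry, with an independent relief-like pattern so the
  two regressors are not collinear.
* **Biomass.** `AGB = intercept + a·MAP_eff + b·MAT` with the documented
  default coefficients (a·100 = 3.4, b = −0.32); above 2400 mm yr⁻¹ the
  rainfall dependence flattens to a 25% residual slope (`satSlope`). A
  fully flat wet regime would drag the tropics-wide OLS refit visibly below
  the injected coefficient, which contradicts how the real tropics-wide fit
  behaves; with the residual slope the refit stays within sampling error of
  the injected value while windows centered above ~2500 mm yr⁻¹ still lose
  significance, matching the observed 2400 mm cutoff qualitatively. Noise
  is mean-preserving multiplicative lognormal with SD proportional to the
  surface (clamped to 4–45 Mg C ha⁻¹), mirroring the relative-error
  structure of satellite biomass retrievals; it leaves the conditional mean
  exactly on the surface, so OLS recovery is unbiased despite the AGB ≥ 0
  constraint. A homoscedastic Gaussian option exists
  (`noiseModel = "homoscedastic"`), but with a 32 Mg C ha⁻¹ SD it clips
  almost every dry cell at zero and is unusable for recovery checks. The
  residual structure of the real maps is not characterized anywhere we can
  check, so this is a modelling choice, not an inference.
* **Tree cover** saturates with biomass, `tc = 0.92 (1 − exp(−AGB/120))`
  plus noise — hence, on average, a monotone saturating function of MAP.
  The scale was calibrated once so the cover–biomass regression lands in
  the observed 19–22 Mg C ha⁻¹ per 10% band (the synthetic tropics-wide
  value is ≈ 20.8).
* **Ensemble.** Each model has its own RNG stream derived from the master
  seed (adding members never perturbs earlier ones), a multiplicative
  precipitation-climatology bias (SD 5%), and regional responses drawn from
  the documented per-region normal distributions (e.g. Amazon relative
  rainfall −6.7 ± 4.7%, warming 0.5 ± 0.5 °C, cover −44.7 ± 6.0 pp). The
  deforested run ramps the response linearly over 50 years and holds it,
  with interannual noise (4% of climatology; 0.3 °C) so the delta estimator
  is genuinely exercised. One caveat: where the drawn cover loss exceeds
  the locally available synthetic cover, the realized cover delta truncates
  (regional means ≈ −34 pp instead of −44.7) — cover cannot go negative.
  Recovery tests therefore check the unbounded variables.
* **CO₂ runs** share a fertilization-driven AGB growth; the fully coupled
  run additionally feels an injected per-region feedback parameter times a
  warming that ramps to 3.5 °C over 140 years, so the first-20/last-20
  difference recovers the injected gamma.

**What passing tests do not show.** The generator is linear-by-construction
plus noise: it cannot reveal misspecification of the linear model on real
data, spatial autocorrelation of residuals (the inference is plain OLS, as
in the original analysis), basin-shape effects, ENSO-like variability, or
teleconnections. Tests on it validate the *estimation machinery*, not the
earth-system conclusions.

## Numerical choices

* Grid: 1° cell centers, latitudes strictly inside 23°S–23°N, longitudes in
  [−180, 180); masks and fields must share a grid exactly — no implicit
  regridding. Area weights are cos(latitude of cell center).
* Missing data are `NA` throughout; every spatial statistic uses
  pairwise-complete cells and reports the effective cell count (attribute
  `n`).
* Bilinear regridding clamps outside-hull targets to the nearest inside
  position; a target whose 4-point neighbourhood contains missing values is
  `NA`.
* OLS is solved by QR; `robustSE = TRUE` switches to HC1
  heteroskedasticity-consistent standard errors (used in the recovery
  tests, since the generator's noise is heteroscedastic by design).
* Degenerate windows (rank-deficient or < 4 cells) are reported as `NA`
  rows flagged not significant, never fatal.
* Field I/O is plain-text CSV plus a JSON sidecar with 17-significant-digit
  formatting, so write→read round trips are bit-exact.
* Combined additionality rounds half *up* (`floor(x + 0.5)`) for table
  output; round-half-even would turn 10 + 0.5 into 10.

## Problem sizes used in the tests

The checked configurations are the package's own choices for a
desk-scale validation: the observation bundle uses the full 46 × 360
tropical belt (~4000 analysis cells after filtering); coefficient-recovery
checks run 100 seeds of that bundle; ensemble-distribution checks use 50
members on a reduced belt; end-to-end pipeline checks run ten seeds of the
full eight-member ensemble with a shortened run (10-year ramp + 30-year
window — the injected response distributions, and hence the estimated
deltas, are unchanged by the shorter ramp).

## Known limitations

* The temperature term is weakly identified at realistic noise levels; its
  window-level sign wobbles around zero, which is precisely why the
  historical warming term is reported under both sign conventions.
* Percent additionality divides regional mean losses (consistent with the
  printed ratio identities); averaging cellwise percentages would weight
  regions differently.
* Basin masks are synthetic boxes intersected with land; real basin
  shapefiles can be supplied as masks but are not bundled.
* Local edge-effect percentages in the combined-additionality table are
  literature constants passed in as configuration, never computed here.
* The CO₂-run generator is an ensemble-mean emulator; it exercises the
  gamma machinery but carries no member spread.
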