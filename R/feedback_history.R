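# Carbon-climate feedback parameters (gamma) and historical linear-scaling
# attribution of biophysical AGB losses.

.gammaField <- function(num, den, lat, lon, kind, threshold) {
  g <- num / den
  g[abs(den) < threshold] <- NA  # tiny denominators would dominate the map
  new("GammaField",
      field = Field(g, lat, lon, units = "Mg C ha-1 degC-1",
                    name = paste0("gamma_", kind)),
      kind = kind, threshold = threshold)
}

#' CO2-driven carbon-climate feedback parameter
#'
#' From the idealized transient CO2-increase experiments:
#' `gamma = (dC_full - dC_bgc) / dT_full` per cell, where `dC_full` and
#' `dC_bgc` are the AGB changes of the fully coupled and the
#' biogeochemically coupled run and `dT_full` the fully coupled warming,
#' each a last-20-minus-first-20-year difference (see [timeWindowMean]).
#' Cells with `|dT_full|` below `threshold` are masked. A negative gamma is
#' a carbon loss per degree of warming, the usual tropical-land sign.
#'
#' @param dCfull,dCbgc AGB change [Field-class]s (Mg C ha-1).
#' @param dTfull warming [Field-class] (degC).
#' @param threshold |dT| masking threshold, degC (default 0.1).
#' @return A [GammaField-class] (Mg C ha-1 degC-1; multiply by 0.1 for
#'   kg C m-2 degC-1).
#' @export
gammaCo2 <- function(dCfull, dCbgc, dTfull, threshold = 0.1) {
  stopifnot(is(dCfull, "Field"), is(dCbgc, "Field"), is(dTfull, "Field"))
  if (!.sameGrid(dCfull, dCbgc) || !.sameGrid(dCfull, dTfull))
    stop("inputs are on different grids")
  .gammaField(dCfull@values - dCbgc@values, dTfull@values,
              dCfull@lat, dCfull@lon, "co2", threshold)
}

#' Deforestation-driven carbon-climate feedback parameter
#'
#' Ratio of the biophysical AGB change to the deforestation-induced
#' warming, `gamma = dC / dT` per cell; cells with `|dT| < threshold`
#' are masked.
#'
#' @param dC biophysical AGB change [Field-class] (Mg C ha-1), e.g. the
#'   `total` of [biophysicalAgbChange].
#' @param dT multimodel-mean deforestation warming [Field-class] (degC).
#' @inheritParams gammaCo2
#' @return A [GammaField-class].
#' @export
gammaDeforest <- function(dC, dT, threshold = 0.1) {
  stopifnot(is(dC, "Field"), is(dT, "Field"))
  if (!.sameGrid(dC, dT)) stop("inputs are on different grids")
  .gammaField(dC@values, dT@values, dC@lat, dC@lon, "deforest", threshold)
}

#' Regional gamma from regional aggregates
#'
#' Regional gamma is the ratio of the area-weighted regional carbon change
#' to the area-weighted regional warming (not the mean of cellwise ratios,
#' which is dominated by small-denominator cells).
#'
#' @param dC,dT [Field-class]s as in [gammaDeforest] (for the CO2 variant
#'   pass `dC = dCfull - dCbgc`).
#' @param mask a [RegionMask-class].
#' @return gamma, Mg C ha-1 degC-1.
#' @export
regionalGamma <- function(dC, dT, mask) {
  as.numeric(areaWeightedMean(dC, mask)) /
    as.numeric(areaWeightedMean(dT, mask))
}

#' Scale the idealized climate response to a historical deforestation level
#'
#' Assuming the diagnosed deforestation-climate relationship is linear in
#' the deforestation level, a historical primary-forest fraction loss
#' scales the idealized-experiment deltas by
#' `f = histLoss / |refCoverChange|`.
#'
#' @param histLoss historical primary-forest fraction loss, % (>= 0).
#' @param refCoverChange reference tree-cover change of the idealized
#'   experiment, % (non-zero; sign ignored).
#' @param refPmm,refPrel,refT reference deltas (mm yr-1, %, degC).
#' @return list with `factor`, `dPmm`, `dPrel`, `dT`.
#' @examples
#' scaleHistoricalResponse(11.5, -44.7, -150, -6.7, 0.5)$dPmm  # ~ -38.6
#' @export
scaleHistoricalResponse <- function(histLoss, refCoverChange,
                                    refPmm, refPrel, refT) {
  if (refCoverChange == 0) stop("reference cover change must be non-zero")
  if (histLoss < 0 || histLoss > abs(refCoverChange))
    stop("historical loss must lie between 0 and the reference magnitude")
  f <- histLoss / abs(refCoverChange)
  list(factor = f, dPmm = f * refPmm, dPrel = f * refPrel, dT = f * refT)
}

#' Cumulative regional biophysical loss for a historical scenario
#'
#' Combines scaled climate deltas with the observational sensitivities:
#' per-hectare change `= sP * dPmm + sT * dT`; the regional total is the
#' per-hectare change times the basin area (1 km2 = 100 ha), in Tg C.
#'
#' The sign of the warming term depends on the temperature coefficient at
#' the region's background rainfall: the reported basin totals treat
#' warming as a small gain (locally positive coefficient from the
#' moving-window fit), while the tropics-wide coefficient is negative.
#' Pass the `sT` you intend; both conventions are legitimate and
#' [runPipeline] reports both.
#'
#' @param scaled list from [scaleHistoricalResponse].
#' @param sP,sT sensitivities (Mg C ha-1 per mm yr-1, per degC).
#' @param areaKm2 region area, km2.
#' @param region region name.
#' @param histLoss,refCoverChange echoed scenario metadata (%).
#' @return A [HistoricalScenario-class].
#' @export
cumulativeRegionalLoss <- function(scaled, sP, sT, areaKm2,
                                   region = "region",
                                   histLoss = NA_real_,
                                   refCoverChange = NA_real_) {
  if (areaKm2 <= 0) stop("area must be positive")
  rain <- sP * scaled$dPmm
  warm <- sT * scaled$dT
  net <- rain + warm
  totalTg <- net * areaKm2 * 100 / 1e6  # Mg C ha-1 * ha -> Tg C
  new("HistoricalScenario", region = region,
      histLoss = if (is.na(histLoss)) scaled$factor * abs(refCoverChange)
                 else histLoss,
      refCoverChange = if (is.na(refCoverChange)) NA_real_ else refCoverChange,
      factor = scaled$factor, dPmm = scaled$dPmm, dPrel = scaled$dPrel,
      dT = scaled$dT, perHaRain = rain, perHaWarm = warm, perHaNet = net,
      areaKm2 = areaKm2, totalTgC = totalTg)
}
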