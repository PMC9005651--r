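# Combining climate deltas with the moving-window sensitivity curve:
# background rainfall, per-cell sensitivity lookup, biophysical AGB change
# and its precipitation/temperature partition, direct deforestation losses
# from the tree-cover--biomass relationship, percent additionality and
# quadrature uncertainty propagation.

#' Post-deforestation background rainfall
#'
#' The rainfall level at which each remaining-forest cell operates after
#' deforestation: the observed climatology plus the deforestation-induced
#' relative change, `bg = climatology * (1 + dP_rel / 100)`, floored at 0.
#'
#' @param climatology observed rainfall climatology [Field-class] (mm yr-1).
#' @param dPrel multimodel-mean relative rainfall change, % (Field, matrix
#'   or scalar).
#' @return [Field-class], mm yr-1.
#' @export
backgroundRainfall <- function(climatology, dPrel) {
  stopifnot(is(climatology, "Field"))
  rel <- if (is(dPrel, "Field")) dPrel@values else dPrel
  bg <- pmax(climatology@values * (1 + rel / 100), 0)
  Field(bg, climatology@lat, climatology@lon, units = "mm yr-1",
        name = "background_rainfall")
}

#' Per-cell sensitivity from the moving-window curve
#'
#' Looks up the AGB-climate sensitivities at each cell's background rainfall
#' level. Coefficients are linearly interpolated between the two bracketing
#' window levels after zeroing non-significant ones, so cells whose
#' bracketing levels are both non-significant get exactly (0, 0) -- no
#' additional loss is predicted in the wettest areas -- and cells between a
#' significant and a non-significant level are interpolated toward zero.
#' Below the lowest / above the highest level the nearest endpoint value
#' (possibly zero) is used.
#'
#' With `mode = "per-coefficient"` (default) each coefficient is masked by
#' its own significance flag; `mode = "joint"` masks both coefficients
#' wherever the joint flag is FALSE.
#'
#' @param curve a [SensitivityCurve-class].
#' @param bg background rainfall [Field-class] (mm yr-1).
#' @param mode significance masking rule (see Details).
#' @return list of two [Field-class]s: `sP` (Mg C ha-1 per mm yr-1) and
#'   `sT` (Mg C ha-1 per degC).
#' @export
sensitivityLookup <- function(curve, bg,
                              mode = c("per-coefficient", "joint")) {
  stopifnot(is(curve, "SensitivityCurve"), is(bg, "Field"))
  mode <- match.arg(mode)
  tb <- curve@table
  if (!nrow(tb)) stop("empty sensitivity curve")
  sigA <- if (mode == "joint") tb$significant else tb$sigA
  sigB <- if (mode == "joint") tb$significant else tb$sigB
  aEff <- ifelse(sigA & !is.na(tb$a), tb$a, 0)
  bEff <- ifelse(sigB & !is.na(tb$b), tb$b, 0)
  x <- as.vector(bg@values)
  if (nrow(tb) == 1L) {
    sP <- rep(aEff, length(x)); sT <- rep(bEff, length(x))
  } else {
    sP <- approx(tb$level, aEff, xout = x, rule = 2)$y
    sT <- approx(tb$level, bEff, xout = x, rule = 2)$y
  }
  dims <- dim(bg@values)
  sP[is.na(x)] <- NA; sT[is.na(x)] <- NA
  list(sP = Field(matrix(sP, dims[1], dims[2]), bg@lat, bg@lon,
                  units = "Mg C ha-1 per mm yr-1", name = "sP"),
       sT = Field(matrix(sT, dims[1], dims[2]), bg@lat, bg@lon,
                  units = "Mg C ha-1 per degC", name = "sT"))
}

#' Biophysical AGB change from deforestation-induced climate change
#'
#' Per-cell product of the climate deltas with the local sensitivities:
#' `dAGB = sP * dP_mm + sT * dT`. The precipitation and temperature
#' contributions are returned separately; they sum to the total exactly.
#'
#' @param sP,sT sensitivity [Field-class]s (or matrices/scalars).
#' @param dPmm absolute precipitation change, mm yr-1.
#' @param dT temperature change, degC.
#' @return list of [Field-class]s `total`, `precipTerm`, `tempTerm`
#'   (Mg C ha-1, signed; negative = loss). When no Field input is given the
#'   bare numeric results are returned.
#' @export
biophysicalAgbChange <- function(sP, sT, dPmm, dT) {
  grid <- NULL
  for (x in list(sP, sT, dPmm, dT)) if (is(x, "Field")) { grid <- x; break }
  val <- function(x) if (is(x, "Field")) x@values else x
  pTerm <- val(sP) * val(dPmm)
  tTerm <- val(sT) * val(dT)
  tot <- pTerm + tTerm
  if (is.null(grid))
    return(list(total = tot, precipTerm = pTerm, tempTerm = tTerm))
  asF <- function(v, nm) Field(matrix(v, length(grid@lat), length(grid@lon)),
                               grid@lat, grid@lon, units = "Mg C ha-1",
                               name = nm)
  list(total = asF(tot, "dAGB_biophys"), precipTerm = asF(pTerm, "dAGB_P"),
       tempTerm = asF(tTerm, "dAGB_T"))
}

#' Observational tree-cover--biomass slope
#'
#' OLS slope of AGB on tree-cover percentage over the analysis cells,
#' reported per 10 percentage points of cover. In the satellite
#' observations this slope is about 19-22 Mg C ha-1 per 10% cover.
#'
#' @param AGB AGB [Field-class] or matrix (Mg C ha-1).
#' @param treeCover tree-cover fraction in \[0, 1\] (converted to percent
#'   internally) or percentage if values exceed 1.
#' @param cells logical matrix of analysis cells or `NULL`.
#' @return slope, Mg C ha-1 per 10% tree cover (attribute `n` = cells used).
#' @export
treecoverAgbSlope <- function(AGB, treeCover, cells = NULL) {
  agb <- .asMatrixLike(AGB); tc <- .asMatrixLike(treeCover)
  if (max(tc, na.rm = TRUE) <= 1) tc <- tc * 100
  if (is.null(cells)) cells <- !(is.na(agb) | is.na(tc))
  y <- agb[cells]; x <- tc[cells]
  if (length(y) < 3L) stop("need at least 3 cells")
  if (sd(x) < 1e-10) stop("degenerate tree-cover variance")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  structure(slope * 10, n = length(y))
}

#' Direct AGB loss from tree-cover change
#'
#' Product of the simulated tree-cover change and the observational
#' tree-cover--biomass slope: `loss = dCover * slope / 10`. With the loss
#' sign convention (negative cover change), the result is negative.
#'
#' @param dCover tree-cover change, percentage points (negative = loss).
#' @param slopePer10 slope, Mg C ha-1 per 10% cover (positive).
#' @return AGB change, Mg C ha-1 (signed).
#' @export
directAgbLoss <- function(dCover, slopePer10) {
  if (any(slopePer10 <= 0)) stop("slope must be positive")
  dCover * slopePer10 / 10
}

#' Percent additionality of the biophysical loss
#'
#' The biophysical AGB loss expressed relative to the direct loss,
#' `100 * biophysical / direct`; both carried as signed losses, so the
#' result is positive when both are losses.
#'
#' @param biophysical,direct AGB changes, Mg C ha-1 (signed).
#' @return percent.
#' @export
percentAdditionality <- function(biophysical, direct) {
  if (any(direct == 0)) stop("direct loss must be non-zero")
  100 * biophysical / direct
}

#' Quadrature propagation of the biophysical-loss uncertainty
#'
#' The one-SD uncertainty of the biophysical loss from the regional SDs of
#' the precipitation and temperature changes, propagated through the
#' observational regression coefficients assuming independence:
#' `sigma = sqrt((a * sigmaP)^2 + (b * sigmaT)^2)`.
#'
#' @param a,b observational regression coefficients (per mm yr-1, per degC).
#' @param sigmaP SD of the absolute precipitation change, mm yr-1.
#' @param sigmaT SD of the temperature change, degC.
#' @return SD of the biophysical loss, Mg C ha-1.
#' @examples
#' propagateUncertainty(0.034, -0.32, 105, 0.5)  # ~3.6
#' @export
propagateUncertainty <- function(a, b, sigmaP, sigmaT) {
  if (any(sigmaP < 0) || any(sigmaT < 0)) stop("sigma inputs must be >= 0")
  sqrt((a * sigmaP)^2 + (b * sigmaT)^2)
}

#' Combined local-edge plus regional-feedback additionality
#'
#' Simple sum of the literature-derived local edge-effect percentage and
#' the regional climate-feedback percentage, rounded to integer percent for
#' table output.
#'
#' @param edgePct local edge-effect additionality, % (literature constant).
#' @param regionalPct regional climate-feedback additionality, %.
#' @return integer percent.
#' @examples
#' combineAdditionality(36, 5.1)  # 41
#' @export
combineAdditionality <- function(edgePct, regionalPct) {
  if (any(edgePct < 0) || any(regionalPct < 0))
    stop("percentages must be non-negative")
  floor(edgePct + regionalPct + 0.5)  # round half up, as in printed tables
}
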