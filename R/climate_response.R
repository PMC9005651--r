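# Per-model deforestation climate deltas, multimodel summaries with
# sign-agreement masks, and Table-style regional climate rows.

#' Deforestation-minus-control climate deltas for one model
#'
#' For each shared variable, the delta is the difference of the last
#' `nYears` temporal means between the deforested and the control run.
#' Precipitation additionally yields a relative change
#' `dP_rel = 100 * dP / mean(control P)` (undefined where the control
#' climatology is zero), and tree cover a change in percentage points.
#'
#' @param control,deforest named lists of [FieldStack-class] runs; variable
#'   names are matched (`P`, `T`, `tree_cover` are recognized specially,
#'   any other supplied variable is differenced as-is).
#' @param nYears averaging window (default 30).
#' @return named list of delta [Field-class]s: `dP` (mm yr-1), `dP_rel` (%),
#'   `dT` (degC), `dCover` (percentage points) and `d<var>` for extras.
#' @export
deforestationDelta <- function(control, deforest, nYears = 30) {
  vars <- intersect(names(control), names(deforest))
  if (!length(vars)) stop("control and deforest share no variables")
  out <- list()
  for (v in vars) {
    ctl <- control[[v]]; def <- deforest[[v]]
    stopifnot(is(ctl, "FieldStack"), is(def, "FieldStack"))
    if (!.sameGrid(ctl, def)) stop("grid mismatch for variable ", v)
    mc <- timeWindowMean(ctl, "last", nYears)
    md <- timeWindowMean(def, "last", nYears)
    dv <- md@values - mc@values
    if (v == "P") {
      out$dP <- Field(dv, ctl@lat, ctl@lon, units = "mm yr-1", name = "dP")
      rel <- 100 * dv / mc@values
      rel[mc@values == 0] <- NA  # relative change undefined at zero climatology
      out$dP_rel <- Field(rel, ctl@lat, ctl@lon, units = "%", name = "dP_rel")
    } else if (v == "T") {
      out$dT <- Field(dv, ctl@lat, ctl@lon, units = "degC", name = "dT")
    } else if (v == "tree_cover") {
      out$dCover <- Field(100 * dv, ctl@lat, ctl@lon,
                          units = "percentage points", name = "dCover")
    } else {
      out[[paste0("d", v)]] <- Field(dv, ctl@lat, ctl@lon,
                                     units = ctl@units, name = paste0("d", v))
    }
  }
  out
}

#' Multimodel summary of per-model deltas
#'
#' Builds an [EnsembleDelta-class]: the unweighted multimodel mean, the
#' cross-model standard deviation (n-1 denominator) and the per-cell count
#' of models whose delta shares the sign of the multimodel mean. Exactly
#' zero deltas agree with neither sign (a conservative choice). The robust
#' mask requires agreement of at least `ceiling(0.75 * nModels)` models
#' (six of eight).
#'
#' @param deltas list of per-model delta lists as returned by
#'   [deforestationDelta], one element per model.
#' @param models optional model names.
#' @return An [EnsembleDelta-class].
#' @export
ensembleSummary <- function(deltas, models = NULL) {
  nm <- length(deltas)
  if (nm < 2L) stop("cross-model SD needs at least two models")
  if (is.null(models))
    models <- if (!is.null(names(deltas))) names(deltas) else
      paste0("model", seq_len(nm))
  vars <- names(deltas[[1]])
  f1 <- deltas[[1]][[1]]
  lat <- f1@lat; lon <- f1@lon
  perModel <- meanL <- sdL <- agL <- robL <- list()
  need <- ceiling(0.75 * nm)
  for (v in vars) {
    arr <- array(NA_real_, c(length(lat), length(lon), nm))
    for (m in seq_len(nm)) {
      fm <- deltas[[m]][[v]]
      if (!.sameGrid(fm, f1)) stop("models are on different grids")
      arr[, , m] <- fm@values
    }
    mu <- rowMeans(arr, dims = 2)
    sdv <- sqrt(rowSums((arr - as.vector(mu))^2, dims = 2) / (nm - 1))
    agree <- rowSums(sign(arr) == as.vector(sign(mu)) & arr != 0, dims = 2)
    perModel[[v]] <- arr
    meanL[[v]] <- mu
    sdL[[v]] <- sdv
    agL[[v]] <- agree
    robL[[v]] <- !is.na(agree) & agree >= need
  }
  new("EnsembleDelta", perModel = perModel, mean = meanL, sd = sdL,
      agreement = agL, robust = robL, models = models, lat = lat, lon = lon)
}

#' Relative-to-absolute precipitation change
#'
#' The absolute change is the product of the multimodel-mean relative
#' rainfall change (%) and the observed rainfall climatology, cellwise:
#' `dP_mm = (dP_rel / 100) * climatology`. Using the observed (rather than
#' each model's own) climatology avoids propagating simulated rainfall
#' biases into the absolute change.
#'
#' @param dPrel relative change [Field-class] or matrix (%).
#' @param climatology observed rainfall climatology [Field-class]
#'   (mm yr-1, non-negative).
#' @return [Field-class] of absolute change, mm yr-1.
#' @export
absolutePrecipChange <- function(dPrel, climatology) {
  stopifnot(is(climatology, "Field"))
  if (any(climatology@values < 0, na.rm = TRUE))
    stop("climatology must be non-negative")
  rel <- .asMatrixLike(dPrel)
  Field(rel / 100 * climatology@values, climatology@lat, climatology@lon,
        units = "mm yr-1", name = "dP_mm")
}

#' Regional climate summary row
#'
#' Area-weighted per-model regional means of the deforestation deltas,
#' summarized across models (mean and n-1 SD). The absolute precipitation
#' change is the regional mean of the cellwise product of each model's
#' relative change with the observed climatology, so its SD is the
#' cross-model spread of per-model products.
#'
#' @param ens an [EnsembleDelta-class] containing `dP_rel`, `dT` and
#'   (optionally) `dCover`.
#' @param mask a [RegionMask-class].
#' @param climatology observed rainfall climatology [Field-class].
#' @return one-row data.frame: `region`, then mean and SD of `dCover`
#'   (percentage points), `dPrel` (%), `dPmm` (mm yr-1) and `dT` (degC).
#' @export
regionalClimateRow <- function(ens, mask, climatology) {
  stopifnot(is(ens, "EnsembleDelta"), is(mask, "RegionMask"))
  nm <- length(ens@models)
  regMean <- function(valuesMatrix) {
    f <- Field(valuesMatrix, ens@lat, ens@lon)
    as.numeric(areaWeightedMean(f, mask))
  }
  perVar <- function(v, transform = identity) {
    if (is.null(ens@perModel[[v]])) return(c(NA_real_, NA_real_))
    x <- vapply(seq_len(nm), function(m)
      regMean(transform(ens@perModel[[v]][, , m])), numeric(1))
    c(mean(x), sd(x))
  }
  cover <- perVar("dCover")
  prel <- perVar("dP_rel")
  pmm <- if (!is.null(ens@perModel[["dP_rel"]]))
    perVar("dP_rel", transform = function(m) m / 100 * climatology@values)
  else c(NA_real_, NA_real_)
  dT <- perVar("dT")
  data.frame(region = mask@name,
             dCover = cover[1], dCover_sd = cover[2],
             dPrel = prel[1], dPrel_sd = prel[2],
             dPmm = pmm[1], dPmm_sd = pmm[2],
             dT = dT[1], dT_sd = dT[2],
             stringsAsFactors = FALSE)
}
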