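#' @rdname fieldValues
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))

#' Accessors for gridded objects
#'
#' `fieldValues()` returns the value matrix (or array for a stack),
#' `gridLat()`/`gridLon()` the cell-center coordinates, `fieldUnits()` and
#' `fieldName()` the metadata, and `maskMember()` the logical membership
#' matrix of a [RegionMask-class].
#'
#' @param x a [Field-class], [FieldStack-class] or [RegionMask-class].
#' @return The corresponding slot content.
#' @name fieldValues
#' @aliases gridLat gridLon fieldUnits fieldName maskMember
NULL

#' @rdname fieldValues
#' @export
setGeneric("gridLat", function(x) standardGeneric("gridLat"))
#' @rdname fieldValues
#' @export
setGeneric("gridLon", function(x) standardGeneric("gridLon"))
#' @rdname fieldValues
#' @export
setGeneric("fieldUnits", function(x) standardGeneric("fieldUnits"))
#' @rdname fieldValues
#' @export
setGeneric("fieldName", function(x) standardGeneric("fieldName"))
#' @rdname fieldValues
#' @export
setGeneric("maskMember", function(x) standardGeneric("maskMember"))

setMethod("fieldValues", "Field", function(x) x@values)
setMethod("fieldValues", "FieldStack", function(x) x@values)
setMethod("gridLat", "Field", function(x) x@lat)
setMethod("gridLat", "FieldStack", function(x) x@lat)
setMethod("gridLat", "RegionMask", function(x) x@lat)
setMethod("gridLon", "Field", function(x) x@lon)
setMethod("gridLon", "FieldStack", function(x) x@lon)
setMethod("gridLon", "RegionMask", function(x) x@lon)
setMethod("fieldUnits", "Field", function(x) x@units)
setMethod("fieldUnits", "FieldStack", function(x) x@units)
setMethod("fieldName", "Field", function(x) x@name)
setMethod("fieldName", "FieldStack", function(x) x@name)
setMethod("fieldName", "RegionMask", function(x) x@name)
setMethod("maskMember", "RegionMask", function(x) x@member)

#' @rdname fieldValues
#' @export
setGeneric("curveTable", function(x) standardGeneric("curveTable"))

#' @describeIn fitMovingWindow extract the per-level table of a
#'   [SensitivityCurve-class].
#' @param x a `SensitivityCurve`.
#' @export
setMethod("curveTable", "SensitivityCurve", function(x) x@table)

setMethod("show", "Field", function(object) {
  v <- object@values
  cat(sprintf("Field \"%s\" [%s]: %d x %d grid (lat %.2f..%.2f, lon %.2f..%.2f)\n",
              object@name, object@units, nrow(v), ncol(v),
              min(object@lat), max(object@lat),
              min(object@lon), max(object@lon)))
  cat(sprintf("  values: min %.4g, mean %.4g, max %.4g, NA %d\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              mean(v, na.rm = TRUE),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
})

setMethod("show", "FieldStack", function(object) {
  d <- dim(object@values)
  cat(sprintf("FieldStack \"%s\" [%s]: %d x %d grid, %d years\n",
              object@name, object@units, d[1], d[2], d[3]))
})

setMethod("show", "RegionMask", function(object) {
  cat(sprintf("RegionMask \"%s\": %d member cells of %d\n", object@name,
              sum(object@member, na.rm = TRUE), length(object@member)))
})

setMethod("show", "RegressionFit", function(object) {
  cat("Spatial regression AGB ~ MAP + MAT\n")
  cat(sprintf("  a = %.4g Mg C ha-1 per mm yr-1 (a*100 = %.3g, p = %.3g)\n",
              object@a, object@a * 100, object@pA))
  cat(sprintf("  b = %.4g Mg C ha-1 per degC (p = %.3g)\n", object@b, object@pB))
  cat(sprintf("  intercept = %.4g, R2 = %.3f, RMSE = %.3g Mg C ha-1, n = %d\n",
              object@intercept, object@r2, object@rmse, object@nCells))
  cat(sprintf("  deltaMAP = %.3g%% per 100 mm yr-1, deltaMAT = %.3g%% per degC\n",
              object@deltaMAP, object@deltaMAT))
})

setMethod("show", "SensitivityCurve", function(object) {
  tb <- object@table
  cat(sprintf("SensitivityCurve: %d levels (%g..%g mm yr-1), window +/- %g\n",
              nrow(tb), min(tb$level), max(tb$level), object@halfWidth))
  cat(sprintf("  jointly significant at alpha = %g: %d levels\n",
              object@alpha, sum(tb$significant, na.rm = TRUE)))
})

setMethod("show", "EnsembleDelta", function(object) {
  cat(sprintf("EnsembleDelta: %d models, variables: %s\n",
              length(object@models), paste(names(object@mean), collapse = ", ")))
})

setMethod("show", "GammaField", function(object) {
  cat(sprintf("GammaField (%s), |dT| >= %.2f degC; Mg C ha-1 degC-1\n",
              object@kind, object@threshold))
  show(object@field)
})

setMethod("show", "HistoricalScenario", function(object) {
  cat(sprintf("HistoricalScenario \"%s\": %.1f%% historical forest loss (factor %.3f)\n",
              object@region, object@histLoss, object@factor))
  cat(sprintf("  scaled deltas: %.1f mm yr-1 (%.2f%%), %.3f degC\n",
              object@dPmm, object@dPrel, object@dT))
  cat(sprintf("  per-ha: rain %.3f + warm %.3f = %.3f Mg C ha-1; total %.1f Tg C\n",
              object@perHaRain, object@perHaWarm, object@perHaNet,
              object@totalTgC))
})
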