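#' @import methods
#' @importFrom stats lm coef pt rnorm sd approx setNames
#' @importFrom utils write.csv read.csv
NULL

.sameGrid <- function(x, y, tol = 1e-8) {
  length(x@lat) == length(y@lat) && length(x@lon) == length(y@lon) &&
    all(abs(x@lat - y@lat) < tol) && all(abs(x@lon - y@lon) < tol)
}

#' Gridded 2-D field
#'
#' A single physical variable on a regular latitude/longitude grid, the
#' universal currency of the pipeline. Values are stored as an
#' `nlat x nlon` matrix; missing data are `NA`, never silently zero.
#'
#' @slot values numeric matrix, rows indexed by `lat`, columns by `lon`.
#' @slot lat numeric vector of cell-center latitudes, strictly increasing,
#'   within \[-90, 90\].
#' @slot lon numeric vector of cell-center longitudes, monotone, in
#'   \[-180, 180).
#' @slot units character(1) physical units, e.g. `"mm yr-1"`.
#' @slot name character(1) variable name.
#'
#' @exportClass Field
setClass("Field",
  representation(values = "matrix", lat = "numeric", lon = "numeric",
                 units = "character", name = "character"))

setValidity("Field", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (nrow(v) != length(object@lat)) return("nrow(values) != length(lat)")
  if (ncol(v) != length(object@lon)) return("ncol(values) != length(lon)")
  if (length(object@lat) < 1L || length(object@lon) < 1L)
    return("grid must have at least one cell")
  if (any(diff(object@lat) <= 0)) return("lat must be strictly increasing")
  if (any(object@lat < -90 | object@lat > 90)) return("lat outside [-90, 90]")
  dl <- diff(object@lon)
  if (length(dl) && !(all(dl > 0) || all(dl < 0)))
    return("lon must be monotone")
  TRUE
})

#' Construct a Field
#'
#' @param values numeric matrix (`length(lat)` rows, `length(lon)` columns)
#'   or a single number recycled over the grid.
#' @param lat,lon cell-center coordinates.
#' @param units,name metadata strings.
#' @return A [Field-class] object.
#' @examples
#' f <- Field(0, lat = c(-0.5, 0.5), lon = c(10.5, 11.5), units = "degC")
#' @export
Field <- function(values, lat, lon, units = "", name = "") {
  if (length(values) == 1L)
    values <- matrix(as.numeric(values), length(lat), length(lon))
  new("Field", values = as.matrix(values), lat = as.numeric(lat),
      lon = as.numeric(lon), units = units, name = name)
}

#' Annual series of fields
#'
#' A stack of yearly 2-D fields sharing one grid, stored as a
#' `nlat x nlon x nyear` array.
#'
#' @slot values numeric 3-D array `(lat, lon, year)`.
#' @slot lat,lon grid cell centers (as in [Field-class]).
#' @slot years integer-valued year labels.
#' @slot units,name metadata.
#' @exportClass FieldStack
setClass("FieldStack",
  representation(values = "array", lat = "numeric", lon = "numeric",
                 years = "numeric", units = "character", name = "character"))

setValidity("FieldStack", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L) return("values must be a 3-D array (lat, lon, year)")
  if (d[1] != length(object@lat)) return("dim 1 != length(lat)")
  if (d[2] != length(object@lon)) return("dim 2 != length(lon)")
  if (d[3] != length(object@years)) return("dim 3 != length(years)")
  if (any(diff(object@lat) <= 0)) return("lat must be strictly increasing")
  TRUE
})

#' Construct a FieldStack
#' @param values 3-D array `(lat, lon, year)`.
#' @param lat,lon grid cell centers.
#' @param years year labels (defaults to `1:nyear`).
#' @param units,name metadata strings.
#' @return A [FieldStack-class] object.
#' @export
FieldStack <- function(values, lat, lon, years = seq_len(dim(values)[3]),
                       units = "", name = "") {
  new("FieldStack", values = values, lat = as.numeric(lat),
      lon = as.numeric(lon), years = as.numeric(years),
      units = units, name = name)
}

#' Named boolean region mask on the analysis grid
#'
#' @slot name region name, e.g. `"amazon"`.
#' @slot member logical matrix on the same grid as the fields it masks.
#' @slot lat,lon grid cell centers.
#' @exportClass RegionMask
setClass("RegionMask",
  representation(name = "character", member = "matrix",
                 lat = "numeric", lon = "numeric"))

setValidity("RegionMask", function(object) {
  if (!is.logical(object@member)) return("member must be logical")
  if (nrow(object@member) != length(object@lat)) return("nrow != length(lat)")
  if (ncol(object@member) != length(object@lon)) return("ncol != length(lon)")
  if (!any(object@member, na.rm = TRUE)) return("mask has no member cells")
  TRUE
})

#' Construct a RegionMask
#' @param name region name.
#' @param member logical matrix (TRUE = cell belongs to the region).
#' @param lat,lon grid cell centers.
#' @return A [RegionMask-class] object.
#' @export
RegionMask <- function(name, member, lat, lon) {
  new("RegionMask", name = name, member = member,
      lat = as.numeric(lat), lon = as.numeric(lon))
}

#' Ordinary-least-squares fit of biomass on climate
#'
#' Holds the coefficients and diagnostics of the spatial regression
#' AGB ~ MAP + MAT, including the relative sensitivities
#' `deltaMAP` (% per 100 mm yr-1) and `deltaMAT` (% per degC), each the
#' coefficient expressed relative to the domain-mean AGB.
#'
#' @slot a precipitation coefficient, Mg C ha-1 per mm yr-1.
#' @slot b temperature coefficient, Mg C ha-1 per degC.
#' @slot intercept Mg C ha-1 (0 when fitted without intercept).
#' @slot r2,rmse goodness of fit.
#' @slot nCells number of grid cells entering the fit.
#' @slot seA,seB,pA,pB standard errors and two-sided p-values.
#' @slot deltaMAP,deltaMAT relative sensitivities (percent).
#' @exportClass RegressionFit
setClass("RegressionFit",
  representation(a = "numeric", b = "numeric", intercept = "numeric",
                 r2 = "numeric", rmse = "numeric", nCells = "integer",
                 seA = "numeric", seB = "numeric",
                 pA = "numeric", pB = "numeric",
                 deltaMAP = "numeric", deltaMAT = "numeric"))

setValidity("RegressionFit", function(object) {
  if (!is.na(object@r2) && (object@r2 < -1e-8 || object@r2 > 1 + 1e-8))
    return("r2 outside [0, 1]")
  if (!is.na(object@rmse) && object@rmse < 0) return("rmse < 0")
  TRUE
})

#' Moving-window sensitivity of biomass to climate
#'
#' One regression per precipitation level; windows span
#' `level +/- halfWidth` mm yr-1. `sigA`/`sigB` flag per-coefficient
#' significance at `alpha`; `significant` is the joint flag (both
#' coefficients significant). Windows with fewer than `minCells` cells are
#' reported but flagged not significant.
#'
#' @slot table data.frame with one row per level: `level, a, b, intercept,
#'   seA, seB, pA, pB, r2, rmse, n, sigA, sigB, significant`.
#' @slot halfWidth window half width, mm yr-1.
#' @slot alpha significance level for the coefficient t-tests.
#' @slot minCells minimum cells for a significance-eligible window.
#' @exportClass SensitivityCurve
setClass("SensitivityCurve",
  representation(table = "data.frame", halfWidth = "numeric",
                 alpha = "numeric", minCells = "numeric"))

setValidity("SensitivityCurve", function(object) {
  need <- c("level", "a", "b", "pA", "pB", "n", "sigA", "sigB", "significant")
  if (!all(need %in% names(object@table)))
    return(paste("table missing columns:",
                 paste(setdiff(need, names(object@table)), collapse = ", ")))
  TRUE
})

#' Multimodel ensemble of deforestation climate deltas
#'
#' Per-model deforestation-minus-control change fields plus the unweighted
#' multimodel mean, the cross-model standard deviation (n-1 denominator) and
#' the per-cell count of models agreeing with the sign of the mean.
#'
#' @slot perModel named list (one element per variable) of 3-D arrays
#'   `(lat, lon, model)`.
#' @slot mean,sd,agreement named lists of matrices per variable.
#' @slot robust named list of logical matrices: agreement >=
#'   `ceiling(0.75 * nModels)`.
#' @slot models model names.
#' @slot lat,lon grid cell centers.
#' @exportClass EnsembleDelta
setClass("EnsembleDelta",
  representation(perModel = "list", mean = "list", sd = "list",
                 agreement = "list", robust = "list", models = "character",
                 lat = "numeric", lon = "numeric"))

setValidity("EnsembleDelta", function(object) {
  n <- length(object@models)
  if (n < 2L) return("at least two models are required")
  for (v in names(object@agreement)) {
    ag <- object@agreement[[v]]
    if (any(ag > n, na.rm = TRUE)) return("agreement count exceeds n models")
    if (any(object@sd[[v]] < 0, na.rm = TRUE)) return("negative SD")
  }
  TRUE
})

#' Carbon-climate feedback parameter field
#'
#' Per-cell gamma (carbon-stock change per degree of warming),
#' Mg C ha-1 degC-1; multiply by 0.1 for kg C m-2 degC-1. Cells where the
#' warming denominator is below `threshold` in absolute value are masked.
#'
#' @slot field the gamma [Field-class].
#' @slot kind `"co2"` or `"deforest"`.
#' @slot threshold the |dT| masking threshold (degC).
#' @exportClass GammaField
setClass("GammaField",
  representation(field = "Field", kind = "character", threshold = "numeric"))

setValidity("GammaField", function(object) {
  if (!object@kind %in% c("co2", "deforest"))
    return("kind must be 'co2' or 'deforest'")
  TRUE
})

#' Historical linear-scaling attribution record
#'
#' The deforestation-induced climate deltas of the idealized experiment are
#' assumed linear in the deforestation level, so a historical primary-forest
#' fraction loss scales them by `histLoss / |refCoverChange|`; the scaled
#' deltas times the observational climate sensitivities give a per-hectare
#' biomass change and, with the basin area, a regional total in Tg C.
#'
#' @slot region region name.
#' @slot histLoss historical primary-forest fraction loss (%).
#' @slot refCoverChange reference (idealized-experiment) tree-cover change (%).
#' @slot factor scaling factor `histLoss / |refCoverChange|`.
#' @slot dPmm,dPrel,dT scaled climate deltas (mm yr-1, %, degC).
#' @slot perHaRain,perHaWarm,perHaNet per-hectare biomass change components
#'   (Mg C ha-1, signed; negative = loss).
#' @slot areaKm2 region area (km2).
#' @slot totalTgC regional total (Tg C, signed).
#' @exportClass HistoricalScenario
setClass("HistoricalScenario",
  representation(region = "character", histLoss = "numeric",
                 refCoverChange = "numeric", factor = "numeric",
                 dPmm = "numeric", dPrel = "numeric", dT = "numeric",
                 perHaRain = "numeric", perHaWarm = "numeric",
                 perHaNet = "numeric", areaKm2 = "numeric",
                 totalTgC = "numeric"))

setValidity("HistoricalScenario", function(object) {
  if (object@factor < 0 || object@factor > 1)
    return("scaling factor must lie in [0, 1]")
  if (object@areaKm2 <= 0) return("area must be positive")
  TRUE
})
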