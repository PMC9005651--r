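# Field I/O, regridding and masked area-weighted statistics.
#
# Conventions: cell-center coordinates, regular spacing, longitudes in
# [-180, 180); masks and fields must share a grid exactly -- no implicit
# regridding.

.checkRegular <- function(x, what) {
  if (length(x) > 1L) {
    d <- diff(x)
    if (max(abs(d - d[1])) > 1e-6 * max(abs(d)))
      stop(what, " coordinates are not on a regular grid")
  }
  invisible(TRUE)
}

#' Bilinear regridding to a target grid
#'
#' Interpolates a [Field-class] to new cell centers; the value at each target
#' center is the bilinear interpolant of the four surrounding source centers.
#' Target points outside the source centers' hull are clamped to the nearest
#' inside position (nearest-inside extrapolation at the edges). Units are
#' preserved. A target cell whose four-point neighbourhood contains missing
#' source values becomes `NA`.
#'
#' @param field a [Field-class] on a regular grid.
#' @param lat,lon target cell-center coordinates.
#' @return A [Field-class] on the target grid.
#' @examples
#' f <- Field(matrix(c(0, 1, 0, 1), 2, 2), lat = c(0, 1), lon = c(0, 1))
#' fieldValues(regridBilinear(f, lat = 0.5, lon = 0.5))  # 0.5
#' @export
regridBilinear <- function(field, lat, lon) {
  stopifnot(is(field, "Field"))
  .checkRegular(field@lat, "source latitude")
  .checkRegular(field@lon, "source longitude")
  v <- field@values
  if (all(is.na(v))) stop("all source values are missing")
  slat <- field@lat
  slon <- field@lon
  if (length(slon) > 1L && slon[2] < slon[1]) {  # monotone decreasing lon
    slon <- rev(slon)
    v <- v[, rev(seq_along(field@lon)), drop = FALSE]
  }
  tlat <- pmin(pmax(as.numeric(lat), slat[1]), slat[length(slat)])
  tlon <- pmin(pmax(as.numeric(lon), slon[1]), slon[length(slon)])
  iy <- findInterval(tlat, slat, all.inside = TRUE)
  ix <- findInterval(tlon, slon, all.inside = TRUE)
  fy <- if (length(slat) > 1L) (tlat - slat[iy]) / (slat[iy + 1L] - slat[iy]) else 0
  fx <- if (length(slon) > 1L) (tlon - slon[ix]) / (slon[ix + 1L] - slon[ix]) else 0
  i1 <- if (length(slat) > 1L) iy + 1L else iy
  j1 <- if (length(slon) > 1L) ix + 1L else ix
  rowMix <- function(m0, m1) m0 * rep(1 - fx, each = nrow(m0)) +
    m1 * rep(fx, each = nrow(m1))
  top <- rowMix(v[iy, ix, drop = FALSE], v[iy, j1, drop = FALSE])
  bot <- rowMix(v[i1, ix, drop = FALSE], v[i1, j1, drop = FALSE])
  out <- top * (1 - fy) + bot * fy
  Field(out, lat = as.numeric(lat), lon = as.numeric(lon),
        units = field@units, name = field@name)
}

#' Area-weighted spatial mean over a region
#'
#' Computes `sum(w * x) / sum(w)` with weights proportional to the cosine of
#' the cell-center latitude. Missing cells are excluded from both sums
#' (pairwise-complete rule). The effective number of contributing cells is
#' attached as attribute `"n"`.
#'
#' @param field a [Field-class].
#' @param mask optional [RegionMask-class] on the same grid; `NULL` means the
#'   whole grid.
#' @return numeric scalar with attribute `n` (effective cell count).
#' @examples
#' f <- Field(matrix(c(0, 1), 2, 1), lat = c(0, 60), lon = 0)
#' areaWeightedMean(f)  # 1/3: cos(60 deg) = 0.5
#' @export
areaWeightedMean <- function(field, mask = NULL) {
  stopifnot(is(field, "Field"))
  keep <- !is.na(field@values)
  if (!is.null(mask)) {
    stopifnot(is(mask, "RegionMask"))
    if (!.sameGrid(field, mask))
      stop("mask and field are on different grids")
    keep <- keep & mask@member
  }
  if (!any(keep)) stop("no unmasked, non-missing cells")
  w <- matrix(cos(field@lat * pi / 180), nrow(field@values), ncol(field@values))
  val <- sum(w[keep] * field@values[keep]) / sum(w[keep])
  structure(val, n = sum(keep))
}

#' Temporal mean over the first or last n years
#'
#' Per-cell arithmetic mean of a [FieldStack-class] over the selected window.
#'
#' @param stack a [FieldStack-class].
#' @param align `"last"` or `"first"` window position.
#' @param nYears window length in years.
#' @return A [Field-class] of per-cell means.
#' @export
timeWindowMean <- function(stack, align = c("last", "first"), nYears) {
  stopifnot(is(stack, "FieldStack"))
  align <- match.arg(align)
  nt <- dim(stack@values)[3]
  if (nYears > nt)
    stop("series has ", nt, " years, window needs ", nYears)
  idx <- if (align == "last") (nt - nYears + 1L):nt else 1:nYears
  m <- rowMeans(stack@values[, , idx, drop = FALSE], dims = 2)
  Field(m, lat = stack@lat, lon = stack@lon, units = stack@units,
        name = stack@name)
}

#' Write/read a Field as plain text
#'
#' Serializes a [Field-class] as a long-format CSV (`lat, lon, value`) plus a
#' JSON sidecar (`<path>.json`) holding name, units and the grid definition.
#' Values are written with 17 significant digits so a round trip reproduces
#' them bit-exactly.
#'
#' @param field a [Field-class].
#' @param path CSV file path; the sidecar is written to `paste0(path, ".json")`.
#' @return `writeFieldCSV` returns `path` invisibly; `readFieldCSV` returns
#'   the reconstructed [Field-class].
#' @export
writeFieldCSV <- function(field, path) {
  stopifnot(is(field, "Field"))
  grid <- expand.grid(lat = field@lat, lon = field@lon,
                      KEEP.OUT.ATTRS = FALSE)
  df <- data.frame(lat = sprintf("%.17g", grid$lat),
                   lon = sprintf("%.17g", grid$lon),
                   value = sprintf("%.17g", as.vector(field@values)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(name = field@name, units = field@units,
               lat = sprintf("%.17g", field@lat),
               lon = sprintf("%.17g", field@lon))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeFieldCSV
#' @export
readFieldCSV <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read.csv(path)
  lat <- as.numeric(side$lat)
  lon <- as.numeric(side$lon)
  v <- matrix(df$value, length(lat), length(lon))
  Field(v, lat = lat, lon = lon,
        units = if (is.null(side$units)) "" else side$units,
        name = if (is.null(side$name)) "" else side$name)
}
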