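# Shared fixtures, built in code.

# a reduced tropical belt covering all three region boxes; keeps ensemble
# stacks small enough for fast tests
smallCfg <- function(seed = 1L, ...) {
  syntheticConfig(seed = seed,
                  lat = seq(-15.5, 10.5, by = 1),
                  lon = seq(-80.5, 159.5, by = 1),
                  nYears = 35, rampYears = 5, windowYears = 30, ...)
}

# tiny field on an equatorial grid (cos-lat weights ~ 1)
tinyField <- function(values, nlat = NULL, nlon = NULL, units = "") {
  if (is.null(dim(values)))
    values <- matrix(values, nlat, nlon)
  Field(values, lat = seq_len(nrow(values)) - 0.5,
        lon = seq_len(ncol(values)) - 0.5, units = units)
}

# constant-in-time stack from a single matrix
constStack <- function(m, nYears, units = "") {
  FieldStack(array(rep(m, nYears), c(nrow(m), ncol(m), nYears)),
             lat = seq_len(nrow(m)) - 0.5, lon = seq_len(ncol(m)) - 0.5,
             units = units)
}

# closed-form OLS via the normal equations (independent oracle)
olsOracle <- function(y, X) solve(crossprod(X), crossprod(X, y))
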