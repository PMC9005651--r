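# Synthetic observation bundle and pseudo multimodel ensemble.
#
# The generator emulates only the statistical structure the analysis
# exploits: AGB approximately linear in MAP and MAT with a saturating
# high-rainfall regime, tree cover increasing and saturating with MAP,
# MAT anticorrelated with MAP, idealized continents with soft coastlines,
# and per-model regional climate responses drawn around prescribed
# ensemble means/SDs. It makes no attempt at geographic realism.

#' Configuration of the synthetic world
#'
#' Defaults reproduce the study conditions: the observational regression
#' coefficients (a*100 = 3.4 Mg C ha-1 per 100 mm yr-1, b = -0.32 per degC),
#' a residual scale of ~32 Mg C ha-1, saturation of the biomass-rainfall
#' relation above 2400 mm yr-1, and per-region response distributions for
#' eight models (relative precipitation change, warming and tree-cover loss
#' with their cross-model SDs).
#'
#' @slot seed master RNG seed; one stream per model member is derived from
#'   it so adding models does not perturb earlier members.
#' @slot lat,lon analysis-grid cell centers (1 degree, strictly inside
#'   23S-23N).
#' @slot aTrue,bTrue,interceptTrue generative coefficients of the
#'   AGB surface (Mg C ha-1 per mm yr-1 / per degC / offset).
#' @slot noiseModel `"proportional"` (SD proportional to the noiseless
#'   surface, mirroring the relative-error structure of satellite biomass
#'   maps) or `"homoscedastic"`.
#' @slot sigmaObs homoscedastic noise SD (Mg C ha-1).
#' @slot relNoise,sigmaMin,sigmaMax proportional-noise parameters:
#'   `sd = clamp(relNoise * surface, sigmaMin, sigmaMax)`.
#' @slot satThreshold MAP level (mm yr-1) above which the AGB surface
#'   flattens; `Inf` disables saturation.
#' @slot satSlope fraction of the rainfall slope retained above the
#'   saturation threshold (0 = fully flat). A small residual slope keeps
#'   the tropics-wide regression consistent with the linear-regime
#'   coefficients while wet windows still lose significance.
#' @slot treeCoverMax,treeCoverScale,treeCoverNoise saturating tree-cover
#'   curve `tcMax * (1 - exp(-AGB / scale))` plus Gaussian noise; because
#'   AGB increases with rainfall, tree cover is on average a monotone
#'   saturating function of MAP. The scale is chosen so the tree-cover to
#'   biomass regression lands in the observed 19-22 Mg C ha-1 per 10% band.
#' @slot regions data.frame with one row per region (`region`,
#'   `dPrel_mean`, `dPrel_sd` (%), `dT_mean`, `dT_sd` (degC),
#'   `dCover_mean`, `dCover_sd` (percentage points)).
#' @slot nModels,nYears,rampYears,windowYears ensemble dimensions: run
#'   length, deforestation ramp length and averaging window (years).
#' @slot climBiasSd per-model multiplicative precipitation climatology bias
#'   (SD, fraction).
#' @slot interannualP,interannualT interannual noise (fraction of the
#'   precipitation climatology; degC).
#' @slot gammaCo2True named per-region CO2-feedback parameters injected by
#'   [generateCo2Runs] (Mg C ha-1 degC-1).
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(seed = "numeric", lat = "numeric", lon = "numeric",
                 aTrue = "numeric", bTrue = "numeric",
                 interceptTrue = "numeric", noiseModel = "character",
                 sigmaObs = "numeric", relNoise = "numeric",
                 sigmaMin = "numeric", sigmaMax = "numeric",
                 satThreshold = "numeric", satSlope = "numeric",
                 treeCoverMax = "numeric",
                 treeCoverScale = "numeric", treeCoverNoise = "numeric",
                 regions = "data.frame", nModels = "numeric",
                 nYears = "numeric", rampYears = "numeric",
                 windowYears = "numeric", climBiasSd = "numeric",
                 interannualP = "numeric", interannualT = "numeric",
                 gammaCo2True = "numeric"))

setValidity("SyntheticConfig", function(object) {
  if (object@nModels < 2) return("nModels must be >= 2")
  if (object@sigmaObs < 0) return("sigmaObs must be >= 0")
  if (length(object@lat) < 1 || length(object@lon) < 1)
    return("grid must be non-empty")
  if (any(abs(object@lat) >= 23))
    return("grid must lie strictly inside 23S-23N")
  if (object@nYears < object@windowYears)
    return("nYears shorter than the averaging window")
  need <- c("region", "dPrel_mean", "dPrel_sd", "dT_mean", "dT_sd",
            "dCover_mean", "dCover_sd")
  if (!all(need %in% names(object@regions)))
    return("regions table missing required columns")
  TRUE
})

.defaultRegions <- function() {
  data.frame(region = c("amazon", "congo", "tropical_asia"),
             dPrel_mean = c(-6.7, -2.7, -1.3),
             dPrel_sd = c(4.7, 3.7, 2.0),
             dT_mean = c(0.5, 0.1, -0.1),
             dT_sd = c(0.5, 0.5, 0.2),
             dCover_mean = c(-44.7, -38.7, -31.2),
             dCover_sd = c(6.0, 8.8, 8.9),
             stringsAsFactors = FALSE)
}

#' Construct a SyntheticConfig
#'
#' @param seed master seed.
#' @param lat,lon grid cell centers.
#' @param aTrue,bTrue,interceptTrue AGB-surface coefficients.
#' @param noiseModel,sigmaObs,relNoise,sigmaMin,sigmaMax noise model.
#' @param satThreshold saturation MAP threshold (mm yr-1).
#' @param treeCoverMax,treeCoverScale,treeCoverNoise tree-cover curve.
#' @param regions per-region response distribution table.
#' @param nModels,nYears,rampYears,windowYears ensemble dimensions.
#' @param climBiasSd,interannualP,interannualT ensemble noise settings.
#' @param gammaCo2True injected per-region CO2 feedback parameters.
#' @return A [SyntheticConfig-class].
#' @export
syntheticConfig <- function(seed = 1L,
                            lat = seq(-22.5, 22.5, by = 1),
                            lon = seq(-179.5, 179.5, by = 1),
                            aTrue = 0.034, bTrue = -0.32,
                            interceptTrue = 0,
                            noiseModel = c("proportional", "homoscedastic"),
                            sigmaObs = 32, relNoise = 0.6,
                            sigmaMin = 4, sigmaMax = 45,
                            satThreshold = 2400, satSlope = 0.25,
                            treeCoverMax = 0.92, treeCoverScale = 120,
                            treeCoverNoise = 0.03,
                            regions = .defaultRegions(),
                            nModels = 8, nYears = 80, rampYears = 50,
                            windowYears = 30, climBiasSd = 0.05,
                            interannualP = 0.04, interannualT = 0.3,
                            gammaCo2True = c(amazon = -4, congo = -1.2,
                                             tropical_asia = -1)) {
  new("SyntheticConfig", seed = seed, lat = lat, lon = lon, aTrue = aTrue,
      bTrue = bTrue, interceptTrue = interceptTrue,
      noiseModel = match.arg(noiseModel), sigmaObs = sigmaObs,
      relNoise = relNoise, sigmaMin = sigmaMin, sigmaMax = sigmaMax,
      satThreshold = satThreshold, satSlope = satSlope,
      treeCoverMax = treeCoverMax,
      treeCoverScale = treeCoverScale, treeCoverNoise = treeCoverNoise,
      regions = regions, nModels = nModels, nYears = nYears,
      rampYears = rampYears, windowYears = windowYears,
      climBiasSd = climBiasSd, interannualP = interannualP,
      interannualT = interannualT, gammaCo2True = gammaCo2True)
}

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf("SyntheticConfig: %d x %d grid, %d models x %d years, seed %d\n",
              length(object@lat), length(object@lon), object@nModels,
              object@nYears, as.integer(object@seed)))
  cat(sprintf("  AGB surface: a*100 = %.3g, b = %.3g, intercept = %.3g, sat > %g mm\n",
              object@aTrue * 100, object@bTrue, object@interceptTrue,
              object@satThreshold))
})

.latLonGrids <- function(cfg) {
  list(LAT = matrix(cfg@lat, length(cfg@lat), length(cfg@lon)),
       LON = matrix(cfg@lon, length(cfg@lat), length(cfg@lon), byrow = TRUE))
}

# Deterministic "wetness" climatology and continent score. Idealized
# continental blocks: tropical America with an east-west rainfall gradient,
# Africa with dry subtropical belts, the maritime continent as an island
# pattern, mainland southeast Asia, monsoon India and semi-arid northern
# Australia. No geographic realism intended.
.worldTemplate <- function(cfg) {
  g <- .latLonGrids(cfg)
  LAT <- g$LAT; LON <- g$LON
  amer <- LON >= -82 & LON <= -34 & LAT >= -22 & LAT <= 13
  afr <- LON >= 6 & LON <= 44 & LAT >= -20 & LAT <= 17
  afrDry <- afr & (LAT > 11 | LAT < -13)
  asia <- LON >= 95 & LON <= 155 & LAT >= -11 & LAT <= 11
  sea <- LON >= 95 & LON <= 109 & LAT >= 8 & LAT <= 20
  ind <- LON >= 70 & LON <= 88 & LAT >= 8 & LAT <= 22
  aus <- LON >= 120 & LON <= 150 & LAT >= -22 & LAT <= -12
  w <- matrix(1000, nrow(LAT), ncol(LAT))
  w[amer] <- pmin(2600, 3000 - 20 * (LON[amer] + 82))
  w[afr] <- 1600
  w[afrDry] <- 450
  w[asia] <- 2800
  w[sea] <- 2300
  w[ind] <- 1400
  w[aus] <- 650
  latFactor <- 0.7 + 0.3 * cos(pi * LAT / 27)
  wetness <- w * latFactor
  edgeScore <- function(block, lon0, lon1, lat0, lat1) {
    d <- pmin(LON - lon0, lon1 - LON, LAT - lat0, lat1 - LAT)
    s <- pmin(1, (d + 0.5) / 1.5)
    ifelse(block, pmax(0, s), 0)
  }
  land <- pmax(edgeScore(amer, -82, -34, -22, 13),
               edgeScore(afr, 6, 44, -20, 17),
               edgeScore(sea, 95, 109, 8, 20),
               edgeScore(ind, 70, 88, 8, 22),
               edgeScore(aus, 120, 150, -22, -12))
  # maritime continent: a sparse island pattern, most cells ocean-dominated
  sinprod <- sin(LON * 0.7) * sin(LAT * 0.9 + LON * 0.3)
  island <- ifelse(sinprod > 0.55, 0.7 + 0.3 * sinprod,
                   0.25 * (sinprod + 1))
  land <- pmax(land, ifelse(asia & !sea, island, 0))
  # weak independent relief pattern perturbing temperature only
  relief <- 1.2 * sin(LON * 0.23 + 1) * cos(LAT * 0.31)
  list(wetness = wetness, landScore = land, relief = relief,
       LAT = LAT, LON = LON)
}

#' Noiseless generative AGB surface
#'
#' The expectation of the synthetic AGB given climate: linear in MAP and MAT
#' below the saturation threshold, nearly flat in MAP above it:
#' `surface = intercept + a * (min(MAP, sat) + satSlope * max(MAP - sat, 0))
#' + b * MAT`.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param MAP,MAT climate [Field-class]s or matrices.
#' @return matrix of surface values (may be negative; the generated AGB is
#'   clipped at zero).
#' @export
agbSurface <- function(cfg, MAP, MAT) {
  map <- .asMatrixLike(MAP); mat <- .asMatrixLike(MAT)
  excess <- pmax(map - cfg@satThreshold, 0)
  excess[is.infinite(cfg@satThreshold) | is.na(excess)] <- 0
  cfg@interceptTrue +
    cfg@aTrue * (pmin(map, cfg@satThreshold) + cfg@satSlope * excess) +
    cfg@bTrue * mat
}

#' Generate the observation-like bundle
#'
#' Produces MAP, MAT, AGB, tree cover and land fraction on the configured
#' grid. MAP spans the dry-desert to wet-maritime range with spatial
#' gradients; MAT is anticorrelated with MAP (drier areas are hotter and
#' more variable); AGB follows [agbSurface] plus noise, clipped at zero;
#' tree cover is a monotone saturating function of MAP; land fraction is 1
#' over continental interiors with partial coastal and island cells.
#' Identical seeds give bit-identical output.
#'
#' @param cfg a [SyntheticConfig-class].
#' @return named list of [Field-class]s: `MAP`, `MAT`, `AGB`, `tree_cover`,
#'   `land_fraction`.
#' @export
generateObservationBundle <- function(cfg) {
  stopifnot(is(cfg, "SyntheticConfig"))
  tpl <- .worldTemplate(cfg)
  nlat <- length(cfg@lat); nlon <- length(cfg@lon); n <- nlat * nlon
  set.seed(as.integer(cfg@seed))
  MAP <- matrix(pmin(3600, pmax(40, tpl$wetness + rnorm(n, 0, 120))),
                nlat, nlon)
  # drier areas are hotter and spatially more variable in temperature
  matSd <- 0.6 + 0.9 * (1 - MAP / 3600)
  MAT <- matrix(32.5 - 0.0022 * MAP - 2.5 * (abs(tpl$LAT) / 23) +
                  tpl$relief + rnorm(n, 0, 1) * matSd, nlat, nlon)
  land <- pmin(1, pmax(0, tpl$landScore + rnorm(n, 0, 0.12)))
  mu <- agbSurface(cfg, MAP, MAT)
  z <- rnorm(n, 0, 1)
  if (cfg@noiseModel == "proportional") {
    # mean-preserving multiplicative lognormal noise where the surface is
    # positive (mirrors the relative-error structure of satellite biomass
    # retrievals and keeps E[AGB | MAP, MAT] exactly on the surface);
    # additive floor noise, clipped at zero, where it is not
    sdv <- pmin(cfg@sigmaMax, pmax(cfg@sigmaMin, cfg@relNoise * mu))
    s2 <- log(1 + (sdv / pmax(mu, 1e-12))^2)
    AGB <- ifelse(mu > 0, mu * exp(sqrt(s2) * z - s2 / 2),
                  pmax(0, mu + sdv * z))
  } else {
    AGB <- pmax(0, mu + cfg@sigmaObs * z)
  }
  # tree cover saturates with biomass (hence, on average, with rainfall)
  tc <- pmin(1, pmax(0, cfg@treeCoverMax *
                       (1 - exp(-pmax(AGB, 0) / cfg@treeCoverScale)) +
                       rnorm(n, 0, cfg@treeCoverNoise)))
  mk <- function(v, units, name)
    Field(matrix(v, nlat, nlon), cfg@lat, cfg@lon, units = units, name = name)
  list(MAP = mk(MAP, "mm yr-1", "MAP"),
       MAT = mk(MAT, "degC", "MAT"),
       AGB = mk(AGB, "Mg C ha-1", "AGB"),
       tree_cover = mk(tc, "fraction", "tree_cover"),
       land_fraction = mk(land, "fraction", "land_fraction"))
}

#' Cells where the generative AGB surface is strictly linear
#'
#' The analysis-domain cells (see [applyDomainFilters]) below the
#' saturation threshold and with a noiseless surface high enough that the
#' zero-clipping of AGB is negligible; on these cells an OLS refit is an
#' unbiased estimate of the injected coefficients.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param bundle output of [generateObservationBundle].
#' @return logical matrix.
#' @export
linearRegimeMask <- function(cfg, bundle) {
  keep <- applyDomainFilters(bundle)
  mu <- agbSurface(cfg, bundle$MAP, bundle$MAT)
  ok <- if (cfg@noiseModel == "proportional") mu > 0 else
    mu > 2 * cfg@sigmaObs  # keep zero-clipping negligible
  keep & bundle$MAP@values < cfg@satThreshold & ok
}

#' Generate the region masks of the synthetic world
#'
#' Three disjoint masks: `tropical_asia` is exactly the land cells within
#' 10S-10N, 95E-155E; `amazon` and `congo` are synthetic basin boxes
#' intersected with land.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param landFraction land-fraction [Field-class] from the bundle.
#' @param minLand land-fraction threshold for mask membership.
#' @return named list of [RegionMask-class] objects.
#' @export
generateRegionMasks <- function(cfg, landFraction, minLand = 0.5) {
  stopifnot(is(landFraction, "Field"))
  g <- .latLonGrids(cfg)
  land <- landFraction@values >= minLand
  boxes <- list(
    amazon = g$LAT >= -15 & g$LAT <= 3 & g$LON >= -75 & g$LON <= -47,
    congo = g$LAT >= -8 & g$LAT <= 5 & g$LON >= 12 & g$LON <= 30,
    tropical_asia = g$LAT >= -10 & g$LAT <= 10 & g$LON >= 95 & g$LON <= 155)
  out <- lapply(names(boxes), function(nm)
    RegionMask(nm, boxes[[nm]] & land, cfg@lat, cfg@lon))
  names(out) <- names(boxes)
  out
}

.modelSeed <- function(cfg, m, offset = 0L) {
  as.integer((as.integer(cfg@seed) * 37 + m * 1009 + offset) %% 2147483647L)
}

#' Generate one pseudo-model's control/deforested run pair
#'
#' The control climatology is the observation bundle's MAP (with a
#' per-model multiplicative bias) and MAT; the deforested run applies the
#' model's regional responses, ramped linearly over `rampYears` and held
#' constant afterwards, plus interannual noise. Each model has its own RNG
#' stream derived from the master seed.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param m model index (1-based).
#' @param bundle observation bundle (see [generateObservationBundle]).
#' @param masks region masks (see [generateRegionMasks]).
#' @return list with `piControl` and `deforest`, each a named list of
#'   [FieldStack-class]s (`P`, `T`, `tree_cover`, `veg_carbon`), plus the
#'   drawn `responses` table.
#' @export
generateModelRun <- function(cfg, m, bundle, masks) {
  set.seed(.modelSeed(cfg, m))
  nlat <- length(cfg@lat); nlon <- length(cfg@lon)
  n <- nlat * nlon; ny <- cfg@nYears
  biasP <- rnorm(1, 0, cfg@climBiasSd)
  biasT <- rnorm(1, 0, 0.3)
  climP <- bundle$MAP@values * (1 + biasP)
  climT <- bundle$MAT@values + biasT
  reg <- cfg@regions
  resp <- data.frame(region = reg$region,
                     dPrel = rnorm(nrow(reg), reg$dPrel_mean, reg$dPrel_sd),
                     dT = rnorm(nrow(reg), reg$dT_mean, reg$dT_sd),
                     dCover = rnorm(nrow(reg), reg$dCover_mean, reg$dCover_sd))
  DP <- DT <- DC <- matrix(0, nlat, nlon)
  for (i in seq_len(nrow(resp))) {
    mem <- masks[[resp$region[i]]]@member
    DP[mem] <- resp$dPrel[i]
    DT[mem] <- resp$dT[i]
    DC[mem] <- resp$dCover[i]
  }
  ramp <- pmin(seq_len(ny) / cfg@rampYears, 1)
  tc0 <- bundle$tree_cover@values
  vc0 <- bundle$AGB@values / (0.8 * tc0 + 0.4 * (1 - tc0))
  mkStack <- function(base, delta, noiseSd, clip01 = FALSE, ramped = TRUE) {
    arr <- array(NA_real_, c(nlat, nlon, ny))
    for (t in seq_len(ny)) {
      f <- if (ramped) ramp[t] else 0
      v <- base + f * delta + rnorm(n, 0, 1) * noiseSd
      if (clip01) v <- pmin(1, pmax(0, v))
      arr[, , t] <- v
    }
    arr
  }
  sdP <- cfg@interannualP * climP
  st <- function(arr, units, name)
    FieldStack(arr, cfg@lat, cfg@lon, units = units, name = name)
  ctl <- list(
    P = st(mkStack(climP, 0, sdP, ramped = FALSE), "mm yr-1", "P"),
    T = st(mkStack(climT, 0, cfg@interannualT, ramped = FALSE), "degC", "T"),
    tree_cover = st(mkStack(tc0, 0, 0.003, clip01 = TRUE, ramped = FALSE),
                    "fraction", "tree_cover"),
    veg_carbon = st(mkStack(vc0, 0, 1, ramped = FALSE), "Mg C ha-1",
                    "veg_carbon"))
  def <- list(
    P = st(mkStack(climP, climP * DP / 100, sdP), "mm yr-1", "P"),
    T = st(mkStack(climT, DT, cfg@interannualT), "degC", "T"),
    tree_cover = st(mkStack(tc0, DC / 100, 0.003, clip01 = TRUE),
                    "fraction", "tree_cover"),
    veg_carbon = st(mkStack(vc0, vc0 * DC / 100, 1), "Mg C ha-1",
                    "veg_carbon"))
  list(piControl = ctl, deforest = def, responses = resp)
}

#' Generate the full pseudo-ensemble
#'
#' Loops [generateModelRun] over `cfg@nModels` members. Because each member
#' has its own seed stream, the first k members of an n-model ensemble are
#' identical to a k-model ensemble with the same master seed.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param bundle observation bundle; generated from `cfg` when `NULL`.
#' @param masks region masks; generated when `NULL`.
#' @return named list of model runs (see [generateModelRun]).
#' @export
generateEnsemble <- function(cfg, bundle = NULL, masks = NULL) {
  if (cfg@nYears < cfg@windowYears)
    stop("nYears shorter than the averaging window")
  if (is.null(bundle)) bundle <- generateObservationBundle(cfg)
  if (is.null(masks)) masks <- generateRegionMasks(cfg, bundle$land_fraction)
  runs <- lapply(seq_len(cfg@nModels), generateModelRun, cfg = cfg,
                 bundle = bundle, masks = masks)
  names(runs) <- paste0("model", seq_len(cfg@nModels))
  runs
}

#' Generate idealized CO2-increase pseudo-runs
#'
#' An ensemble-mean pair of transient CO2 runs for the feedback-parameter
#' stage: both share a CO2-fertilization growth of AGB; the fully coupled
#' run additionally feels an injected per-region feedback parameter
#' (`cfg@gammaCo2True`, background -0.5 elsewhere) times the warming, which
#' ramps linearly to 3.5 degC over the run.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param bundle observation bundle; generated when `NULL`.
#' @param masks region masks; generated when `NULL`.
#' @param nYears run length (default 140).
#' @return list with `full` (`T`, `AGB` stacks) and `bgc` (`AGB` stack).
#' @export
generateCo2Runs <- function(cfg, bundle = NULL, masks = NULL, nYears = 140) {
  if (is.null(bundle)) bundle <- generateObservationBundle(cfg)
  if (is.null(masks)) masks <- generateRegionMasks(cfg, bundle$land_fraction)
  set.seed(.modelSeed(cfg, 0L, offset = 777L))
  nlat <- length(cfg@lat); nlon <- length(cfg@lon); n <- nlat * nlon
  G <- matrix(-0.5, nlat, nlon)
  for (nm in names(cfg@gammaCo2True))
    if (!is.null(masks[[nm]])) G[masks[[nm]]@member] <- cfg@gammaCo2True[[nm]]
  warm0 <- 3.5
  Tarr <- Cfull <- Cbgc <- array(NA_real_, c(nlat, nlon, nYears))
  agb0 <- bundle$AGB@values
  for (t in seq_len(nYears)) {
    f <- t / nYears
    Tarr[, , t] <- bundle$MAT@values + warm0 * f + rnorm(n, 0, 0.15)
    grow <- agb0 * (1 + 0.25 * f)
    Cbgc[, , t] <- grow + rnorm(n, 0, 1)
    Cfull[, , t] <- grow + G * warm0 * f + rnorm(n, 0, 1)
  }
  st <- function(arr, units, name)
    FieldStack(arr, cfg@lat, cfg@lon, units = units, name = name)
  list(full = list(T = st(Tarr, "degC", "T"),
                   AGB = st(Cfull, "Mg C ha-1", "AGB")),
       bgc = list(AGB = st(Cbgc, "Mg C ha-1", "AGB")))
}

#' Serialize a config to a plain list
#'
#' Used for the JSON sidecars and the pipeline manifest.
#' @param cfg a [SyntheticConfig-class].
#' @return named list of all configuration values.
#' @export
configToList <- function(cfg) {
  sl <- slotNames(cfg)
  out <- lapply(sl, function(s) {
    v <- slot(cfg, s)
    if (is.data.frame(v)) as.list(v) else v
  })
  names(out) <- sl
  out
}

#' Write the observation bundle as plain text
#'
#' One CSV + JSON sidecar per field (see [writeFieldCSV]) plus a
#' `config.json` recording the full configuration and seed.
#'
#' @param bundle output of [generateObservationBundle].
#' @param dir output directory (created if needed).
#' @param cfg the generating [SyntheticConfig-class].
#' @return `dir`, invisibly.
#' @export
writeBundle <- function(bundle, dir, cfg = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle))
    writeFieldCSV(bundle[[nm]], file.path(dir, paste0(nm, ".csv")))
  if (!is.null(cfg))
    jsonlite::write_json(configToList(cfg), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
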