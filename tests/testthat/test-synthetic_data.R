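test_that("config validity enforces the study-domain invariants", {
  expect_error(syntheticConfig(nModels = 1), "nModels")
  expect_error(syntheticConfig(sigmaObs = -1), "sigmaObs")
  expect_error(syntheticConfig(lat = c(-25, 0, 20)), "23S-23N")
  expect_error(syntheticConfig(nYears = 10, windowYears = 30), "window")
})

test_that("noiseless bundle lies exactly on the generative surface", {
  cfg <- smallCfg(noiseModel = "homoscedastic", sigmaObs = 0,
                  satThreshold = Inf)
  b <- generateObservationBundle(cfg)
  mu <- cfg@interceptTrue + cfg@aTrue * fieldValues(b$MAP) +
    cfg@bTrue * fieldValues(b$MAT)
  expect_equal(fieldValues(b$AGB), pmax(mu, 0))
  pos <- mu > 0
  expect_equal(fieldValues(b$AGB)[pos], mu[pos])  # exact, no noise
})

test_that("identical seeds give bit-identical bundles, different seeds differ", {
  b1 <- generateObservationBundle(smallCfg(seed = 3))
  b2 <- generateObservationBundle(smallCfg(seed = 3))
  b3 <- generateObservationBundle(smallCfg(seed = 4))
  for (nm in names(b1)) {
    expect_identical(fieldValues(b1[[nm]]), fieldValues(b2[[nm]]))
  }
  expect_false(identical(fieldValues(b1$AGB), fieldValues(b3$AGB)))
})

test_that("refit coefficients agree across seeds within sampling error", {
  fits <- t(sapply(1:8, function(s) {
    cfg <- smallCfg(seed = s)
    b <- generateObservationBundle(cfg)
    f <- fitGlobalRegression(b$AGB, b$MAP, b$MAT, linearRegimeMask(cfg, b),
                             robustSE = TRUE)
    c(a = f@a, se = f@seA)
  }))
  # seed-to-seed spread of the estimate is of the order of its SE
  expect_lt(sd(fits[, "a"]), 3 * mean(fits[, "se"]))
  expect_lt(max(abs(fits[, "a"] - 0.034)), 4 * mean(fits[, "se"]))
})

test_that("bundle fields respect their physical ranges and structure", {
  b <- generateObservationBundle(smallCfg(seed = 2))
  MAP <- fieldValues(b$MAP); tc <- fieldValues(b$tree_cover)
  lf <- fieldValues(b$land_fraction)
  expect_true(min(MAP) < 100)    # desert cells exist (exercise the filter)
  expect_true(max(MAP) > 3100)
  expect_true(all(tc >= 0 & tc <= 1))
  expect_true(all(lf >= 0 & lf <= 1))
  expect_true(any(lf < 0.5) && any(lf >= 0.5))
  expect_true(all(fieldValues(b$AGB) >= 0))
  # MAT anticorrelated with MAP
  expect_lt(cor(as.vector(MAP), as.vector(fieldValues(b$MAT))), -0.5)
  # tree cover increases with rainfall on average (binned means monotone)
  bins <- cut(MAP, c(0, 500, 1000, 1500, 2000, 2500, 4000))
  mtc <- tapply(tc, bins, mean)
  expect_true(all(diff(mtc) > 0))
})

test_that("region masks are disjoint and tropical_asia is the stated box", {
  cfg <- smallCfg(seed = 1)
  b <- generateObservationBundle(cfg)
  masks <- generateRegionMasks(cfg, b$land_fraction)
  expect_named(masks, c("amazon", "congo", "tropical_asia"))
  tot <- Reduce(`+`, lapply(masks, function(m) maskMember(m) * 1L))
  expect_true(all(tot <= 1L))  # no cell in two regions
  for (m in masks) expect_gt(sum(maskMember(m)), 0)

  asia <- masks$tropical_asia
  iLat <- match(0.5, gridLat(asia)); iLon <- match(120.5, gridLon(asia))
  land <- fieldValues(b$land_fraction)[iLat, iLon] >= 0.5
  expect_identical(maskMember(asia)[iLat, iLon], land)
  # outside the 10S-10N box no membership regardless of land
  north <- which(gridLat(asia) > 10)
  expect_false(any(maskMember(asia)[north, ]))
  # inside the box but over ocean: never a member
  expect_true(all(fieldValues(b$land_fraction)[maskMember(asia)] >= 0.5))
})

test_that("null-response ensemble produces near-zero deltas", {
  reg <- defoCarbon:::.defaultRegions()
  reg[, -1] <- 0
  cfg <- smallCfg(seed = 6, regions = reg, nModels = 2, climBiasSd = 0)
  b <- generateObservationBundle(cfg)
  masks <- generateRegionMasks(cfg, b$land_fraction)
  run <- generateModelRun(cfg, 1, b, masks)
  d <- deforestationDelta(run$piControl, run$deforest, cfg@windowYears)
  am <- masks$amazon
  expect_lt(abs(as.numeric(areaWeightedMean(d$dP_rel, am))), 0.5)
  expect_lt(abs(as.numeric(areaWeightedMean(d$dT, am))), 0.1)
  expect_lt(abs(as.numeric(areaWeightedMean(d$dCover, am))), 0.5)
})

test_that("identical injected responses and zero noise give identical models", {
  reg <- defoCarbon:::.defaultRegions()
  reg$dPrel_sd <- reg$dT_sd <- reg$dCover_sd <- 0
  cfg <- smallCfg(seed = 9, regions = reg, nModels = 2, climBiasSd = 0,
                  interannualP = 0, interannualT = 0)
  b <- generateObservationBundle(cfg)
  masks <- generateRegionMasks(cfg, b$land_fraction)
  r1 <- generateModelRun(cfg, 1, b, masks)
  r2 <- generateModelRun(cfg, 2, b, masks)
  d1 <- deforestationDelta(r1$piControl, r1$deforest, cfg@windowYears)
  d2 <- deforestationDelta(r2$piControl, r2$deforest, cfg@windowYears)
  expect_equal(fieldValues(d1$dP_rel), fieldValues(d2$dP_rel))
  expect_equal(fieldValues(d1$dT), fieldValues(d2$dT))
})

test_that("regional delta distribution matches the injected one (many models)", {
  cfg <- smallCfg(seed = 13, nModels = 50)
  b <- generateObservationBundle(cfg)
  masks <- generateRegionMasks(cfg, b$land_fraction)
  am <- masks$amazon
  prel <- dT <- numeric(cfg@nModels)
  for (m in seq_len(cfg@nModels)) {
    run <- generateModelRun(cfg, m, b, masks)
    d <- deforestationDelta(run$piControl, run$deforest, cfg@windowYears)
    prel[m] <- as.numeric(areaWeightedMean(d$dP_rel, am))
    dT[m] <- as.numeric(areaWeightedMean(d$dT, am))
  }
  # injected amazon responses: dPrel ~ N(-6.7, 4.7), dT ~ N(0.5, 0.5)
  expect_lt(abs(mean(prel) + 6.7), 3 * 4.7 / sqrt(50))
  expect_lt(abs(sd(prel) - 4.7) / 4.7, 0.3)
  expect_lt(abs(mean(dT) - 0.5), 3 * 0.5 / sqrt(50))
  expect_lt(abs(sd(dT) - 0.5) / 0.5, 0.3)
})

test_that("per-model seed streams make early members stable when models are added", {
  cfg2 <- smallCfg(seed = 21, nModels = 2)
  cfg5 <- smallCfg(seed = 21, nModels = 5)
  b <- generateObservationBundle(cfg2)
  masks <- generateRegionMasks(cfg2, b$land_fraction)
  r2 <- generateModelRun(cfg2, 2, b, masks)
  r2b <- generateModelRun(cfg5, 2, b, masks)
  expect_identical(fieldValues(r2$deforest$P), fieldValues(r2b$deforest$P))
})

test_that("synthetic CO2 runs encode the injected feedback parameter", {
  cfg <- smallCfg(seed = 17)
  b <- generateObservationBundle(cfg)
  masks <- generateRegionMasks(cfg, b$land_fraction)
  co2 <- generateCo2Runs(cfg, b, masks, nYears = 140)
  dC <- function(st) fieldValues(timeWindowMean(st, "last", 20)) -
    fieldValues(timeWindowMean(st, "first", 20))
  num <- Field(dC(co2$full$AGB) - dC(co2$bgc$AGB), cfg@lat, cfg@lon)
  den <- Field(dC(co2$full$T), cfg@lat, cfg@lon)
  g <- regionalGamma(num, den, masks$amazon)
  expect_equal(g, unname(cfg@gammaCo2True["amazon"]), tolerance = 0.15)
})

test_that("bundle writer emits one CSV per field plus a config sidecar", {
  cfg <- smallCfg(seed = 1)
  b <- generateObservationBundle(cfg)
  d <- withr::local_tempdir()
  writeBundle(b, d, cfg)
  expect_setequal(list.files(d, pattern = "\\.csv$"),
                  paste0(names(b), ".csv"))
  cfgBack <- jsonlite::read_json(file.path(d, "config.json"),
                                 simplifyVector = TRUE)
  expect_equal(cfgBack$seed, 1)
  expect_equal(cfgBack$aTrue, cfg@aTrue)
  rt <- readFieldCSV(file.path(d, "MAP.csv"))
  expect_identical(fieldValues(rt), fieldValues(b$MAP))
})
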