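test_that("vegetation carbon converts to AGB via the tree-cover blend", {
  expect_equal(vegcToAgb(100, 1), 80)
  expect_equal(vegcToAgb(100, 0), 40)
  expect_equal(vegcToAgb(100, 0.5), 60)
  expect_error(vegcToAgb(100, 1.2), "0, 1")
  f <- tinyField(matrix(100, 2, 2))
  tc <- tinyField(matrix(c(0, 1, 0.5, 0.25), 2, 2))
  expect_equal(fieldValues(vegcToAgb(f, tc)),
               matrix(c(40, 80, 60, 50), 2, 2))
})

test_that("dry biomass carries a carbon fraction of one half", {
  expect_equal(dryBiomassToCarbon(100), 50)
  expect_equal(dryBiomassToCarbon(0), 0)
  expect_equal(dryBiomassToCarbon(37), 18.5)
  expect_error(dryBiomassToCarbon(-1), "non-negative")
})

test_that("domain filters drop deserts, ocean-edge cells and missing data", {
  lat <- c(-0.5, 0.5); lon <- c(0.5, 1.5, 2.5)
  mk <- function(v, u = "") Field(matrix(v, 2, 3, byrow = TRUE), lat, lon, u)
  bundle <- list(
    MAP = mk(c(80, 2000, 2000, 500, 1500, NA)),
    MAT = mk(25), AGB = mk(50),
    land_fraction = mk(c(1, 0.4, 1, 1, 1, 1)))
  keep <- applyDomainFilters(bundle)
  expect_identical(as.vector(t(keep)),
                   c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
  bundle$MAP <- mk(80)
  expect_error(applyDomainFilters(bundle), "no analysis cells")
})

test_that("global regression recovers noiseless coefficients exactly", {
  set.seed(1)
  map <- matrix(runif(60, 200, 3000), 6, 10)
  mat <- matrix(runif(60, 20, 30), 6, 10)
  agb <- 12 + 0.03 * map - 0.4 * mat
  f <- fitGlobalRegression(agb, map, mat)
  expect_equal(f@a, 0.03, tolerance = 1e-10)
  expect_equal(f@b, -0.4, tolerance = 1e-10)
  expect_equal(f@intercept, 12, tolerance = 1e-8)
  expect_equal(f@r2, 1)
  expect_lt(f@rmse, 1e-8)
})

test_that("OLS coefficients match the closed-form normal equations", {
  # hand-sized problem solvable by solve(X'X, X'y)
  map <- c(500, 1200, 2100, 2900, 800, 1700)
  mat <- c(29, 27, 25, 24, 28, 26)
  agb <- c(8, 30, 61, 75, 15, 49)
  f <- fitGlobalRegression(matrix(agb, 1), matrix(map, 1), matrix(mat, 1))
  beta <- as.vector(olsOracle(agb, cbind(1, map, mat)))
  # QR solution vs normal equations: agreement to the oracle's conditioning
  expect_equal(c(f@intercept, f@a, f@b), beta, tolerance = 1e-6)
  expect_error(fitGlobalRegression(matrix(agb, 1), matrix(map, 1),
                                   matrix(map / 100, 1)), "collinear")
})

test_that("OLS residuals are orthogonal to the regressors", {
  set.seed(7)
  map <- runif(200, 100, 3000); mat <- runif(200, 20, 32)
  agb <- 5 + 0.02 * map - 0.3 * mat + rnorm(200, 0, 10)
  f <- fitGlobalRegression(matrix(agb, 1), matrix(map, 1), matrix(mat, 1))
  res <- agb - (f@intercept + f@a * map + f@b * mat)
  expect_lt(abs(sum(res * map)) / sum(abs(res * map)), 1e-10)
  expect_lt(abs(sum(res * mat)) / sum(abs(res * mat)), 1e-10)
  # relative sensitivity identity by construction
  expect_equal(f@deltaMAP, 100 * f@a * 100 / mean(agb))
  expect_equal(f@deltaMAT, 100 * f@b / mean(agb))
})

test_that("moving window on homogeneous linear data gives a flat curve", {
  set.seed(3)
  map <- matrix(runif(4000, 100, 3600), 40, 100)
  mat <- matrix(runif(4000, 20, 32), 40, 100)
  agb <- 10 + 0.03 * map - 0.5 * mat + matrix(rnorm(4000, 0, 2), 40, 100)
  cv <- curveTable(fitMovingWindow(agb, map, mat))
  expect_equal(nrow(cv), 26)
  expect_identical(cv$level, seq(600, 3100, by = 100))
  expect_lt(max(cv$a) - min(cv$a), 0.004)
  expect_true(all(cv$sigA & cv$sigB))

  # a window at least as wide as the data range reproduces the global fit
  g <- fitGlobalRegression(agb, map, mat)
  wide <- curveTable(fitMovingWindow(agb, map, mat, levels = 1800,
                                     halfWidth = 4000))
  expect_equal(wide$a, g@a)
  expect_equal(wide$b, g@b)
  expect_equal(wide$n, g@nCells)
})

test_that("moving window localizes a piecewise slope change", {
  set.seed(4)
  n <- 6000
  map <- matrix(runif(n, 100, 3600), 60, 100)
  mat <- matrix(runif(n, 20, 32), 60, 100)
  base <- 0.02
  slope <- ifelse(map >= 1500 & map <= 2000, 2 * base, base)
  # integrated piecewise-linear response in MAP
  y <- base * pmin(map, 1500) + 2 * base * pmin(pmax(map - 1500, 0), 500) +
    base * pmax(map - 2000, 0) - 0.3 * mat + matrix(rnorm(n, 0, 1), 60, 100)
  cv <- curveTable(fitMovingWindow(y, map, mat))
  peak <- cv$level[which.max(cv$a)]
  expect_gte(peak, 1500)
  expect_lte(peak, 2000)
})

test_that("sparse windows are flagged not significant but still reported", {
  set.seed(9)
  map <- matrix(runif(80, 100, 1200), 8, 10)
  mat <- matrix(runif(80, 20, 30), 8, 10)
  agb <- 5 + 0.03 * map - 0.2 * mat + matrix(rnorm(80, 0, 1), 8, 10)
  cv <- curveTable(fitMovingWindow(agb, map, mat, minCells = 30))
  dryn <- cv[cv$level == 600, ]
  expect_gt(dryn$n, 30)
  wet <- cv[cv$level == 3100, ]   # no cells that far wet
  expect_identical(wet$n, length(map[map >= 2600]))
  expect_false(wet$significant)
})

test_that("seasonality covariates match brute-force definitions", {
  p <- array(100, c(1, 1, 12)); tmp <- array(25, c(1, 1, 12))
  cv <- derivedCovariates(p, tmp)
  expect_equal(as.vector(cv$Pamp), 0)
  expect_equal(as.vector(cv$PRD), 300)

  p2 <- array(c(0, 0, 0, rep(200, 9)), c(1, 1, 12))
  expect_equal(as.vector(derivedCovariates(p2, tmp)$PRD), 0)

  t3 <- array(20:31, c(1, 1, 12))
  cv3 <- derivedCovariates(p, t3)
  expect_equal(as.vector(cv3$Tamp), 11)
  expect_equal(as.vector(cv3$MAXT), 31)

  # random monthly rainfall: PRD equals the minimum over all 12 cyclic
  # 3-month sums computed by explicit enumeration
  set.seed(12)
  pr <- array(runif(2 * 3 * 12, 0, 300), c(2, 3, 12))
  tr <- array(runif(2 * 3 * 12, 18, 32), c(2, 3, 12))
  got <- derivedCovariates(pr, tr)
  for (i in 1:2) for (j in 1:3) {
    sums <- sapply(1:12, function(k)
      sum(pr[i, j, (c(k, k + 1, k + 2) - 1) %% 12 + 1]))
    expect_equal(got$PRD[i, j], min(sums))
    expect_equal(got$Pamp[i, j], max(pr[i, j, ]) - min(pr[i, j, ]))
  }
  expect_error(derivedCovariates(pr[, , 1:11, drop = FALSE], tr), "12")
})

test_that("collinearity diagnostics follow the singular-value construction", {
  X <- cbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0))
  d <- collinearityDiagnostics(X)
  expect_equal(unname(d$conditionIndices), rep(1, 3))
  expect_equal(nrow(d$flagged), 0)

  Xdup <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  ddup <- collinearityDiagnostics(Xdup)
  expect_true(any(!is.finite(ddup$conditionIndices) |
                    ddup$conditionIndices > 1e6))
  expect_gt(nrow(ddup$flagged), 0)

  set.seed(21)
  x1 <- rnorm(300); x2 <- 0.99 * x1 + sqrt(1 - 0.99^2) * rnorm(300)
  Xc <- cbind(x1 = x1, x2 = x2)
  dc <- collinearityDiagnostics(Xc)
  sv <- svd(sweep(Xc, 2, sqrt(colSums(Xc^2)), "/"))$d
  expect_equal(unname(dc$conditionIndices), max(sv) / sv)
  expect_true(all(abs(colSums(dc$varianceProportions) - 1) < 1e-10))
  expect_error(collinearityDiagnostics(cbind(x1, 0)), "zero-variance")
})

test_that("adding correlated covariates never lowers R-squared", {
  cfg <- smallCfg(seed = 5)
  b <- generateObservationBundle(cfg)
  keep <- applyDomainFilters(b)
  df <- data.frame(agb = fieldValues(b$AGB)[keep],
                   map = fieldValues(b$MAP)[keep],
                   mat = fieldValues(b$MAT)[keep])
  # proxies of the seasonality covariates, collinear with MAP and MAT
  set.seed(5)
  df$pamp <- 0.3 * df$map + rnorm(nrow(df), 0, 40)
  df$maxt <- df$mat + 4 + rnorm(nrow(df), 0, 0.5)
  r2base <- summary(lm(agb ~ map + mat, df))$r.squared
  r2full <- summary(lm(agb ~ map + mat + pamp + maxt, df))$r.squared
  expect_gte(r2full, r2base)
  expect_lt(r2full - r2base, 0.02)  # no real improvement, mirroring the data
})
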