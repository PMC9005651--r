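mkCurve <- function(level, a, b, sigA = TRUE, sigB = TRUE) {
  tb <- data.frame(level = level, a = a, b = b, intercept = 0,
                   seA = NA_real_, seB = NA_real_, pA = NA_real_,
                   pB = NA_real_, r2 = NA_real_, rmse = NA_real_,
                   n = 1000L, sigA = sigA, sigB = sigB,
                   significant = sigA & sigB)
  new("SensitivityCurve", table = tb, halfWidth = 500, alpha = 0.001,
      minCells = 30)
}

test_that("background rainfall applies the relative change to the climatology", {
  clim <- tinyField(matrix(2000, 1, 1), units = "mm yr-1")
  expect_equal(as.vector(fieldValues(backgroundRainfall(clim, -6.7))), 1866)
  expect_equal(as.vector(fieldValues(backgroundRainfall(clim, 0))), 2000)
  # post-deforestation level for the wet-forest climatology
  clim2 <- tinyField(matrix(2240, 1, 1))
  expect_equal(as.vector(fieldValues(backgroundRainfall(clim2, -6.7))),
               2089.92)
  # floored at zero for extreme declines
  expect_equal(as.vector(fieldValues(backgroundRainfall(clim, -150))), 0)
})

test_that("sensitivity lookup interpolates and zeroes non-significant levels", {
  cv <- mkCurve(c(2000, 2100), c(0.02, 0.04), c(-0.3, -0.1))
  at <- function(bg) sensitivityLookup(cv, tinyField(matrix(bg, 1, 1)))
  expect_equal(as.vector(fieldValues(at(2000)$sP)), 0.02)  # node value
  expect_equal(as.vector(fieldValues(at(2050)$sP)), 0.03)  # midway
  expect_equal(as.vector(fieldValues(at(2050)$sT)), -0.2)
  # beyond the range: nearest endpoint
  expect_equal(as.vector(fieldValues(at(500)$sP)), 0.02)
  expect_equal(as.vector(fieldValues(at(3500)$sP)), 0.04)

  # both bracketing levels non-significant: exactly zero (wettest areas)
  cvn <- mkCurve(c(2500, 2600, 2700), c(0.02, 0.015, 0.01),
                 c(0, 0, 0), sigA = c(TRUE, FALSE, FALSE))
  expect_equal(as.vector(fieldValues(
    sensitivityLookup(cvn, tinyField(matrix(2650, 1, 1)))$sP)), 0)
  # joint mode masks both coefficients by the joint flag
  cvj <- mkCurve(2000, 0.03, -0.3, sigA = TRUE, sigB = FALSE)
  lk <- sensitivityLookup(cvj, tinyField(matrix(2000, 1, 1)), mode = "joint")
  expect_equal(as.vector(fieldValues(lk$sP)), 0)
})

test_that("biophysical change is the product of sensitivities and deltas", {
  z <- biophysicalAgbChange(0.034, -0.32, 0, 0)
  expect_equal(z$total, 0)
  r <- biophysicalAgbChange(0.034, -0.32, -150, 0.5)
  expect_equal(r$total, -5.26)
  expect_equal(r$precipTerm, -5.1)
  expect_equal(r$tempTerm, -0.16)
  # the precipitation share of the loss dominates, as over the wet tropics
  expect_equal(r$precipTerm / r$total, 5.1 / 5.26, tolerance = 1e-12)
  expect_gt(r$precipTerm / r$total, 0.8)

  # cellwise decomposition is exact on fields
  set.seed(6)
  sP <- tinyField(matrix(runif(12, 0, 0.04), 3, 4))
  sT <- tinyField(matrix(runif(12, -0.5, 0), 3, 4))
  dP <- tinyField(matrix(rnorm(12, -100, 30), 3, 4))
  dT <- tinyField(matrix(rnorm(12, 0.4, 0.2), 3, 4))
  out <- biophysicalAgbChange(sP, sT, dP, dT)
  expect_equal(fieldValues(out$total),
               fieldValues(out$precipTerm) + fieldValues(out$tempTerm))
})

test_that("tree-cover slope matches constructed and closed-form values", {
  tc <- matrix(seq(0.1, 0.9, length.out = 40), 4, 10)
  agb <- 200 * tc + 5       # 2.0 Mg C ha-1 per percentage point
  expect_equal(as.numeric(treecoverAgbSlope(agb, tc)), 20)

  # 4-point hand OLS against the normal equations
  x <- c(10, 30, 50, 80); y <- c(25, 60, 95, 170)
  beta <- olsOracle(y, cbind(1, x))
  got <- treecoverAgbSlope(matrix(y, 1), matrix(x, 1))
  expect_equal(as.numeric(got), beta[2] * 10)
  expect_error(treecoverAgbSlope(matrix(y, 1), matrix(0.5, 1, 4)),
               "degenerate")
})

test_that("direct loss scales cover change by the cover-biomass slope", {
  expect_equal(directAgbLoss(-44.7, 22), -98.34)
  expect_equal(directAgbLoss(0, 22), 0)
  expect_equal(directAgbLoss(-10, 20), -20)
  expect_error(directAgbLoss(-10, -3), "positive")
})

test_that("percent additionality is scale invariant and handles edge cases", {
  expect_equal(percentAdditionality(-5.0, -98.3), 100 * 5 / 98.3)
  expect_equal(percentAdditionality(0, -62.4), 0)
  expect_error(percentAdditionality(-5, 0), "non-zero")
  for (c0 in c(0.1, 2, 37)) {
    expect_equal(percentAdditionality(-2.9 * c0, -75.5 * c0),
                 percentAdditionality(-2.9, -75.5))
  }
})

test_that("quadrature propagation is monotone with exact limiting cases", {
  expect_equal(propagateUncertainty(0.034, -0.32, 0, 0), 0)
  expect_equal(propagateUncertainty(0.034, -0.32, 105, 0),
               0.034 * 105)
  s1 <- propagateUncertainty(0.034, -0.32, 56, 0.5)
  s2 <- propagateUncertainty(0.034, -0.32, 105, 0.5)
  s3 <- propagateUncertainty(0.034, -0.32, 105, 0.9)
  expect_true(s1 < s2 && s2 < s3)
  expect_error(propagateUncertainty(0.034, -0.32, -1, 0.5), ">= 0")
})

test_that("combined additionality sums and rounds to integer percent", {
  expect_identical(combineAdditionality(0, 0), 0)
  expect_identical(combineAdditionality(19, 3.8), 23)
  expect_error(combineAdditionality(-1, 5), "non-negative")
})
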