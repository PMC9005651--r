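# Spatial sensitivity of aboveground biomass (AGB) to mean annual
# precipitation (MAP) and temperature (MAT): unit conversions, domain
# filters, the global OLS fit, the moving-window fit along the rainfall
# gradient, derived seasonality covariates and Belsley collinearity
# diagnostics.

.asMatrixLike <- function(x) if (is(x, "Field")) x@values else as.matrix(x)

#' Convert simulated vegetation carbon to aboveground biomass
#'
#' Total vegetation carbon is converted to AGB with an empirical
#' aboveground-to-total ratio of 0.8 for forests and 0.4 for savannas,
#' blended by the tree-cover fraction:
#' `AGB = vegC * (0.8 * tc + 0.4 * (1 - tc))`.
#'
#' @param vegCarbon vegetation carbon [Field-class] or matrix (Mg C ha-1).
#' @param treeCover tree-cover fraction in \[0, 1\], same grid.
#' @return AGB on the same grid (Field in, Field out).
#' @examples
#' vegcToAgb(100, 1)    # 80
#' vegcToAgb(100, 0.5)  # 60
#' @export
vegcToAgb <- function(vegCarbon, treeCover) {
  tc <- if (is(treeCover, "Field")) treeCover@values else treeCover
  if (any(tc < 0 | tc > 1, na.rm = TRUE))
    stop("tree cover must lie in [0, 1]")
  fac <- 0.8 * tc + 0.4 * (1 - tc)
  if (is(vegCarbon, "Field"))
    Field(vegCarbon@values * fac, vegCarbon@lat, vegCarbon@lon,
          units = "Mg C ha-1", name = "AGB")
  else vegCarbon * fac
}

#' Convert dry aboveground biomass to carbon
#'
#' Dry biomass (Mg ha-1) carries a carbon fraction of 0.5.
#'
#' @param agbDry dry biomass, Mg ha-1 (Field, matrix or numeric), >= 0.
#' @return carbon stock, Mg C ha-1.
#' @export
dryBiomassToCarbon <- function(agbDry) {
  v <- if (is(agbDry, "Field")) agbDry@values else agbDry
  if (any(v < 0, na.rm = TRUE)) stop("dry biomass must be non-negative")
  if (is(agbDry, "Field"))
    Field(v * 0.5, agbDry@lat, agbDry@lon, units = "Mg C ha-1",
          name = agbDry@name)
  else v * 0.5
}

#' Analysis-domain filter
#'
#' Cells enter the regression when they lie within 23S-23N, have
#' MAP >= 100 mm yr-1 (excludes deserts), land fraction >= 0.5 (excludes
#' ocean-dominated edge pixels) and all regressors non-missing.
#'
#' @param bundle named list with [Field-class] elements `MAP`, `MAT`, `AGB`,
#'   `land_fraction` on one grid.
#' @param latLimit half-width of the tropical belt (degrees).
#' @param minMAP minimum mean annual precipitation (mm yr-1).
#' @param minLand minimum land fraction.
#' @return logical matrix on the grid (TRUE = analysis cell).
#' @export
applyDomainFilters <- function(bundle, latLimit = 23, minMAP = 100,
                               minLand = 0.5) {
  MAP <- bundle$MAP; MAT <- bundle$MAT
  AGB <- bundle$AGB; lf <- bundle$land_fraction
  stopifnot(is(MAP, "Field"), is(MAT, "Field"), is(AGB, "Field"),
            is(lf, "Field"))
  latOK <- matrix(abs(MAP@lat) <= latLimit, nrow(MAP@values), ncol(MAP@values))
  keep <- latOK & MAP@values >= minMAP & lf@values >= minLand &
    !is.na(MAP@values) & !is.na(MAT@values) & !is.na(AGB@values)
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop("domain filters leave no analysis cells")
  keep
}

.olsFit <- function(y, x1, x2, intercept = TRUE, robustSE = FALSE) {
  n <- length(y)
  X <- if (intercept) cbind(1, x1, x2) else cbind(x1, x2)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient design (MAP, MAT collinear)")
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  p <- ncol(X)
  sigma2 <- sum(res^2) / (n - p)
  XtXinv <- chol2inv(qr.R(qrX))
  se <- if (robustSE) {
    # HC1 heteroskedasticity-consistent covariance
    meat <- crossprod(X * as.vector(res))
    sqrt(diag(XtXinv %*% meat %*% XtXinv) * n / (n - p))
  } else sqrt(diag(XtXinv) * sigma2)
  tval <- beta / se
  pval <- 2 * pt(abs(tval), df = n - p, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  i <- if (intercept) 2L else 1L
  list(a = unname(beta[i]), b = unname(beta[i + 1L]),
       intercept = if (intercept) unname(beta[1]) else 0,
       seA = unname(se[i]), seB = unname(se[i + 1L]),
       pA = unname(pval[i]), pB = unname(pval[i + 1L]),
       r2 = max(0, min(1, 1 - sum(res^2) / tss)),
       rmse = sqrt(mean(res^2)), n = n, residuals = as.vector(res))
}

#' Global spatial regression of AGB on climate
#'
#' Ordinary least squares of AGB on MAP and MAT over the analysis cells
#' (intercept included by default). The relative sensitivities are
#' `deltaMAP = 100 * (a * 100) / mean(AGB)` (% per 100 mm yr-1) and
#' `deltaMAT = 100 * b / mean(AGB)` (% per degC).
#'
#' @param AGB,MAP,MAT [Field-class] objects or matrices on one grid.
#' @param cells logical matrix of analysis cells (see [applyDomainFilters]),
#'   or `NULL` for all non-missing cells.
#' @param intercept include an intercept (default TRUE).
#' @param robustSE use HC1 heteroskedasticity-consistent standard errors
#'   (coefficients are unchanged).
#' @return A [RegressionFit-class].
#' @export
fitGlobalRegression <- function(AGB, MAP, MAT, cells = NULL, intercept = TRUE,
                                robustSE = FALSE) {
  agb <- .asMatrixLike(AGB); map <- .asMatrixLike(MAP); mat <- .asMatrixLike(MAT)
  if (is.null(cells)) cells <- !(is.na(agb) | is.na(map) | is.na(mat))
  y <- agb[cells]; x1 <- map[cells]; x2 <- mat[cells]
  if (length(y) < 4L) stop("need at least 4 cells for the regression")
  f <- .olsFit(y, x1, x2, intercept = intercept, robustSE = robustSE)
  mAGB <- mean(y)
  new("RegressionFit", a = f$a, b = f$b, intercept = f$intercept,
      r2 = f$r2, rmse = f$rmse, nCells = as.integer(f$n),
      seA = f$seA, seB = f$seB, pA = f$pA, pB = f$pB,
      deltaMAP = 100 * (f$a * 100) / mAGB, deltaMAT = 100 * f$b / mAGB)
}

#' Moving-window sensitivity along the rainfall gradient
#'
#' Fits the AGB ~ MAP + MAT regression within overlapping precipitation
#' windows `[L - halfWidth, L + halfWidth]` (closed interval) centered at
#' each level `L`. A coefficient is flagged significant when its two-sided
#' t-test p-value is below `alpha`; the joint `significant` flag requires
#' both climate coefficients. Windows with fewer than `minCells` cells are
#' fitted when possible but flagged not significant.
#'
#' @inheritParams fitGlobalRegression
#' @param levels window centers, mm yr-1.
#' @param halfWidth window half width, mm yr-1.
#' @param alpha significance level.
#' @param minCells minimum cells for a significance-eligible window.
#' @return A [SensitivityCurve-class].
#' @export
fitMovingWindow <- function(AGB, MAP, MAT, cells = NULL,
                            levels = seq(600, 3100, by = 100),
                            halfWidth = 500, alpha = 0.001, minCells = 30,
                            intercept = TRUE) {
  agb <- .asMatrixLike(AGB); map <- .asMatrixLike(MAP); mat <- .asMatrixLike(MAT)
  if (is.null(cells)) cells <- !(is.na(agb) | is.na(map) | is.na(mat))
  y0 <- agb[cells]; x10 <- map[cells]; x20 <- mat[cells]
  rows <- lapply(levels, function(L) {
    w <- x10 >= L - halfWidth & x10 <= L + halfWidth
    n <- sum(w)
    if (n >= 4L && length(unique(x10[w])) > 2L) {
      f <- tryCatch(.olsFit(y0[w], x10[w], x20[w], intercept = intercept),
                    error = function(e) NULL)
    } else f <- NULL
    if (is.null(f)) {
      data.frame(level = L, a = NA_real_, b = NA_real_, intercept = NA_real_,
                 seA = NA_real_, seB = NA_real_, pA = NA_real_, pB = NA_real_,
                 r2 = NA_real_, rmse = NA_real_, n = n,
                 sigA = FALSE, sigB = FALSE, significant = FALSE)
    } else {
      eligible <- n >= minCells
      sigA <- eligible && is.finite(f$pA) && f$pA < alpha
      sigB <- eligible && is.finite(f$pB) && f$pB < alpha
      data.frame(level = L, a = f$a, b = f$b, intercept = f$intercept,
                 seA = f$seA, seB = f$seB, pA = f$pA, pB = f$pB,
                 r2 = f$r2, rmse = f$rmse, n = n,
                 sigA = sigA, sigB = sigB, significant = sigA && sigB)
    }
  })
  new("SensitivityCurve", table = do.call(rbind, rows),
      halfWidth = halfWidth, alpha = alpha, minCells = minCells)
}

#' Seasonality covariates from monthly climate
#'
#' From 12 monthly precipitation and temperature fields derives:
#' `MAXT` (maximum of the supplied monthly temperatures), `Pamp` and `Tamp`
#' (wettest-minus-driest / warmest-minus-coldest month), and `PRD` (minimum
#' rainfall of any 3 consecutive months, cyclic across the year boundary).
#'
#' @param monthlyP,monthlyT 3-D arrays `(lat, lon, 12)`.
#' @return list of matrices `MAXT`, `Pamp`, `Tamp`, `PRD` plus
#'   `maxtMethod` recording how MAXT was derived.
#' @export
derivedCovariates <- function(monthlyP, monthlyT) {
  if (dim(monthlyP)[3] != 12L || dim(monthlyT)[3] != 12L)
    stop("12 monthly values per cell are required")
  if (any(is.na(monthlyP)) || any(is.na(monthlyT)))
    stop("missing months are not allowed")
  pmax12 <- apply(monthlyP, c(1, 2), max)
  pmin12 <- apply(monthlyP, c(1, 2), min)
  tmax12 <- apply(monthlyT, c(1, 2), max)
  tmin12 <- apply(monthlyT, c(1, 2), min)
  prd <- NULL
  for (k in 1:12) {
    idx <- ((k - 1):(k + 1)) %% 12 + 1  # cyclic 3-month window
    s <- monthlyP[, , idx[1]] + monthlyP[, , idx[2]] + monthlyP[, , idx[3]]
    prd <- if (is.null(prd)) s else pmin(prd, s)
  }
  list(MAXT = tmax12, Pamp = pmax12 - pmin12, Tamp = tmax12 - tmin12,
       PRD = prd, maxtMethod = "max of supplied monthly values")
}

#' Belsley collinearity diagnostics
#'
#' Columns are scaled to unit length and decomposed by singular values.
#' Condition indices are `max(d) / d`; the variance-decomposition proportion
#' of coefficient j attributable to singular value k is
#' `(v_jk^2 / d_k^2) / sum_k(v_jk^2 / d_k^2)`. A pair of columns is flagged
#' collinear when a condition index above `threshold` carries more than
#' `propLimit` of the variance of both.
#'
#' @param X numeric matrix of design columns (no constant column needed
#'   unless you want the intercept diagnosed too).
#' @param threshold condition-index threshold (default 30).
#' @param propLimit variance-proportion threshold (default 0.5).
#' @return list with `conditionIndices`, `varianceProportions`
#'   (rows = condition indices, columns = variables) and `flagged`
#'   (data.frame of column pairs).
#' @export
collinearityDiagnostics <- function(X, threshold = 30, propLimit = 0.5) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("at least two columns are required")
  len <- sqrt(colSums(X^2))
  if (any(len == 0)) stop("zero-variance (all-zero) column")
  Xs <- sweep(X, 2, len, "/")
  sv <- svd(Xs)
  d <- sv$d
  eps <- max(d) * 1e-12
  ci <- ifelse(d > eps, max(d) / d, Inf)
  phi <- sweep(sv$v^2, 2, pmax(d, eps)^2, "/")  # vars x components
  pi_kj <- t(sweep(phi, 1, rowSums(phi), "/"))  # components x vars
  colnames(pi_kj) <- colnames(X, do.NULL = FALSE, prefix = "V")
  flagged <- list()
  for (k in which(ci > threshold)) {
    heavy <- which(pi_kj[k, ] > propLimit)
    if (length(heavy) >= 2L) {
      cmb <- utils::combn(heavy, 2)
      for (q in seq_len(ncol(cmb)))
        flagged[[length(flagged) + 1L]] <- data.frame(
          index = k, conditionIndex = ci[k],
          var1 = colnames(pi_kj)[cmb[1, q]], var2 = colnames(pi_kj)[cmb[2, q]])
    }
  }
  flagged <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(index = integer(), conditionIndex = numeric(),
               var1 = character(), var2 = character())
  list(conditionIndices = ci, varianceProportions = pi_kj, flagged = flagged)
}
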