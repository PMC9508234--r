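#' Select dominant climate variables (random forest + stepwise)
#'
#' Two-stage selection of the climate variables that drive NDVI: (i) a
#' random-forest regression on a seeded subsample of pixel-years scores all
#' candidates by permutation importance (the scaled %IncMSE, a z-like
#' statistic over trees) and screens in those with score > `importanceZ`;
#' (ii) bidirectional p-value stepwise regression on the spatially averaged
#' regional series (entry p <= 0.05, removal p >= 0.10) retains the
#' significant survivors.  The returned set is the variables passing both
#' stages, ordered by forest importance.  When the stepwise stage retains
#' nothing although screened variables exist -- which happens whenever
#' regional responses of opposite sign cancel in the spatial average -- the
#' screened set itself is returned (logged in the `path` attribute), since
#' the pixel-level forest is the stage that remains informative there.
#' Constant candidates are excluded with a warning.  Deterministic given
#' `seed`.
#'
#' @param ndvi NDVI [GridStack-class] (response).
#' @param climate named list of candidate climate `GridStack`s.
#' @param entryP,removalP stepwise entry/removal p-value thresholds.
#' @param importanceZ forest-importance screening threshold (scaled
#'   %IncMSE).
#' @param nTrees random-forest size.
#' @param maxRows cap on sampled pixel-years for the forest.
#' @param seed integer seed.
#' @return Character vector of selected variable names, with attributes
#'   `importance` (named %IncMSE ranking over all candidates) and `path`
#'   (stepwise entry/removal log).
#' @export
selectClimateVariables <- function(ndvi, climate, entryP = 0.05,
                                   removalP = 0.10, importanceZ = 2,
                                   nTrees = 500L, maxRows = 100000L,
                                   seed = 1L) {
  if (length(climate) < 1L) stop("no candidate variables")
  ny <- nYears(ndvi)
  if (ny < 10L) stop("need >= 10 years for variable selection")
  yFlat <- matrix(ndvi@values, nrow = ny)
  xFlat <- lapply(climate, function(s) matrix(s@values, nrow = ny))

  keep <- vapply(xFlat, function(m) sd(m, na.rm = TRUE) > 0, TRUE)
  if (any(!keep))
    warning("excluding constant candidate(s): ",
            paste(names(climate)[!keep], collapse = ", "))
  vars <- names(climate)[keep]
  if (!length(vars)) return(character())

  # stage 1: random-forest importance on sampled pixel-years.  Values are
  # two-way centred (per pixel and per year) first: static spatial
  # gradients would otherwise dominate the pooled sample, and regionally
  # coherent weather anomalies would otherwise let any variable act as a
  # proxy for the year and predict the yearly mean NDVI regardless of any
  # real response.  What remains is each variable's pixel-level anomaly,
  # so importance measures the local NDVI response.
  demean2 <- function(m) {
    m <- sweep(m, 2L, colMeans(m, na.rm = TRUE))
    m - rowMeans(m, na.rm = TRUE)
  }
  df <- data.frame(ndvi = as.vector(demean2(yFlat)))
  for (v in vars) df[[v]] <- as.vector(demean2(xFlat[[v]]))
  # pixel coordinates as context features, so the forest can represent
  # responses whose sign or strength varies across the scene
  d <- gridDim(ndvi)
  px <- seq_len(d[1L] * d[2L]) - 1L
  df$.row <- rep(px %% d[1L] + 1L, each = ny)
  df$.col <- rep(px %/% d[1L] + 1L, each = ny)
  df <- df[complete.cases(df), , drop = FALSE]
  set.seed(seed)
  if (nrow(df) > maxRows) df <- df[sample.int(nrow(df), maxRows), ]
  rf <- randomForest::randomForest(ndvi ~ ., data = df, ntree = nTrees,
                                   importance = TRUE)
  imp <- randomForest::importance(rf, type = 1L)[vars, 1L]
  imp <- sort(imp, decreasing = TRUE)
  screened <- names(imp)[imp > importanceZ]
  if (!length(screened)) {
    out <- character()
    attr(out, "importance") <- imp
    attr(out, "path") <- "no variable passed the importance screen"
    return(out)
  }

  # stage 2: bidirectional p-value stepwise on the regional mean series.
  # A time covariate is always in the base model: any secular NDVI trend
  # (including a human-activity trend) would otherwise be soaked up by
  # whichever candidate happens to correlate with time, making the entry
  # tests invalid.  Candidates are therefore judged on the interannual
  # variation they explain.
  regY <- rowMeans(yFlat, na.rm = TRUE)
  regX <- vapply(xFlat[screened], function(m) rowMeans(m, na.rm = TRUE),
                 numeric(ny))
  tau <- ndvi@years - mean(ndvi@years)
  pOf <- function(members) {
    X <- regX[, members, drop = FALSE]
    cf <- summary(lm(regY ~ tau + X))$coefficients
    vapply(members, function(v) {
      rn <- paste0("X", v)
      if (!rn %in% rownames(cf) && "X" %in% rownames(cf)) rn <- "X"
      if (rn %in% rownames(cf)) cf[rn, 4L] else 1
    }, 0)
  }
  inModel <- character()
  path <- character()
  repeat {
    changed <- FALSE
    out <- setdiff(screened, inModel)
    if (length(out)) {
      pv <- vapply(out, function(v) pOf(c(inModel, v))[[v]], 0)
      if (min(pv) <= entryP) {
        v <- names(which.min(pv))
        inModel <- c(inModel, v)
        path <- c(path, paste0("+", v))
        changed <- TRUE
      }
    }
    if (length(inModel) > 1L) {
      pv <- pOf(inModel)
      if (max(pv) >= removalP) {
        v <- names(which.max(pv))
        inModel <- setdiff(inModel, v)
        path <- c(path, paste0("-", v))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (!length(inModel)) {
    # regionally balanced responses cancel in the spatial mean; the
    # pixel-level forest screen is the informative stage then
    inModel <- screened
    path <- c(path, "stepwise uninformative: returning screened set")
  }
  sel <- names(imp)[names(imp) %in% inModel]
  attr(sel, "importance") <- imp
  attr(sel, "path") <- path
  sel
}

#' Fit the per-pixel climate-NDVI regression
#'
#' Ordinary least squares of each pixel's annual NDVI on the selected
#' climate series plus an intercept: the climate-predicted NDVI
#' (`a*T + b*P + c*S + d` for the canonical three-variable model).  Pixels
#' with a rank-deficient design or insufficient years are nodata (counted
#' in a warning).
#'
#' @param ndvi NDVI [GridStack-class].
#' @param climate named list of climate `GridStack`s.
#' @param variables which climate variables to use (default: all supplied).
#' @return List with `coefficients` (array `[n_vars+1, rows, cols]`,
#'   intercept last), `se` (matching array of coefficient standard
#'   errors), `r2` (matrix), and `predicted` (a `GridStack` of
#'   climate-predicted NDVI).
#' @export
fitPixelRegression <- function(ndvi, climate, variables = names(climate)) {
  for (v in variables)
    if (!sameGrid(ndvi, climate[[v]]))
      stop("alignment error: climate stack '", v,
           "' is not on the NDVI grid")
  ny <- nYears(ndvi)
  p <- length(variables)
  if (ny < p + 2L) stop("need at least ", p + 2L, " years for ", p,
                        " predictors")
  d <- gridDim(ndvi)
  yFlat <- matrix(ndvi@values, nrow = ny)
  xFlat <- lapply(climate[variables], function(s) matrix(s@values, nrow = ny))
  npix <- ncol(yFlat)
  coefs <- ses <- matrix(NA_real_, p + 1L, npix)
  r2 <- rep(NA_real_, npix)
  pred <- matrix(NA_real_, ny, npix)
  nBad <- 0L
  X <- matrix(1, ny, p + 1L)
  for (k in seq_len(npix)) {
    y <- yFlat[, k]
    for (j in seq_len(p)) X[, j] <- xFlat[[j]][, k]
    good <- !is.na(y) & rowSums(is.na(X)) == 0L
    ng <- sum(good)
    if (ng < p + 2L) { nBad <- nBad + 1L; next }
    Xg <- X[good, , drop = FALSE]
    fit <- .lm.fit(Xg, y[good])
    if (fit$rank < p + 1L) { nBad <- nBad + 1L; next }
    cf <- fit$coefficients
    coefs[, k] <- cf
    yhat <- X %*% cf
    pred[, k] <- yhat
    ssTot <- sum((y[good] - mean(y[good]))^2)
    ssRes <- sum(fit$residuals^2)
    sigma2 <- ssRes / (ng - p - 1L)
    xtxi <- tryCatch(solve(crossprod(Xg)), error = function(e) NULL)
    if (!is.null(xtxi)) ses[, k] <- sqrt(pmax(sigma2 * diag(xtxi), 0))
    r2[k] <- if (ssTot < 1e-300) (if (ssRes < 1e-300) 1 else 0)
             else max(0, min(1, 1 - ssRes / ssTot))
  }
  if (nBad > 0L)
    warning(nBad, " pixel(s) with rank-deficient or too-short design ",
            "set to nodata")
  coefArr <- array(coefs, c(p + 1L, d))
  seArr <- array(ses, c(p + 1L, d))
  dimnames(coefArr) <- dimnames(seArr) <-
    list(c(variables, "intercept"), NULL, NULL)
  list(coefficients = coefArr, se = seArr, r2 = matrix(r2, d[1L], d[2L]),
       predicted = gridStack(array(t(t(pred)), c(ny, d)), ndvi@years,
                             "ndvi_c", "1", ndvi@origin, ndvi@pixelSize,
                             ndvi@crs))
}

#' Decompose observed dynamics into climate and human components
#'
#' Residual-trend decomposition: `NDVI_H = NDVI_obs - NDVI_C` per
#' pixel-year, and the same subtraction for the 3x3-window CV stacks, with
#' `CV_NDVI(C)` computed by running the window CV on the climate-predicted
#' stack.  The subtractions are exact, so adding a component back
#' reconstructs its minuend bit for bit.
#'
#' @param ndvi observed NDVI [GridStack-class].
#' @param predicted climate-predicted NDVI stack (from
#'   [fitPixelRegression()]).
#' @return List of stacks: `ndviH`, `cvObs`, `cvC`, `cvH`.
#' @export
restrendDecompose <- function(ndvi, predicted) {
  if (!sameGrid(ndvi, predicted) ||
      !identical(ndvi@years, predicted@years))
    stop("alignment error: observed and predicted stacks differ")
  ndviH <- gridStack(ndvi@values - predicted@values, ndvi@years, "ndvi_h",
                     "1", ndvi@origin, ndvi@pixelSize, ndvi@crs)
  cvObs <- windowStack(ndvi, "cv")
  cvC <- windowStack(predicted, "cv")
  cvH <- gridStack(cvObs@values - cvC@values, ndvi@years, "cv_ndvi_h",
                   "1", ndvi@origin, ndvi@pixelSize, ndvi@crs)
  list(ndviH = ndviH, cvObs = cvObs, cvC = cvC, cvH = cvH)
}

#' Classify the driver of an observed trend and its contribution rates
#'
#' The six-row driver truth table on the signs of the observed, climate and
#' human trend components.  When climate and human components reinforce the
#' observed sign, the contributions are `100 * slope_C / slope_obs` and
#' `100 * slope_H / slope_obs`; when they oppose, the component matching
#' the observed sign gets 100%.  An exactly zero component assigns the
#' other component the full 100% (the pure-driver rows).  Inputs that are
#' not additively consistent (a sign pattern outside the table) raise an
#' error.  Works elementwise on vectors or matrices; the class code is the
#' driver letter (C/H/B) plus the direction suffix (NI/ND for NDVI,
#' CI/CD for CV).
#'
#' @param slopeObs,slopeC,slopeH observed, climate and human trend
#'   components (NA and exact-zero observed slopes give NA).
#' @param dynamic `"ndvi"` or `"cv"`: chooses the suffix convention.
#' @return List with `class` (character codes), `climatePct`, `humanPct`.
#' @examples
#' classifyDriver(0.004, 0.003, 0.001)  # BDNI, 75% / 25%
#' @export
classifyDriver <- function(slopeObs, slopeC, slopeH,
                           dynamic = c("ndvi", "cv")) {
  dynamic <- match.arg(dynamic)
  so <- as.vector(slopeObs); sc <- as.vector(slopeC); sh <- as.vector(slopeH)
  n <- length(so)
  cls <- rep(NA_character_, n)
  cp <- hp <- rep(NA_real_, n)
  ok <- !is.na(so) & !is.na(sc) & !is.na(sh) & so != 0

  pure_c <- ok & ((sh == 0 & sc != 0) | (so > 0 & sc > 0 & sh < 0) |
                    (so < 0 & sc < 0 & sh > 0))
  pure_h <- ok & ((sc == 0 & sh != 0) | (so > 0 & sc < 0 & sh > 0) |
                    (so < 0 & sc > 0 & sh < 0))
  both <- ok & ((so > 0 & sc > 0 & sh > 0) | (so < 0 & sc < 0 & sh < 0))
  bad <- ok & !(pure_c | pure_h | both)
  if (any(bad))
    stop(sum(bad), " pixel(s) with a sign pattern outside the driver ",
         "table; components are not additively consistent with the ",
         "observed slope")
  letter <- rep(NA_character_, n)
  letter[pure_c] <- "C"; letter[pure_h] <- "H"; letter[both] <- "B"
  cp[pure_c] <- 100; hp[pure_c] <- 0
  cp[pure_h] <- 0; hp[pure_h] <- 100
  cp[both] <- 100 * sc[both] / so[both]
  hp[both] <- 100 * sh[both] / so[both]

  suf <- if (dynamic == "ndvi") c("NI", "ND") else c("CI", "CD")
  sfx <- ifelse(so > 0, suf[1L], suf[2L])
  cls[!is.na(letter)] <- paste0(letter[!is.na(letter)], "D",
                                sfx[!is.na(letter)])
  shape <- function(v) if (is.matrix(slopeObs))
    matrix(v, nrow(slopeObs), ncol(slopeObs)) else v
  list(class = shape(cls), climatePct = shape(cp), humanPct = shape(hp))
}

#' The twelve-scenario lookup table
#'
#' All 36 valid (NDVI driver, CV driver) pairs and the scenario each maps
#' to.  The scenario group is fixed by the direction suffixes (NI+CD:
#' restoration, scenarios 1-3; NI+CI: slight degradation or re-growing,
#' 4-6; ND+CI: moderate degradation, 7-9; ND+CD: severe degradation or
#' desertification, 10-12) and the scenario within the group by the
#' combined driver letter: C for pairs \{C,C\}, \{C,B\}, \{B,C\}; H for
#' \{H,H\}, \{H,B\}, \{B,H\}; B for \{C,H\}, \{H,C\}, \{B,B\}.
#'
#' @return data.frame with `scenario`, `label`, `ndviDriver`, `cvDriver`.
#' @export
scenarioTable <- function() {
  groups <- list(c("NI", "CD"), c("NI", "CI"), c("ND", "CI"), c("ND", "CD"))
  labels <- c("CDI", "HDI", "BDI", "CDSR", "HDSR", "BDSR",
              "CDMD", "HDMD", "BDMD", "CDSD", "HDSD", "BDSD")
  rows <- list()
  for (g in seq_along(groups)) {
    nsuf <- groups[[g]][1L]; csuf <- groups[[g]][2L]
    for (l1 in c("C", "H", "B")) for (l2 in c("C", "H", "B")) {
      comb <- combinedDriverLetter(l1, l2)
      scn <- (g - 1L) * 3L + match(comb, c("C", "H", "B"))
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = scn, label = labels[scn],
        ndviDriver = paste0(l1, "D", nsuf),
        cvDriver = paste0(l2, "D", csuf), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$scenario), ]
}

# zero an insignificant human slope (t test, n-2 df); kept nonzero where
# the climate component is zero so the driver pattern stays classifiable
gateHumanSlope <- function(slopeH, se, slopeC, n, alpha) {
  crit <- stats::qt(1 - alpha / 2, df = n - 2L)
  t <- abs(slopeH) / se
  gate <- !is.na(slopeH) & !is.na(se) &
    ((se > 0 & (!is.finite(t) | t < crit))) &
    !is.na(slopeC) & slopeC != 0
  slopeH[gate] <- 0
  slopeH
}

combinedDriverLetter <- function(l1, l2) {
  ifelse((l1 == "C" & l2 != "H") | (l1 == "B" & l2 == "C"), "C",
    ifelse((l1 == "H" & l2 != "C") | (l1 == "B" & l2 == "H"), "H", "B"))
}

#' Classify the twelve-scenario typology from the driver pair
#'
#' Elementwise lookup of [scenarioTable()]: the NDVI-driver and CV-driver
#' codes determine the scenario id 1-12 and its label.  NA inputs give NA.
#'
#' @param ndviDriver,cvDriver character codes as returned by
#'   [classifyDriver()] (e.g. `"CDNI"`, `"BDCD"`).
#' @return List with `scenario` (integer) and `label` (character), same
#'   shape as the inputs.
#' @examples
#' classifyScenario("CDNI", "CDCD")  # scenario 1, CDI
#' @export
classifyScenario <- function(ndviDriver, cvDriver) {
  nd <- as.vector(ndviDriver); cd <- as.vector(cvDriver)
  ok <- !is.na(nd) & !is.na(cd)
  bad <- ok & !(substr(nd, 3L, 4L) %in% c("NI", "ND") &
                  substr(cd, 3L, 4L) %in% c("CI", "CD") &
                  substr(nd, 1L, 1L) %in% c("C", "H", "B") &
                  substr(cd, 1L, 1L) %in% c("C", "H", "B"))
  if (any(bad))
    stop(sum(bad), " driver pair(s) absent from the scenario table: ",
         paste(unique(paste(nd[bad], cd[bad])), collapse = ", "))
  scn <- rep(NA_integer_, length(nd))
  grp <- rep(NA_integer_, length(nd))
  grp[ok & substr(nd, 3L, 4L) == "NI" & substr(cd, 3L, 4L) == "CD"] <- 0L
  grp[ok & substr(nd, 3L, 4L) == "NI" & substr(cd, 3L, 4L) == "CI"] <- 3L
  grp[ok & substr(nd, 3L, 4L) == "ND" & substr(cd, 3L, 4L) == "CI"] <- 6L
  grp[ok & substr(nd, 3L, 4L) == "ND" & substr(cd, 3L, 4L) == "CD"] <- 9L
  comb <- combinedDriverLetter(substr(nd, 1L, 1L), substr(cd, 1L, 1L))
  scn[ok] <- grp[ok] + match(comb[ok], c("C", "H", "B"))
  labels <- c("CDI", "HDI", "BDI", "CDSR", "HDSR", "BDSR",
              "CDMD", "HDMD", "BDMD", "CDSD", "HDSD", "BDSD")
  lab <- labels[scn]
  shape <- function(v) if (is.matrix(ndviDriver))
    matrix(v, nrow(ndviDriver), ncol(ndviDriver)) else v
  list(scenario = shape(scn), label = shape(lab))
}

#' Improved residual-trend attribution of NDVI and CV dynamics
#'
#' The full attribution chain: (optional) variable selection, per-pixel
#' climate regression, residual decomposition, least-squares trends of each
#' component (least squares rather than the Sen median because the
#' decomposition is additive and the contribution rates must sum to 100%),
#' and the driver/scenario classification.
#'
#' A human influence is attributed only where the residual (human) trend is
#' statistically distinguishable from zero: the NDVI and CV residual slopes
#' are t-tested per pixel and slopes with p >= `humanSignificance` are
#' treated as zero, falling back to the pure-climate row.  Without this
#' gate every pixel of a purely climate-driven landscape would receive a
#' spurious same-signed human co-driver about half the time, since a
#' least-squares residual slope is never exactly zero under noise.
#'
#' @param ndvi observed NDVI [GridStack-class].
#' @param climate named list of climate stacks.
#' @param variables climate variables to use; `NULL` runs
#'   [selectClimateVariables()].
#' @param selectionSeed seed for the selection stage.
#' @param zeroTol slopes with magnitude below this are treated as exact
#'   zeros before classification.  The default (1e-10, several orders of
#'   magnitude below any resolvable NDVI trend) only absorbs floating-point
#'   residue of the regression/decomposition round trip, so a component
#'   that is structurally absent classifies as absent.
#' @param humanSignificance two-sided p-value threshold for the residual
#'   (human) trend gate; `NULL` disables gating.
#' @return List with `variables`, `fit` (regression output), `residuals`
#'   (decomposition stacks), `slopes` (all six component slope matrices),
#'   `drivers` (a [DriverMap-class]) and `scenarios` (a
#'   [ScenarioMap-class]).
#' @export
restrendAttribution <- function(ndvi, climate, variables = NULL,
                                selectionSeed = 1L, zeroTol = 1e-10,
                                humanSignificance = 0.05) {
  if (is.null(variables)) {
    variables <- selectClimateVariables(ndvi, climate, seed = selectionSeed)
    if (!length(variables))
      stop("variable selection returned an empty set; supply `variables`")
  }
  fit <- fitPixelRegression(ndvi, climate, variables)
  res <- restrendDecompose(ndvi, fit$predicted)
  snap <- function(m) { m[!is.na(m) & abs(m) < zeroTol] <- 0; m }
  slopeObs <- snap(olsSlopeMap(ndvi))
  slopeC <- snap(olsSlopeMap(fit$predicted))
  slopeH <- snap(slopeObs - slopeC)
  cvSlopeObs <- snap(olsSlopeMap(res$cvObs))
  cvSlopeC <- snap(olsSlopeMap(res$cvC))
  cvSlopeH <- snap(cvSlopeObs - cvSlopeC)
  if (!is.null(humanSignificance)) {
    slopeH <- gateHumanSlope(slopeH, olsSlopeSeMap(res$ndviH)$se,
                             slopeC, nYears(ndvi), humanSignificance)
    cvSlopeH <- gateHumanSlope(cvSlopeH, olsSlopeSeMap(res$cvH)$se,
                               cvSlopeC, nYears(ndvi), humanSignificance)
  }
  drv <- classifyDriver(slopeObs, slopeC, slopeH, dynamic = "ndvi")
  cvDrv <- classifyDriver(cvSlopeObs, cvSlopeC, cvSlopeH, dynamic = "cv")
  scn <- classifyScenario(drv$class, cvDrv$class)
  drivers <- new("DriverMap", ndviDriver = drv$class, cvDriver = cvDrv$class,
                 climatePct = drv$climatePct, humanPct = drv$humanPct,
                 cvClimatePct = cvDrv$climatePct,
                 cvHumanPct = cvDrv$humanPct)
  scenarios <- new("ScenarioMap", scenario = scn$scenario, label = scn$label)
  list(variables = variables, fit = fit, residuals = res,
       slopes = list(ndviObs = slopeObs, ndviC = slopeC, ndviH = slopeH,
                     cvObs = cvSlopeObs, cvC = cvSlopeC, cvH = cvSlopeH),
       drivers = drivers, scenarios = scenarios)
}

setMethod("show", "DriverMap", function(object) {
  cat("DriverMap:", nrow(object@ndviDriver), "x", ncol(object@ndviDriver),
      "cells\n  NDVI drivers:\n")
  print(table(object@ndviDriver, useNA = "no"))
  cat("  CV drivers:\n")
  print(table(object@cvDriver, useNA = "no"))
})

setMethod("show", "ScenarioMap", function(object) {
  cat("ScenarioMap:", nrow(object@scenario), "x", ncol(object@scenario),
      "cells\n")
  print(table(object@label, useNA = "no"))
})
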