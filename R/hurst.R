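#' Rescaled-range (R/S) Hurst exponent of a series
#'
#' Classical R/S analysis: for each window length `m` the series is cut
#' into `floor(n/m)` non-overlapping blocks; each block contributes the
#' range of its cumulative deviations from the block mean divided by the
#' block's (population) standard deviation; block values are averaged into
#' `(R/S)_m`, and the Hurst exponent is the slope of the least-squares fit
#' of `log(R/S)` on `log(m)`, clipped to (0, 1).  The fit R-squared is
#' returned as a quality flag: with short annual series (n = 20 gives only
#' window lengths 8-10) the estimate is noisy and the flag matters.
#'
#' The plain (uncorrected) statistic is the default; `correction =
#' "anis-lloyd"` divides each `(R/S)_m` by its expected value under
#' independence and fits `0.5 + slope` instead, trading faithfulness to
#' the classical estimator for less small-sample bias.
#'
#' @param series numeric vector, length >= 16, not constant (NAs rejected:
#'   R/S needs contiguous blocks).
#' @param minWindow smallest window length (default 8).
#' @param windowSet integer window lengths; default all of
#'   `minWindow:(n/2)`, thinned to ~20 log-spaced values for long series.
#' @param correction `"none"` (default) or `"anis-lloyd"`.
#' @return List with `h` and `r2`, both `NA` (with a warning) for
#'   constant or too-short series.
#' @examples
#' rsHurst(generateFgn(0.8, 512, seed = 1))$h
#' @export
rsHurst <- function(series, minWindow = 8L, windowSet = NULL,
                    correction = c("none", "anis-lloyd")) {
  correction <- match.arg(correction)
  x <- series
  if (anyNA(x)) x <- x[!is.na(x)]
  n <- length(x)
  if (n < 16L) return(list(h = NA_real_, r2 = NA_real_))
  if (sd(x) == 0) {
    warning("constant series: R/S undefined")
    return(list(h = NA_real_, r2 = NA_real_))
  }
  if (is.null(windowSet)) {
    windowSet <- minWindow:(n %/% 2L)
    if (length(windowSet) > 20L) {
      lg <- exp(seq(log(minWindow), log(n %/% 2L), length.out = 20L))
      windowSet <- unique(round(lg))
    }
  }
  windowSet <- windowSet[windowSet >= 2L & windowSet <= n]
  rs <- rep(NA_real_, length(windowSet))
  for (w in seq_along(windowSet)) {
    m <- windowSet[w]
    nb <- n %/% m
    vals <- numeric(0)
    for (b in seq_len(nb)) {
      seg <- x[((b - 1L) * m + 1L):(b * m)]
      mu <- mean(seg)
      X <- cumsum(seg - mu)
      R <- max(X) - min(X)
      S <- sqrt(mean((seg - mu)^2))
      if (S > 0) vals <- c(vals, R / S)
    }
    if (length(vals)) rs[w] <- mean(vals)
  }
  ok <- !is.na(rs) & rs > 0
  if (sum(ok) < 2L) {
    warning("too few valid window lengths for the R/S fit")
    return(list(h = NA_real_, r2 = NA_real_))
  }
  lx <- log(windowSet[ok]); ly <- log(rs[ok])
  if (correction == "anis-lloyd") {
    ely <- log(vapply(windowSet[ok], expectedRsIndependent, 0))
    ly <- ly - ely
  }
  fit <- lm(ly ~ lx)
  h <- unname(coef(fit)[2L])
  if (correction == "anis-lloyd") h <- 0.5 + h
  r2 <- if (var(ly) == 0) 1 else summary(fit)$r.squared
  list(h = min(max(h, 0.001), 0.999), r2 = r2)
}

# Anis-Lloyd expected R/S of an iid series at window length m
expectedRsIndependent <- function(m) {
  i <- seq_len(m - 1L)
  pre <- if (m <= 340) gamma((m - 1) / 2) / (sqrt(pi) * gamma(m / 2))
         else 1 / sqrt(m * pi / 2)
  pre * sum(sqrt((m - i) / i))
}

#' Persistence class from a Hurst exponent
#'
#' `H > 0.5`: the future trend is expected to continue the past one
#' (persistent); `H < 0.5`: it is expected to reverse (anti-persistent);
#' `H = 0.5`: the future trend cannot be forecast.
#'
#' @param h numeric Hurst exponent(s).
#' @return Character vector/matrix: `"persistent"`, `"anti-persistent"`,
#'   `"unpredictable"` or NA.
#' @export
persistenceClass <- function(h) {
  out <- rep(NA_character_, length(h))
  v <- as.vector(h)
  out[!is.na(v) & v > 0.5] <- "persistent"
  out[!is.na(v) & v < 0.5] <- "anti-persistent"
  out[!is.na(v) & v == 0.5] <- "unpredictable"
  if (is.matrix(h)) out <- matrix(out, nrow(h), ncol(h)) else out
}

#' Per-pixel Hurst exponent map of a stack
#'
#' Runs [rsHurst()] on every pixel's annual series.  With `nYears = 20`
#' the default window set is 8:10; the per-pixel fit R-squared is carried
#' as a quality layer.
#'
#' @param stack a [GridStack-class] with >= 16 years.
#' @param ... passed to [rsHurst()].
#' @return A [HurstMap-class].
#' @export
hurstMap <- function(stack, ...) {
  d <- gridDim(stack)
  h <- r2 <- matrix(NA_real_, d[1L], d[2L])
  vals <- matrix(stack@values, nrow = nYears(stack))
  for (k in seq_len(ncol(vals))) {
    x <- vals[, k]
    if (anyNA(x) || sd(x) == 0) next
    fit <- suppressWarnings(rsHurst(x, ...))
    h[k] <- fit$h; r2[k] <- fit$r2
  }
  new("HurstMap", h = h, r2 = r2, variable = stack@variable)
}

#' Forecast transition classes
#' @return data.frame of transition codes and names.
#' @export
forecastClasses <- function() {
  data.frame(
    code = c(1L, 2L, 3L, 4L, 0L),
    name = c("continuous improvement", "degradation to improvement",
             "improvement to degradation", "continuous degradation",
             "indeterminate"),
    stringsAsFactors = FALSE)
}

#' Forecast future grassland dynamics by trend/Hurst superposition
#'
#' Each pixel's forecast NDVI and CV trend signs are the observed signs
#' where the corresponding Hurst exponent exceeds 0.5 (persistent),
#' negated where it is below 0.5 (anti-persistent), and indeterminate at
#' exactly 0.5 or missing.  The forecast signs are re-classified into a
#' degradation level with the same table as the current map, and the
#' transition class compares membership of the degraded set
#' (Slight/Moderate/Severe/Desertification) now versus in the forecast;
#' Improving, Regrowing and Stable count as the improved side.
#'
#' @param hurstNdvi,hurstCv [HurstMap-class] objects for NDVI and CV.
#' @param ndviSlope,cvSlope observed trend matrices (Sen slopes).
#' @param ndviValue period-mean window-median NDVI matrix.
#' @param currentLevel integer matrix of current degradation codes.
#' @return A [ForecastMap-class].
#' @export
forecastDynamics <- function(hurstNdvi, hurstCv, ndviSlope, cvSlope,
                             ndviValue, currentLevel) {
  dm <- dim(ndviSlope)
  if (!identical(dim(hurstNdvi@h), dm) || !identical(dim(hurstCv@h), dm) ||
      !identical(dim(cvSlope), dm) || !identical(dim(currentLevel), dm))
    stop("alignment error: forecast inputs are not on the same grid")
  dirN <- hurstDirection(hurstNdvi@h)
  dirC <- hurstDirection(hurstCv@h)
  fN <- ndviSlope * dirN
  fC <- cvSlope * dirC
  fLevel <- classifyDegradation(fN, fC, ndviValue)
  indet <- is.na(dirN) | is.na(dirC)

  curDeg <- !is.na(currentLevel) & currentLevel %in% degradedCodes()
  fcDeg <- !is.na(fLevel) & fLevel %in% degradedCodes()
  tr <- matrix(NA_integer_, dm[1L], dm[2L])
  ok <- !is.na(currentLevel) & !is.na(fLevel)
  tr[ok & !curDeg & !fcDeg] <- 1L
  tr[ok & curDeg & !fcDeg] <- 2L
  tr[ok & !curDeg & fcDeg] <- 3L
  tr[ok & curDeg & fcDeg] <- 4L
  tr[indet & !is.na(currentLevel)] <- 0L
  fLevel[indet] <- NA_integer_
  new("ForecastMap", transition = tr, forecastLevel = fLevel,
      currentLevel = currentLevel)
}

hurstDirection <- function(h) {
  d <- matrix(NA_real_, nrow(h), ncol(h))
  d[!is.na(h) & h > 0.5] <- 1
  d[!is.na(h) & h < 0.5] <- -1
  d
}

setMethod("show", "HurstMap", function(object) {
  ok <- !is.na(object@h)
  cat(sprintf("HurstMap '%s': %d x %d cells (%d valid)\n", object@variable,
              nrow(object@h), ncol(object@h), sum(ok)))
  if (any(ok))
    cat(sprintf("  mean H = %.3f, %.1f%% persistent (H > 0.5)\n",
                mean(object@h[ok]), 100 * mean(object@h[ok] > 0.5)))
})

setMethod("show", "ForecastMap", function(object) {
  tab <- forecastClasses()
  cnt <- table(factor(object@transition, levels = tab$code,
                      labels = tab$name))
  cat("ForecastMap:", nrow(object@transition), "x",
      ncol(object@transition), "cells\n")
  for (nm in names(cnt)) if (cnt[[nm]] > 0)
    cat(sprintf("  %-28s %d\n", nm, cnt[[nm]]))
})
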