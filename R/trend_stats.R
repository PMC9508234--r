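#' Theil-Sen slope of a time series
#'
#' Median of all pairwise slopes `(a_j - a_i) / (t_j - t_i)` over `j > i`,
#' the robust trend estimator used for every NDVI and CV_NDVI trend map in
#' the package.  With an even number of pairs the median is the mean of the
#' two central values.
#'
#' @param series numeric vector (NA allowed; pairs with NA are dropped).
#' @param years numeric vector of observation times (defaults to
#'   `seq_along(series)`).
#' @return The Sen slope, or `NA` with fewer than two valid points.
#' @examples
#' senSlope(c(1, 3, 2, 5), 1:4)  # 7/6
#' @export
senSlope <- function(series, years = seq_along(series)) {
  ok <- !is.na(series) & !is.na(years)
  x <- series[ok]; t <- years[ok]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  dt <- outer(t, t, "-")
  dx <- outer(x, x, "-")
  idx <- lower.tri(dt)  # [i, j] with i > j  <=>  later minus earlier
  median(dx[idx] / dt[idx])
}

#' Mann-Kendall trend test
#'
#' Computes the S statistic (sum of pairwise signs), the normal-approximation
#' Z with the continuity correction and tie-corrected variance
#' `Var(S) = [n(n-1)(2n+5) - sum t(t-1)(2t+5)] / 18`, and the two-sided
#' p-value.  `Z = 0` when `S = 0`.
#'
#' @param series numeric vector (NAs dropped).
#' @return A list with `s`, `z`, `p` and `n` (valid length); all `NA` when
#'   fewer than 4 valid points.
#' @examples
#' mannKendall(c(1, 3, 2, 5))$s  # 4
#' @export
mannKendall <- function(series) {
  x <- series[!is.na(series)]
  n <- length(x)
  if (n < 4L) return(list(s = NA_real_, z = NA_real_, p = NA_real_, n = n))
  sgn <- sign(outer(x, x, "-"))   # [j, i] = sign(x_j - x_i)
  s <- sum(sgn[lower.tri(sgn)])
  ties <- table(x)
  ties <- ties[ties > 1L]
  varS <- (n * (n - 1) * (2 * n + 5) -
             sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (s > 0) (s - 1) / sqrt(varS)
       else if (s < 0) (s + 1) / sqrt(varS)
       else 0
  p <- 2 * pnorm(-abs(z))
  list(s = s, z = z, p = p, n = n)
}

# 3x3 neighbourhood stack: returns [9, nr, nc] with NA frame at edges
windowNeighborhood <- function(band) {
  nr <- nrow(band); nc <- ncol(band)
  out <- array(NA_real_, c(9L, nr, nc))
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1L
    m <- matrix(NA_real_, nr, nc)
    rs <- seq_len(nr); cs <- seq_len(nc)
    rs <- rs[rs + dr >= 1L & rs + dr <= nr]
    cs <- cs[cs + dc >= 1L & cs + dc <= nc]
    m[rs, cs] <- band[rs + dr, cs + dc]
    out[k, , ] <- m
  }
  out
}

#' Windowed spatial statistics of one annual band
#'
#' `windowCv` computes, per centre pixel, the spatial coefficient of
#' variation over the 3x3 neighbourhood for that year: the sample (n-1)
#' standard deviation of the nine values divided by their mean.  This is the
#' per-year spatial-heterogeneity measure whose temporal trend feeds the
#' degradation classification.  `windowMedian` computes the 3x3 median NDVI
#' the same way.  Both return nodata where any of the nine cells is nodata
#' (so the one-pixel image boundary is always nodata), and `windowCv`
#' additionally where the window mean is <= 0.
#'
#' @param band numeric matrix, one year's raster band.
#' @return A matrix of the same shape.
#' @examples
#' windowCv(matrix(1:9, 3, 3))[2, 2]  # sqrt(7.5)/5
#' @export
windowCv <- function(band) {
  nb <- windowNeighborhood(band)
  n_ok <- colSums(!is.na(nb), dims = 1)
  mu <- colMeans(nb, dims = 1)            # NA wherever any cell NA
  sumsq <- colSums(nb^2, dims = 1)
  v <- (sumsq - 9 * mu^2) / 8
  v[v < 0] <- 0                           # guard tiny negative rounding
  out <- sqrt(v) / mu
  out[n_ok < 9L | is.na(mu) | mu <= 0] <- NA_real_
  out
}

#' @rdname windowCv
#' @export
windowMedian <- function(band) {
  nb <- windowNeighborhood(band)
  out <- apply(nb, c(2L, 3L), function(w) {
    if (anyNA(w)) NA_real_ else median(w)
  })
  out
}

#' Per-year windowed stacks of a GridStack
#'
#' Applies [windowCv()] or [windowMedian()] band by band, returning a new
#' stack on the same grid ("cv_" / "med_" prefixed variable name).
#'
#' @param stack a [GridStack-class].
#' @param stat `"cv"` or `"median"`.
#' @return A `GridStack` of the per-year windowed statistic.
#' @export
windowStack <- function(stack, stat = c("cv", "median")) {
  stat <- match.arg(stat)
  f <- if (stat == "cv") windowCv else windowMedian
  vals <- stack@values
  out <- array(NA_real_, dim(vals))
  for (y in seq_len(nYears(stack)))
    out[y, , ] <- f(vals[y, , , drop = TRUE])
  gridStack(out, stack@years,
            paste0(if (stat == "cv") "cv_" else "med_", stack@variable),
            if (stat == "cv") "1" else stack@units,
            stack@origin, stack@pixelSize, stack@crs)
}

#' Per-pixel Sen slope and Mann-Kendall significance map
#'
#' Runs [senSlope()] and [mannKendall()] on every pixel's annual series.
#' Pixels with fewer than 4 valid years are nodata.
#'
#' @param stack a [GridStack-class] with at least 4 years.
#' @param alpha significance level recorded in the map (default 0.05).
#' @return A [TrendMap-class].
#' @export
trendMap <- function(stack, alpha = 0.05) {
  d <- gridDim(stack)
  yrs <- stack@years
  vals <- stack@values
  slope <- s <- z <- p <- matrix(NA_real_, d[1L], d[2L])
  for (j in seq_len(d[2L])) {
    block <- vals[, , j, drop = TRUE]      # [years, rows]
    if (is.null(dim(block))) block <- matrix(block, ncol = 1L)
    for (i in seq_len(d[1L])) {
      x <- block[, i]
      if (sum(!is.na(x)) < 4L) next
      slope[i, j] <- senSlope(x, yrs)
      mk <- mannKendall(x)
      s[i, j] <- mk$s; z[i, j] <- mk$z; p[i, j] <- mk$p
    }
  }
  new("TrendMap", slope = slope, sStat = s, z = z, p = p,
      alpha = alpha, variable = stack@variable)
}

#' Per-pixel least-squares slope map
#'
#' OLS slope of each pixel's series against the years.  Used inside the
#' attribution stage, where slope additivity across decomposed components is
#' required (the Sen median slope is not additive).
#'
#' @param stack a [GridStack-class].
#' @return A numeric matrix of slopes.
#' @export
olsSlopeMap <- function(stack) {
  yrs <- stack@years
  vals <- stack@values
  d <- gridDim(stack)
  flat <- matrix(vals, nrow = nYears(stack))   # [years, pixels]
  tc <- yrs - mean(yrs)
  denom <- sum(tc^2)
  ok <- colSums(is.na(flat)) == 0L
  out <- rep(NA_real_, ncol(flat))
  if (any(ok))
    out[ok] <- colSums(flat[, ok, drop = FALSE] * tc) / denom
  # pixels with some NAs: per-pixel fallback
  part <- which(!ok & colSums(!is.na(flat)) >= 2L)
  for (k in part) {
    x <- flat[, k]; good <- !is.na(x)
    tt <- yrs[good] - mean(yrs[good])
    out[k] <- sum(x[good] * tt) / sum(tt^2)
  }
  matrix(out, d[1L], d[2L])
}

#' Per-pixel least-squares slope with standard error
#'
#' Like [olsSlopeMap()] but also returns the standard error of the slope
#' (from the residuals of the per-pixel straight-line fit), used to test
#' whether a decomposed trend component is distinguishable from zero.
#'
#' @param stack a [GridStack-class].
#' @return List of matrices `slope` and `se` (`se = 0` for an exactly
#'   linear series).
#' @export
olsSlopeSeMap <- function(stack) {
  yrs <- stack@years
  ny <- nYears(stack)
  d <- gridDim(stack)
  flat <- matrix(stack@values, nrow = ny)
  slope <- se <- rep(NA_real_, ncol(flat))
  for (k in seq_len(ncol(flat))) {
    y <- flat[, k]
    good <- !is.na(y)
    ng <- sum(good)
    if (ng < 3L) next
    tt <- yrs[good] - mean(yrs[good])
    sxx <- sum(tt^2)
    b <- sum(y[good] * tt) / sxx
    resid <- y[good] - mean(y[good]) - b * tt
    s2 <- sum(resid^2) / (ng - 2L)
    slope[k] <- b
    se[k] <- sqrt(s2 / sxx)
  }
  list(slope = matrix(slope, d[1L], d[2L]), se = matrix(se, d[1L], d[2L]))
}

#' Pixel-wise Pearson correlation between two stacks
#'
#' @param a,b two [GridStack-class] objects with identical years.
#' @return A matrix of per-pixel Pearson r; `NA` where either series is
#'   constant or has fewer than 3 complete pairs.
#' @export
correlationMap <- function(a, b) {
  if (!identical(a@years, b@years))
    stop("stacks must share the same years")
  fa <- matrix(a@values, nrow = nYears(a))
  fb <- matrix(b@values, nrow = nYears(b))
  out <- rep(NA_real_, ncol(fa))
  for (k in seq_len(ncol(fa))) {
    x <- fa[, k]; y <- fb[, k]
    good <- !is.na(x) & !is.na(y)
    if (sum(good) < 3L) next
    if (sd(x[good]) == 0 || sd(y[good]) == 0) next
    out[k] <- cor(x[good], y[good])
  }
  matrix(out, gridDim(a)[1L], gridDim(a)[2L])
}
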