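#' Default climate-variable specifications for synthetic scenes
#'
#' Each variable is generated as a spatially smooth mean field plus a linear
#' secular trend plus interannual anomalies.  Levels and variabilities are
#' chosen to be realistic for a high-altitude semi-arid grassland (annual
#' mean temperature around -1 degC, ~400 mm annual precipitation, ~2600 h
#' sunshine); wind speed and solar radiation carry no trend and act as decoy
#' predictors in variable-selection experiments.
#'
#' @return Named list of per-variable specs with fields `mean`, `spatialSd`,
#'   `smoothLength` (pixels), `trend` (units/yr), `noiseSd` (interannual),
#'   `units`.
#' @export
defaultClimateSpecs <- function() {
  list(
    temperature   = list(mean = -1,   spatialSd = 1.0, smoothLength = 6,
                         trend = 0.02, noiseSd = 0.4,  units = "degC"),
    precipitation = list(mean = 400,  spatialSd = 30,  smoothLength = 6,
                         trend = 1.5,  noiseSd = 30,   units = "mm"),
    sunshine      = list(mean = 2600, spatialSd = 50,  smoothLength = 6,
                         trend = -1.0, noiseSd = 50,   units = "h"),
    wind          = list(mean = 2.5,  spatialSd = 0.3, smoothLength = 6,
                         trend = 0,    noiseSd = 0.3,  units = "m/s"),
    radiation     = list(mean = 6000, spatialSd = 150, smoothLength = 6,
                         trend = 0,    noiseSd = 150,  units = "MJ/m2")
  )
}

# fraction of interannual climate variance that is pixel-level rather than
# regionally coherent (weather anomalies are spatially coherent)
pixelNoiseFrac <- 0.2

#' Default driver regions for synthetic scenes
#'
#' Six equal vertical strips covering the canonical driver patterns:
#' climate-/human-/jointly-driven improvement and decline.  Climate-response
#' coefficients are chosen so each region's climate-induced NDVI trend and
#' each human trend have magnitude >= 0.003 NDVI/yr, keeping driver signs
#' well away from the classification boundaries.
#'
#' @return List of region specs with fields `name`, `coef` (named:
#'   NDVI-response per climate variable), `baseNdvi`, `humanTrend` (NDVI/yr).
#' @export
defaultRegions <- function() {
  list(
    list(name = "climate_improve",
         coef = c(temperature = 0.10,  precipitation = 0.001),
         baseNdvi = 0.50, humanTrend = 0),
    list(name = "human_improve",
         coef = c(temperature = -0.10, precipitation = -0.001),
         baseNdvi = 0.50, humanTrend = 0.0070),
    list(name = "both_improve",
         coef = c(temperature = 0.10,  precipitation = 0.001),
         baseNdvi = 0.50, humanTrend = 0.0035),
    list(name = "climate_decline",
         coef = c(temperature = -0.10, precipitation = -0.001),
         baseNdvi = 0.50, humanTrend = 0),
    list(name = "human_decline",
         coef = c(temperature = 0.10,  precipitation = 0.001),
         baseNdvi = 0.50, humanTrend = -0.0070),
    list(name = "both_decline",
         coef = c(temperature = -0.10, precipitation = -0.001),
         baseNdvi = 0.50, humanTrend = -0.0035)
  )
}

#' Configure a synthetic scene
#'
#' Bundles everything the generator needs: grid and period size, per-variable
#' climate specs, per-region NDVI response coefficients and human trends,
#' the fine-scale intercept texture that gives each 3x3 window a stable
#' spatial spread (so the CV is well defined), the NDVI observation noise,
#' and the seed that fixes every random draw.
#'
#' @param nYears number of annual bands (>= 10).
#' @param nRows,nCols grid size.
#' @param startYear first year.
#' @param climate named list of climate specs, see [defaultClimateSpecs()].
#' @param regions list of region specs, see [defaultRegions()]; regions are
#'   laid out as equal vertical strips in order.
#' @param textureSd sd of the static fine-scale NDVI texture (intercept
#'   heterogeneity within windows).
#' @param ndviNoiseSd sd of the iid NDVI observation noise.
#' @param seed integer seed fixing all draws.
#' @return A validated list of class `sceneConfig`.
#' @export
sceneConfig <- function(nYears = 20L, nRows = 60L, nCols = 60L,
                        startYear = 2000L,
                        climate = defaultClimateSpecs()[1:3],
                        regions = defaultRegions(),
                        textureSd = 0.16, ndviNoiseSd = 0.02, seed = 42L) {
  cfg <- list(nYears = as.integer(nYears), nRows = as.integer(nRows),
              nCols = as.integer(nCols), startYear = as.integer(startYear),
              climate = climate, regions = regions,
              textureSd = textureSd, ndviNoiseSd = ndviNoiseSd,
              seed = as.integer(seed))
  if (cfg$nYears < 10L)
    stop("nYears must be >= 10 (trend tests and regression need length)")
  if (cfg$ndviNoiseSd < 0 || cfg$textureSd < 0)
    stop("noise sds must be >= 0")
  for (v in names(cfg$climate))
    if (cfg$climate[[v]]$noiseSd < 0) stop("climate noiseSd must be >= 0")
  if (!length(cfg$regions)) stop("at least one region is required")
  class(cfg) <- "sceneConfig"
  cfg
}

# Gaussian-smoothed random field, standardized to the requested mean/sd.
smoothField <- function(nr, nc, mean, sd, smoothLength) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  if (sd == 0) return(matrix(mean, nr, nc))
  if (smoothLength > 0) {
    r <- max(1L, ceiling(2 * smoothLength))
    k <- exp(-((-r:r)^2) / (2 * smoothLength^2))
    k <- k / sum(k)
    conv1 <- function(m) {    # smooth down columns with clamped padding
      idx <- pmin(pmax(seq(1 - r, nrow(m) + r), 1), nrow(m))
      mp <- m[idx, , drop = FALSE]
      out <- matrix(0, nrow(m), ncol(m))
      for (i in seq_along(k))
        out <- out + k[i] * mp[i:(i + nrow(m) - 1L), , drop = FALSE]
      out
    }
    z <- conv1(z)
    z <- t(conv1(t(z)))
  }
  s <- stats::sd(z)
  if (s == 0) return(matrix(mean, nr, nc))
  mean + sd * (z - base::mean(z)) / s
}

# Remove each pixel's sample mean and sample linear time trend from a noise
# array [years, rows, cols], so anomalies are exactly trend-free: the scene's
# secular climate signal then equals its configured trend at every pixel.
detrendNoise <- function(noise, tau) {
  d <- dim(noise)
  flat <- matrix(noise, nrow = d[1L])
  tc <- tau - mean(tau)
  flat <- sweep(flat, 2L, colMeans(flat))
  flat <- flat - outer(tc, colSums(flat * tc) / sum(tc^2))
  array(flat, d)
}

# the smooth spatial mean field of one climate variable (first draw under
# the variable's seed, so it matches the field inside generateClimate)
climateMeanField <- function(config, variable) {
  spec <- config$climate[[variable]]
  set.seed(config$seed + 1000L * climateSeedOffset(config, variable))
  smoothField(config$nRows, config$nCols, spec$mean, spec$spatialSd,
              spec$smoothLength)
}

climateSeedOffset <- function(cfg, variable) {
  k <- match(variable, names(cfg$climate))
  if (is.na(k)) stop("unknown climate variable '", variable, "'")
  k
}

#' Generate one synthetic climate stack
#'
#' Field = smooth spatial mean + trend x (year - startYear) + interannual
#' anomalies.  The anomalies are Gaussian with a regionally coherent yearly
#' component (weather anomalies are spatially coherent) plus a smaller
#' pixel-level component, and are detrended per pixel so the realized
#' secular trend equals the configured trend exactly -- the scene is a
#' designed experiment whose climate signal is the configured one.
#' Deterministic given the config seed (each variable uses a fixed seed
#' offset, so a stack generated alone is identical to the one generated
#' inside [generateScene()]).
#'
#' @param config a [sceneConfig()].
#' @param variable climate variable name present in `config$climate`.
#' @return A [GridStack-class].
#' @export
generateClimate <- function(config, variable) {
  spec <- config$climate[[variable]]
  if (is.null(spec)) stop("unknown climate variable '", variable, "'")
  k <- climateSeedOffset(config, variable)
  nr <- config$nRows; nc <- config$nCols; ny <- config$nYears
  years <- config$startYear + seq_len(ny) - 1L
  tau <- years - config$startYear
  set.seed(config$seed + 1000L * k)
  meanField <- smoothField(nr, nc, spec$mean, spec$spatialSd, spec$smoothLength)
  coh <- rnorm(ny, sd = spec$noiseSd * sqrt(1 - pixelNoiseFrac^2))
  noise <- array(rnorm(ny * nr * nc, sd = spec$noiseSd * pixelNoiseFrac),
                 c(ny, nr, nc))
  if (spec$noiseSd > 0) {
    tc <- tau - mean(tau)
    coh <- coh - mean(coh) - tc * sum(coh * tc) / sum(tc^2)
    noise <- detrendNoise(noise, tau)
  }
  vals <- array(0, c(ny, nr, nc))
  for (y in seq_len(ny))
    vals[y, , ] <- meanField + spec$trend * tau[y] + coh[y] +
      noise[y, , , drop = TRUE]
  gridStack(vals, years, variable, spec$units)
}

#' Region index map of a scene (equal vertical strips)
#' @param config a [sceneConfig()].
#' @return Integer matrix of region indices.
#' @export
regionIndexMap <- function(config) {
  nreg <- length(config$regions)
  idx <- ceiling(seq_len(config$nCols) / (config$nCols / nreg))
  idx <- pmin(pmax(idx, 1L), nreg)
  matrix(rep(idx, each = config$nRows), config$nRows, config$nCols)
}

#' Generate a complete synthetic scene with ground truth
#'
#' Builds the climate stacks, composes NDVI per pixel as
#' `sum(coef_v * climate_v) + d + texture + humanTrend * (year - startYear)
#' + noise` (clipped to the physically plausible range `[-0.2, 1]`; clipping
#' events are reported because they break exact additivity), and derives the
#' per-pixel ground truth: the generating coefficients, the climate-only and
#' human NDVI components and their least-squares trends, the corresponding
#' 3x3-window CV trends, the config-rule driver label, and the true
#' degradation level and scenario id obtained by applying the package's own
#' classification tables to the noise-free components.
#'
#' The per-region intercept is `baseNdvi - sum(coef_v * mean_v)` so each
#' region's mean NDVI sits at `baseNdvi`.
#'
#' @param config a [sceneConfig()].
#' @return List with elements `ndvi` (observed [GridStack-class]),
#'   `climate` (named list of stacks), `ndviC`/`ndviH` (noise-free
#'   components), `truth` (a [SceneTruth-class]) and `config`.
#' @export
generateScene <- function(config) {
  nr <- config$nRows; nc <- config$nCols; ny <- config$nYears
  years <- config$startYear + seq_len(ny) - 1L
  tau <- years - config$startYear
  climate <- lapply(names(config$climate),
                    function(v) generateClimate(config, v))
  names(climate) <- names(config$climate)

  # static fine-scale texture: a regular +/- patch mosaic of fixed amplitude
  # plus jitter, so every 3x3 window has the same, bounded-below spatial
  # spread and the CV trend signal is uniform across the scene
  set.seed(config$seed + 77L)
  checker <- config$textureSd *
    (2 * ((outer(seq_len(nr), seq_len(nc), "+")) %% 2) - 1)
  texture <- checker + matrix(rnorm(nr * nc, sd = 0.2 * config$textureSd),
                              nr, nc)
  set.seed(config$seed + 78L)
  obsNoise <- array(rnorm(ny * nr * nc, sd = config$ndviNoiseSd),
                    c(ny, nr, nc))

  reg <- regionIndexMap(config)
  coefMat <- matrix(0, nr * nc, length(climate),
                    dimnames = list(NULL, names(climate)))
  dVec <- humanVec <- numeric(nr * nc)
  for (k in seq_along(config$regions)) {
    r <- config$regions[[k]]
    px <- which(reg == k)
    for (v in names(r$coef))
      if (v %in% colnames(coefMat)) coefMat[px, v] <- r$coef[[v]]
    dVec[px] <- r$baseNdvi
    # centre the intercept on the local climate mean field so the regional
    # NDVI level sits at baseNdvi and values stay far from the clipping
    # bounds
    for (v in names(r$coef))
      dVec[px] <- dVec[px] -
        r$coef[[v]] * as.vector(climateMeanField(config, v))[px]
    humanVec[px] <- r$humanTrend
  }

  ndviC <- array(0, c(ny, nr, nc))
  for (y in seq_len(ny)) {
    band <- matrix(dVec, nr, nc) + texture
    for (v in names(climate))
      band <- band + matrix(coefMat[, v], nr, nc) *
        climate[[v]]@values[y, , , drop = TRUE]
    ndviC[y, , ] <- band
  }
  ndviH <- array(0, c(ny, nr, nc))
  for (y in seq_len(ny)) ndviH[y, , ] <- matrix(humanVec, nr, nc) * tau[y]

  obs <- ndviC + ndviH + obsNoise
  nClip <- sum(obs < -0.2 | obs > 1)
  if (nClip > 0)
    message("generateScene: clipping ", nClip,
            " NDVI values to [-0.2, 1]; additivity is inexact there")
  obs <- pmin(pmax(obs, -0.2), 1)

  stk <- function(v, name, units = "1")
    gridStack(v, years, name, units)
  ndviCStack <- stk(ndviC, "ndvi_c")
  ndviFree <- stk(ndviC + ndviH, "ndvi_noisefree")

  snap <- function(m) { m[!is.na(m) & abs(m) < 1e-10] <- 0; m }
  slopeC <- snap(olsSlopeMap(ndviCStack))
  slopeH <- matrix(humanVec, nr, nc)
  slopeObs <- slopeC + slopeH

  cvObs <- windowStack(ndviFree, "cv")
  cvC <- windowStack(ndviCStack, "cv")
  cvSlopeObs <- snap(olsSlopeMap(cvObs))
  cvSlopeC <- snap(olsSlopeMap(cvC))
  cvSlopeH <- snap(cvSlopeObs - cvSlopeC)

  med <- windowStack(ndviFree, "median")
  ndviValue <- colMeans(med@values, dims = 1)

  # ground-truth labels derive from the configured trend components alone:
  # the climate-induced NDVI trend g_C = sum(coef_v * trend_v) (exact, the
  # anomalies being detrended), the human trend h, and the static-texture
  # identity sign(CV-component trend) = -sign(NDVI-component trend).
  # Pixels whose 3x3 window straddles two regions mix generating regimes
  # and carry no label.
  gCreg <- vapply(config$regions, function(r)
    sum(vapply(names(r$coef), function(v)
      r$coef[[v]] * config$climate[[v]]$trend, 0)), 0)
  hreg <- vapply(config$regions, function(r) r$humanTrend, 0)
  scnReg <- degReg <- rep(NA_integer_, length(config$regions))
  labReg <- rep("none", length(config$regions))
  for (k in seq_along(config$regions)) {
    g <- gCreg[k] + hreg[k]
    labReg[k] <- if (hreg[k] == 0 && gCreg[k] != 0) "climate"
                 else if (gCreg[k] == 0 && hreg[k] != 0) "human"
                 else if (gCreg[k] != 0 || hreg[k] != 0) "both" else "none"
    if (g == 0) { degReg[k] <- 0L; next }
    nd <- classifyDriver(g, gCreg[k], hreg[k], dynamic = "ndvi")$class
    cd <- classifyDriver(-g, -gCreg[k], -hreg[k], dynamic = "cv")$class
    scnReg[k] <- classifyScenario(nd, cd)$scenario
    degReg[k] <- classifyDegradation(g, -g, config$regions[[k]]$baseNdvi)
  }
  drvLab <- matrix(labReg[reg], nr, nc)
  scnTruth <- matrix(scnReg[reg], nr, nc)
  degTruth <- matrix(degReg[reg], nr, nc)
  interior <- matrix(FALSE, nr, nc)
  if (nr > 2L && nc > 2L) {
    sameL <- reg[, c(1L, seq_len(nc - 1L))] == reg
    sameR <- reg[, c(seq_len(nc - 1L) + 1L, nc)] == reg
    interior[2:(nr - 1L), 2:(nc - 1L)] <-
      (sameL & sameR)[2:(nr - 1L), 2:(nc - 1L)]
  }
  scnTruth[!interior] <- NA_integer_
  degTruth[!interior] <- NA_integer_

  truth <- new("SceneTruth",
    coefA = matrix(coefMat[, 1L], nr, nc),
    coefB = if (ncol(coefMat) >= 2L) matrix(coefMat[, 2L], nr, nc)
            else matrix(0, nr, nc),
    coefC = if (ncol(coefMat) >= 3L) matrix(coefMat[, 3L], nr, nc)
            else matrix(0, nr, nc),
    coefD = matrix(dVec, nr, nc) + texture,
    humanTrend = slopeH, ndviDriver = drvLab,
    slopeObs = slopeObs, slopeC = slopeC, slopeH = slopeH,
    cvSlopeObs = cvSlopeObs, cvSlopeC = cvSlopeC, cvSlopeH = cvSlopeH,
    ndviValue = ndviValue, degradation = degTruth, scenario = scnTruth)

  obsStack <- stk(obs, "ndvi")
  list(ndvi = obsStack, climate = climate,
       ndviC = ndviCStack, ndviH = stk(ndviH, "ndvi_h"),
       truth = truth, config = config)
}

#' Export a scene's ground truth as a data frame
#'
#' One row per pixel (row-major), suitable for writing to CSV.
#'
#' @param truth a [SceneTruth-class].
#' @return A data.frame.
#' @export
truthTable <- function(truth) {
  nr <- nrow(truth@slopeObs); nc <- ncol(truth@slopeObs)
  data.frame(
    row = rep(seq_len(nr), nc), col = rep(seq_len(nc), each = nr),
    coefA = as.vector(truth@coefA), coefB = as.vector(truth@coefB),
    coefC = as.vector(truth@coefC),
    humanTrend = as.vector(truth@humanTrend),
    ndviDriver = as.vector(truth@ndviDriver),
    slopeObs = as.vector(truth@slopeObs),
    slopeC = as.vector(truth@slopeC), slopeH = as.vector(truth@slopeH),
    cvSlopeObs = as.vector(truth@cvSlopeObs),
    ndviValue = as.vector(truth@ndviValue),
    degradation = as.vector(truth@degradation),
    scenario = as.vector(truth@scenario))
}

#' Simulate fractional Gaussian noise with an exact covariance
#'
#' Davies-Harte circulant embedding: the target fGn autocovariance
#' `gamma(k) = 0.5 * (|k+1|^2H - 2|k|^2H + |k-1|^2H)` is embedded in a
#' circulant matrix whose eigenvalues (real FFT of the first row) are
#' non-negative for fGn, giving a stationary Gaussian series with exactly
#' the requested autocovariance.  Used as the independent oracle for the
#' rescaled-range Hurst estimator.  Series of any length `n >= 8` are
#' obtained by embedding at the next power of two.
#'
#' @param hurst Hurst exponent in (0, 1).
#' @param n series length (>= 8).
#' @param seed optional integer seed.
#' @return Numeric vector of length `n` with unit marginal variance.
#' @examples
#' x <- generateFgn(0.8, 256, seed = 1)
#' @export
generateFgn <- function(hurst, n, seed = NULL) {
  if (!is.finite(hurst) || hurst <= 0 || hurst >= 1)
    stop("hurst must be in (0, 1)")
  if (n < 8L) stop("n must be >= 8")
  if (!is.null(seed)) set.seed(seed)
  m <- 2^ceiling(log2(n))          # embedding half-size
  k <- 0:m
  gam <- 0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                  abs(k - 1)^(2 * hurst))
  crow <- c(gam, rev(gam[2:m]))    # circulant first row, length 2m
  lam <- Re(fft(crow))
  lam[lam < 0] <- 0                # guard rounding; theoretically >= 0
  M <- 2L * m
  w <- complex(length.out = M)
  w[1L] <- rnorm(1)
  w[m + 1L] <- rnorm(1)
  u <- rnorm(m - 1L); v <- rnorm(m - 1L)
  w[2:m] <- complex(real = u, imaginary = v) / sqrt(2)
  w[M:(m + 2L)] <- Conj(w[2:m])
  z <- fft(sqrt(lam) * w) / sqrt(M)
  Re(z[seq_len(n)])
}
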