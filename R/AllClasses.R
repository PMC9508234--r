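#' @import methods
#' @importFrom stats coef cor lm lm.fit .lm.fit median pnorm qnorm rnorm runif
#'   sd var complete.cases predict fft setNames
#' @importFrom utils read.csv write.csv head modifyList
NULL

#' GridStack: an annual raster time series
#'
#' The central data container of the package: a stack of co-registered annual
#' raster bands stored as a numeric array indexed \code{[year, row, col]},
#' together with the band years, the variable name/units, and minimal grid
#' geometry (lower-left corner, square cell size, CRS identifier).  Row 1 is
#' the northernmost row.  Missing (nodata) cells are \code{NA}; every
#' statistic in the package skips them.
#'
#' @slot values numeric array \code{[n_years, n_rows, n_cols]}; \code{NA} = nodata.
#' @slot years integer vector, strictly increasing, one per band.
#' @slot variable character scalar, e.g. \code{"ndvi"} or \code{"temperature"}.
#' @slot units character scalar (e.g. \code{"degC"}, \code{"mm"}, \code{"h"}, \code{"1"}).
#' @slot origin numeric length-2 \code{c(xll, yll)}: coordinates of the
#'   lower-left corner of the lower-left cell.
#' @slot pixelSize numeric scalar, cell edge length (square cells).
#' @slot crs character scalar CRS code (informational; all inputs must share it).
#'
#' @seealso [gridStack()], [readStack()], [writeStack()]
#' @export
setClass("GridStack",
  representation(
    values    = "array",
    years     = "integer",
    variable  = "character",
    units     = "character",
    origin    = "numeric",
    pixelSize = "numeric",
    crs       = "character"
  )
)

setValidity("GridStack", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L)
    msg <- c(msg, "values must be a 3-d array [year, row, col]")
  if (length(object@years) != d[1L])
    msg <- c(msg, "length(years) must equal dim(values)[1]")
  if (length(object@years) > 1L && any(diff(object@years) <= 0L))
    msg <- c(msg, "years must be strictly increasing")
  if (length(object@origin) != 2L)
    msg <- c(msg, "origin must be length-2 (xll, yll)")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Mask: a spatial include/exclude layer
#'
#' @slot values logical matrix \code{[n_rows, n_cols]}; \code{TRUE} = include.
#' @slot provenance character, one of \code{"grassland"}, \code{"road_river"},
#'   \code{"custom"}.
#' @export
setClass("Mask",
  representation(values = "matrix", provenance = "character"))

setValidity("Mask", function(object) {
  msg <- character()
  if (!is.logical(object@values))
    msg <- c(msg, "mask values must be logical")
  if (!object@provenance %in% c("grassland", "road_river", "custom"))
    msg <- c(msg, "provenance must be grassland, road_river or custom")
  if (length(msg)) msg else TRUE
})

#' TrendMap: per-pixel Theil-Sen slope and Mann-Kendall significance
#'
#' @slot slope numeric matrix of Sen slopes (variable units per year).
#' @slot sStat numeric matrix of Mann-Kendall S statistics.
#' @slot z numeric matrix of the normal-approximation Z statistic.
#' @slot p numeric matrix of two-sided p-values.
#' @slot alpha significance level used by [significantCells()].
#' @slot variable name of the mapped variable.
#' @export
setClass("TrendMap",
  representation(slope = "matrix", sStat = "matrix", z = "matrix",
                 p = "matrix", alpha = "numeric", variable = "character"))

setValidity("TrendMap", function(object) {
  msg <- character()
  dm <- dim(object@slope)
  for (s in c("sStat", "z", "p"))
    if (!identical(dim(slot(object, s)), dm))
      msg <- c(msg, sprintf("dim(%s) must match dim(slope)", s))
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' SceneTruth: per-pixel ground truth of a synthetic scene
#'
#' Generated alongside a synthetic scene so downstream stages can be scored
#' against a known answer.  All slope/label matrices are on the scene grid;
#' window-based quantities are \code{NA} on the one-pixel boundary.
#'
#' @slot coefA,coefB,coefC,coefD numeric matrices of the generating
#'   climate-response coefficients per pixel.
#' @slot humanTrend numeric matrix, additive human NDVI trend (NDVI/yr).
#' @slot ndviDriver character matrix: \code{"climate"}, \code{"human"},
#'   \code{"both"} or \code{"none"} (rule on the generating trend components).
#' @slot slopeObs,slopeC,slopeH OLS slopes of the noise-free observed,
#'   climate-only and human NDVI components.
#' @slot cvSlopeObs,cvSlopeC,cvSlopeH same for the 3x3-window CV stacks.
#' @slot ndviValue period-mean window-median NDVI of the noise-free scene.
#' @slot degradation integer matrix of true degradation level codes.
#' @slot scenario integer matrix of true scenario ids 1-12 (NA where a slope
#'   is exactly zero).
#' @export
setClass("SceneTruth",
  representation(
    coefA = "matrix", coefB = "matrix", coefC = "matrix", coefD = "matrix",
    humanTrend = "matrix", ndviDriver = "matrix",
    slopeObs = "matrix", slopeC = "matrix", slopeH = "matrix",
    cvSlopeObs = "matrix", cvSlopeC = "matrix", cvSlopeH = "matrix",
    ndviValue = "matrix", degradation = "matrix", scenario = "matrix"
  )
)

#' DegradationMap: six-level degradation/restoration classification
#'
#' Integer-coded level map plus the three inputs that produced it.  Codes are
#' given by [degradationLevels()].
#'
#' @slot level integer matrix of level codes.
#' @slot ndviSlope,cvSlope,ndviValue the classification inputs.
#' @export
setClass("DegradationMap",
  representation(level = "matrix", ndviSlope = "matrix",
                 cvSlope = "matrix", ndviValue = "matrix"))

#' HotPlotMap: local Moran's I clusters over the degraded area
#'
#' @slot localI numeric matrix of local Moran's I values (NA outside the
#'   analysed region).
#' @slot p numeric matrix of conditional-permutation p-values.
#' @slot cluster character matrix with labels \code{"HH"}, \code{"LL"},
#'   \code{"HL"}, \code{"LH"}, \code{"ns"} inside the region, NA outside.
#' @slot alpha significance level used for labelling.
#' @export
setClass("HotPlotMap",
  representation(localI = "matrix", p = "matrix", cluster = "matrix",
                 alpha = "numeric"))

#' DriverMap: per-pixel driver classes and contribution rates
#'
#' @slot ndviDriver character matrix with codes CDNI/HDNI/BDNI/CDND/HDND/BDND.
#' @slot cvDriver character matrix with codes CDCI/HDCI/BDCI/CDCD/HDCD/BDCD.
#' @slot climatePct,humanPct numeric matrices, contribution rates in percent
#'   for the NDVI dynamic (sum to 100 wherever defined).
#' @slot cvClimatePct,cvHumanPct contribution rates for the CV dynamic.
#' @export
setClass("DriverMap",
  representation(ndviDriver = "matrix", cvDriver = "matrix",
                 climatePct = "matrix", humanPct = "matrix",
                 cvClimatePct = "matrix", cvHumanPct = "matrix"))

#' ScenarioMap: the twelve-scenario typology of grassland dynamics
#'
#' @slot scenario integer matrix with ids 1-12.
#' @slot label character matrix with the scenario short labels (CDI, HDI,
#'   BDI, CDSR, ..., BDSD).
#' @export
setClass("ScenarioMap",
  representation(scenario = "matrix", label = "matrix"))

#' HurstMap: per-pixel rescaled-range Hurst exponent
#'
#' @slot h numeric matrix of Hurst exponents in (0, 1).
#' @slot r2 numeric matrix, R-squared of the log-log R/S fit (quality flag).
#' @slot variable name of the analysed variable.
#' @export
setClass("HurstMap",
  representation(h = "matrix", r2 = "matrix", variable = "character"))

#' ForecastMap: future-dynamics transition classes
#'
#' @slot transition integer matrix of transition codes, see
#'   [forecastClasses()].
#' @slot forecastLevel integer matrix of forecast degradation level codes.
#' @slot currentLevel integer matrix of current degradation level codes.
#' @export
setClass("ForecastMap",
  representation(transition = "matrix", forecastLevel = "matrix",
                 currentLevel = "matrix"))
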