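#' Degradation/restoration level codes
#'
#' The six-level typology driven by the signs of the NDVI trend and the
#' CV_NDVI (spatial heterogeneity) trend plus the 0.2 NDVI cover threshold,
#' with an extra `Stable` code for pixels whose NDVI or CV trend is exactly
#' zero (excluded from degraded/restored totals).
#'
#' @return data.frame with `code`, `name`, `group`
#'   (restoration/degradation/stable).
#' @export
degradationLevels <- function() {
  data.frame(
    code = c(1L, 2L, 3L, 4L, 5L, 6L, 0L),
    name = c("Improving", "Regrowing", "Slight degradation",
             "Moderate degradation", "Severe degradation",
             "Desertification", "Stable"),
    group = c("restoration", "restoration", "degradation", "degradation",
              "degradation", "degradation", "stable"),
    stringsAsFactors = FALSE)
}

degradedCodes <- function() c(3L, 4L, 5L, 6L)

#' Classify degradation level from trend signs and NDVI cover
#'
#' Pure function of three inputs, applied elementwise (scalars, vectors or
#' matrices):
#' \itemize{
#'   \item NDVI up, CV down: Improving (1)
#'   \item NDVI up, CV up, NDVI value < 0.2: Regrowing (2)
#'   \item NDVI up, CV up, NDVI value >= 0.2: Slight degradation (3)
#'   \item NDVI down, CV up: Moderate degradation (4)
#'   \item NDVI down, CV down, NDVI value >= 0.2: Severe degradation (5)
#'   \item NDVI down, CV down, NDVI value < 0.2: Desertification (6)
#' }
#' An exactly zero NDVI or CV slope gives Stable (0); an NDVI value of
#' exactly 0.2 falls in the >= 0.2 branch; any NA input gives NA.
#'
#' @param ndviSlope,cvSlope trend estimates (any units, only signs used).
#' @param ndviValue period-mean NDVI (window median), compared to 0.2.
#' @return Integer level codes, same shape as the inputs.
#' @examples
#' classifyDegradation(0.004, -0.001, 0.5)   # 1, Improving
#' classifyDegradation(-0.004, -0.001, 0.5)  # 5, Severe
#' @export
classifyDegradation <- function(ndviSlope, cvSlope, ndviValue) {
  out <- rep(NA_integer_, length(ndviSlope))
  ns <- as.vector(ndviSlope); cs <- as.vector(cvSlope)
  nv <- as.vector(ndviValue)
  ok <- !is.na(ns) & !is.na(cs) & !is.na(nv)
  hi <- nv >= 0.2
  out[ok & ns > 0 & cs < 0] <- 1L
  out[ok & ns > 0 & cs > 0 & !hi] <- 2L
  out[ok & ns > 0 & cs > 0 & hi] <- 3L
  out[ok & ns < 0 & cs > 0] <- 4L
  out[ok & ns < 0 & cs < 0 & hi] <- 5L
  out[ok & ns < 0 & cs < 0 & !hi] <- 6L
  out[ok & (ns == 0 | cs == 0)] <- 0L
  if (is.matrix(ndviSlope)) out <- matrix(out, nrow(ndviSlope), ncol(ndviSlope))
  out
}

#' Build a DegradationMap from trend maps and the NDVI value layer
#'
#' @param ndviTrend [TrendMap-class] of the annual window-median NDVI.
#' @param cvTrend [TrendMap-class] of the annual window CV.
#' @param ndviValue matrix of period-mean window-median NDVI.
#' @return A [DegradationMap-class].
#' @export
degradationMap <- function(ndviTrend, cvTrend, ndviValue) {
  lev <- classifyDegradation(ndviTrend@slope, cvTrend@slope, ndviValue)
  new("DegradationMap", level = lev, ndviSlope = ndviTrend@slope,
      cvSlope = cvTrend@slope, ndviValue = ndviValue)
}

setMethod("show", "DegradationMap", function(object) {
  tab <- degradationLevels()
  cnt <- table(factor(object@level, levels = tab$code, labels = tab$name))
  cat("DegradationMap:", nrow(object@level), "x", ncol(object@level),
      "cells\n")
  for (nm in names(cnt)) if (cnt[[nm]] > 0)
    cat(sprintf("  %-22s %d\n", nm, cnt[[nm]]))
})

# queen-contiguity neighbour lists restricted to a set of pixels
queenNeighbors <- function(inSet) {
  nr <- nrow(inSet); nc <- ncol(inSet)
  id <- matrix(NA_integer_, nr, nc)
  cells <- which(inSet)
  id[cells] <- seq_along(cells)
  nbr <- vector("list", length(cells))
  rc <- arrayInd(cells, dim(inSet))
  for (k in seq_along(cells)) {
    r <- rc[k, 1L]; c <- rc[k, 2L]
    rs <- max(1L, r - 1L):min(nr, r + 1L)
    cs <- max(1L, c - 1L):min(nc, c + 1L)
    ids <- id[rs, cs]
    ids <- ids[!is.na(ids)]
    nbr[[k]] <- ids[ids != id[r, c]]
  }
  list(cells = cells, neighbors = nbr)
}

#' Degradation hot plots via local Moran's I
#'
#' Computes Anselin's local Moran's I of an intensity variable (by default
#' the NDVI Sen slope) over the degraded pixels of a degradation map, with
#' queen-contiguity row-standardised weights and conditional-permutation
#' p-values (each pixel's value held fixed, its neighbours drawn without
#' replacement from the remaining analysed pixels).  Significant pixels are
#' labelled HH/LL/HL/LH by the quadrant of (value, spatial lag) around the
#' regional mean; HH/LL are the degradation hot/cold clusters.
#'
#' @param degradation a [DegradationMap-class].
#' @param intensity matrix of the clustering variable; defaults to the
#'   map's NDVI slope.
#' @param nPermutations conditional permutations (default 999).
#' @param alpha significance level for cluster labels.
#' @param seed optional seed for the permutations.
#' @return A [HotPlotMap-class].
#' @export
hotPlots <- function(degradation, intensity = degradation@ndviSlope,
                     nPermutations = 999L, alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  inSet <- !is.na(degradation@level) &
    degradation@level %in% degradedCodes() & !is.na(intensity)
  n <- sum(inSet)
  if (n < 10L)
    stop("hot-plot analysis needs >= 10 degraded pixels with valid ",
         "intensity; found ", n)
  nb <- queenNeighbors(inSet)
  x <- intensity[nb$cells]
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  lag <- vapply(nb$neighbors,
                function(j) if (length(j)) mean(z[j]) else NA_real_, 0)
  localI <- z / m2 * lag

  p <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    kk <- length(nb$neighbors[[k]])
    if (kk == 0L || is.na(localI[k])) next
    others <- z[-k]
    sims <- vapply(seq_len(nPermutations), function(s)
      mean(others[sample.int(n - 1L, kk)]), 0)
    simI <- z[k] / m2 * sims
    ge <- sum(simI >= localI[k]); le <- sum(simI <= localI[k])
    p[k] <- min(1, 2 * (min(ge, le) + 1) / (nPermutations + 1))
  }

  cl <- rep("ns", n)
  sig <- !is.na(p) & p < alpha
  cl[sig & z > 0 & lag > 0] <- "HH"
  cl[sig & z < 0 & lag < 0] <- "LL"
  cl[sig & z > 0 & lag < 0] <- "HL"
  cl[sig & z < 0 & lag > 0] <- "LH"

  dm <- dim(degradation@level)
  iM <- pM <- matrix(NA_real_, dm[1L], dm[2L])
  cM <- matrix(NA_character_, dm[1L], dm[2L])
  iM[nb$cells] <- localI
  pM[nb$cells] <- p
  cM[nb$cells] <- cl
  new("HotPlotMap", localI = iM, p = pM, cluster = cM, alpha = alpha)
}
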