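# grasstrend

Pixel-wise analysis of grassland degradation and restoration from annual
NDVI raster time series: where grassland is degrading, whether climate or
human activity is driving it, and whether the trend will persist.

Degrading grassland betrays itself twice in satellite greenness: the NDVI
level falls, and — earlier — the fine-scale *spatial heterogeneity* of NDVI
rises as bare-soil patches form. `grasstrend` therefore tracks two coupled
series per pixel: the annual 3×3-window median NDVI and the annual
3×3-window coefficient of variation (CV_NDVI = sd/mean over the nine
cells). On top of these it provides:

- **Trend mapping** — Theil–Sen slope
  `M = median[(a_j − a_i)/(j − i)]` with the Mann–Kendall test
  (`S = Σ_{i<j} sgn(a_j − a_i)`, tie-corrected variance, two-sided p).
- **Degradation levels** — the six-class rule on
  (sign NDVI slope, sign CV slope, NDVI ≷ 0.2): Improving, Regrowing,
  Slight/Moderate/Severe degradation, Desertification.
- **Hot plots** — local Moran's I clusters of the NDVI slope over the
  degraded area (queen weights, conditional permutations).
- **Improved RESTREND attribution** — dominant climate variables selected
  by random forest + stepwise regression; per-pixel OLS
  `NDVI_C = aT + bP + cS + d`; residual `NDVI_H = NDVI_obs − NDVI_C` (and
  the same split for CV_NDVI); driver classes with contribution rates
  `100·slope_C/slope_obs` + `100·slope_H/slope_obs` = 100%; and the
  twelve-scenario typology of (NDVI driver × CV driver) pairs.
- **Persistence forecast** — rescaled-range Hurst exponent per pixel
  (`log(R/S) = a + H log n`), trend-sign superposition (H > 0.5 keeps the
  sign, H < 0.5 flips it, H = 0.5 is unforecastable) and the four
  transition classes (continuous improvement/degradation and the two
  crossovers).
- **Synthetic scenes with ground truth** — co-registered climate and NDVI
  stacks whose per-pixel driver composition is known exactly, plus an
  exact-covariance fractional-Gaussian-noise simulator; every stage is
  validated against this truth.

The package is aimed at ecologists and remote-sensing analysts working
with modest annual stacks (tens of years × up to ~10⁶ pixels) who want the
full degradation → attribution → forecast chain reproducible from one
seeded config.

## Worked example

```r
library(grasstrend)
scene <- generateScene(sceneConfig(nRows = 30, nCols = 36, seed = 7))
scene$ndvi
#> GridStack 'ndvi' [1]: 20 years (2000-2019), 30 x 36 cells
#>   origin (0, 0), pixel 1, crs local; 0.0% nodata

att <- restrendAttribution(scene$ndvi, scene$climate,
                           variables = c("temperature", "precipitation", "sunshine"))
att$scenarios
#> ScenarioMap: 30 x 36 cells
#>  BDI BDMD  CDI CDMD CDSR  HDI HDMD
#>  119  126  165  185   18  174  165

med <- windowStack(scene$ndvi, "median")
cv  <- windowStack(scene$ndvi, "cv")
dm  <- degradationMap(trendMap(med), trendMap(cv),
                      colMeans(gridValues(med), dims = 1))
tab <- summarizeAreas(dm@level, degradationLevels(), pixelSize = 30)
tab[tab$count > 0, ]
#>  code                 name count   area   pct
#>     1            Improving   451 405900 47.37
#>     3   Slight degradation    27  24300  2.84
#>     4 Moderate degradation   462 415800 48.53
#>     5   Severe degradation    12  10800  1.26
```

The scene's six generator regions pair climate-driven, human-driven and
jointly driven NDVI trends of both signs, so the scenario table shows the
corresponding CDI/HDI/BDI (improvement) and CDMD/HDMD/BDMD (moderate
degradation) blocks; the counts above are what the code prints for seed 7.
The area table reads: 48.5% of the analysed area is moderately degrading
(NDVI falling while spatial heterogeneity rises), 47.4% improving, and the
percentages total 100 over the analysed (non-nodata) pixels.

A full pipeline run — trends, degradation, hot plots, attribution, Hurst,
forecast, area summaries and a checksum manifest — comes from one config:

```r
man <- runPipeline(system.file("extdata", "demo_run.yaml", package = "grasstrend"),
                   outputDir = "demo_out")
```

A thin command-line front end (`inst/scripts/grasstrend.R`) wraps
`simulate` and `run-all` for shell use. Real rasters enter as per-year
ESRI ASCII grids or multiband TIFF + JSON sidecar (`readStack`); road and
river exclusions are applied with `applyMask` (buffered dilation) before
the CV stage, and 1 km climate grids are aligned with `resampleTo`
(bilinear for fields, nearest for masks).

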