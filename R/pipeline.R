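#' Read a pipeline run configuration
#'
#' YAML file with either a `scene:` block (synthetic input, fields of
#' [sceneConfig()]) or an `inputs:` block (paths to NDVI and climate `.asc`
#' stacks plus years), and optional `alpha`, `selection` (settings for
#' [selectClimateVariables()] or a fixed `variables:` list), `hurst`
#' settings, `hotplots` settings, `seed` and `outputDir`.
#'
#' @param path YAML config path.
#' @return A validated list of class `runConfig`.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
}

validateRunConfig <- function(cfg) {
  if (is.null(cfg$scene) && is.null(cfg$inputs))
    stop("config must contain either a 'scene' block (synthetic run) or ",
         "an 'inputs' block (paths); both are missing")
  if (!is.null(cfg$inputs)) {
    for (f in c("ndvi", "climate", "years"))
      if (is.null(cfg$inputs[[f]]))
        stop("config field 'inputs$", f, "' is missing")
  }
  cfg$alpha <- cfg$alpha %||% 0.05
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$hotplots <- modifyList(list(enabled = TRUE, nPermutations = 199L),
                             cfg$hotplots %||% list())
  cfg$selection <- cfg$selection %||% list()
  class(cfg) <- "runConfig"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sceneConfigFromList <- function(lst, seed) {
  args <- lst[intersect(names(lst),
                        c("nYears", "nRows", "nCols", "startYear",
                          "textureSd", "ndviNoiseSd", "seed"))]
  if (is.null(args$seed)) args$seed <- seed
  do.call(sceneConfig, args)
}

#' Run the full analysis pipeline from one configuration
#'
#' Executes, in order: input assembly (synthetic scene or `.asc` stacks),
#' windowed median/CV stacks, Sen + Mann-Kendall trend maps, the
#' degradation classification, degradation hot plots, the improved
#' residual-trend attribution (selection, regression, decomposition,
#' drivers, scenarios), per-pixel Hurst maps of NDVI and CV, and the
#' forecast transition map.  Every stage product is materialised under
#' `outputDir` (`.asc` rasters, CSV summaries and code tables, a selection
#' report) together with a JSON manifest of per-file MD5 checksums, so a
#' run is reproducible and auditable from config + seed alone.
#'
#' @param config a `runConfig` list (from [readRunConfig()]) or a path to
#'   a YAML config.
#' @param outputDir overrides the config's output directory.
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`); key results are attached in the `results`
#'   attribute.
#' @export
runPipeline <- function(config, outputDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  else config <- validateRunConfig(unclass(config))
  outDir <- outputDir %||% config$outputDir %||% stop("no output directory")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logf <- function(...) message("[grasstrend] ", sprintf(...))

  # ---- stage 1: inputs ----
  truth <- NULL
  if (!is.null(config$scene)) {
    logf("generating synthetic scene (seed %d)", config$seed)
    sc <- sceneConfigFromList(config$scene, config$seed)
    scene <- generateScene(sc)
    ndvi <- scene$ndvi; climate <- scene$climate; truth <- scene$truth
    write.csv(truthTable(truth), file.path(outDir, "truth.csv"),
              row.names = FALSE)
  } else {
    logf("reading input stacks")
    yrs <- config$inputs$years
    ndvi <- readStack(config$inputs$ndvi, yrs, "ndvi")
    climate <- lapply(config$inputs$climate, function(p)
      readStack(p, yrs, "climate"))
    for (v in names(climate)) climate[[v]]@variable <- v
  }
  if (!is.null(config$inputs$mask)) {
    m <- readAsc(config$inputs$mask)
    ndvi <- applyMask(ndvi, gridMask(!is.na(m$values) & m$values != 0,
                                     "road_river"),
                      config$inputs$maskBuffer %||% 1L)
  }

  # ---- stage 2: windowed stacks + trends ----
  logf("windowed stacks and trend maps")
  med <- windowStack(ndvi, "median")
  cv <- windowStack(ndvi, "cv")
  ndviTrend <- trendMap(med, config$alpha)
  cvTrend <- trendMap(cv, config$alpha)
  ndviValue <- colMeans(med@values, dims = 1)

  # ---- stage 3: degradation ----
  degr <- degradationMap(ndviTrend, cvTrend, ndviValue)

  # ---- stage 4: hot plots ----
  hot <- NULL
  if (isTRUE(config$hotplots$enabled)) {
    hot <- tryCatch(
      hotPlots(degr, nPermutations = config$hotplots$nPermutations,
               alpha = config$alpha, seed = config$seed),
      error = function(e) { logf("hot plots skipped: %s", conditionMessage(e)); NULL })
  }

  # ---- stage 5-6: RESTREND attribution ----
  logf("residual-trend attribution")
  att <- tryCatch(
    restrendAttribution(ndvi, climate,
                        variables = config$selection$variables,
                        selectionSeed = config$seed),
    error = function(e) {
      logf("selection empty (%s); using all candidates", conditionMessage(e))
      restrendAttribution(ndvi, climate, variables = names(climate),
                          selectionSeed = config$seed)
    })

  # ---- stage 7: Hurst + forecast ----
  logf("Hurst persistence and forecast")
  hN <- hurstMap(med)
  hC <- hurstMap(cv)
  fc <- forecastDynamics(hN, hC, ndviTrend@slope, cvTrend@slope,
                         ndviValue, degr@level)

  # ---- outputs ----
  logf("writing products to %s", outDir)
  wAsc <- function(mat, name) {
    writeAsc(mat, file.path(outDir, paste0(name, ".asc")),
             ndvi@origin, ndvi@pixelSize)
  }
  wAsc(ndviTrend@slope, "ndvi_slope"); wAsc(ndviTrend@p, "ndvi_trend_p")
  wAsc(cvTrend@slope, "cv_slope"); wAsc(cvTrend@p, "cv_trend_p")
  wAsc(ndviValue, "ndvi_value")
  wAsc(degr@level + 0, "degradation_level")
  if (!is.null(hot)) { wAsc(hot@localI, "hotplot_local_i"); wAsc(hot@p, "hotplot_p") }
  wAsc(att$slopes$ndviC, "ndvi_slope_climate")
  wAsc(att$slopes$ndviH, "ndvi_slope_human")
  wAsc(att$drivers@climatePct, "climate_contribution_pct")
  wAsc(att$drivers@humanPct, "human_contribution_pct")
  wAsc(att$scenarios@scenario + 0, "scenario")
  wAsc(hN@h, "hurst_ndvi"); wAsc(hC@h, "hurst_cv")
  wAsc(fc@transition + 0, "forecast_transition")

  write.csv(degradationLevels(), file.path(outDir, "degradation_codes.csv"),
            row.names = FALSE)
  write.csv(scenarioTable(), file.path(outDir, "scenario_codes.csv"),
            row.names = FALSE)
  write.csv(forecastClasses(), file.path(outDir, "forecast_codes.csv"),
            row.names = FALSE)
  areas <- list(
    degradation = summarizeAreas(degr@level, degradationLevels(),
                                 ndvi@pixelSize),
    scenario = summarizeAreas(att$scenarios@scenario,
                              data.frame(code = 1:12,
                                         name = scenarioTable()$label[
                                           !duplicated(scenarioTable()$scenario)]),
                              ndvi@pixelSize),
    forecast = summarizeAreas(fc@transition, forecastClasses(),
                              ndvi@pixelSize))
  for (nm in names(areas))
    write.csv(areas[[nm]], file.path(outDir, paste0("area_", nm, ".csv")),
              row.names = FALSE)
  selRep <- data.frame(variable = att$variables,
                       rank = seq_along(att$variables))
  imp <- attr(att$variables, "importance")
  if (!is.null(imp))
    selRep <- merge(selRep,
                    data.frame(variable = names(imp), importance = imp),
                    by = "variable", all.x = TRUE)
  write.csv(selRep, file.path(outDir, "selection_report.csv"),
            row.names = FALSE)

  files <- sort(list.files(outDir, full.names = TRUE))
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    seed = config$seed, alpha = config$alpha,
    variables = as.character(att$variables),
    package = as.character(utils::packageVersion("grasstrend")),
    products = lapply(stats::setNames(files, basename(files)),
                      function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results <- list(ndvi = ndvi, climate = climate, degradation = degr,
                  hotplots = hot, attribution = att, hurstNdvi = hN,
                  hurstCv = hC, forecast = fc, areas = areas, truth = truth)
  attr(manifest, "results") <- results
  invisible(manifest)
}

#' Class-area bookkeeping for a coded map
#'
#' Per class: pixel count, area (count x cell area) and percentage of the
#' analysed (non-nodata) area; percentages sum to 100 up to rounding.
#'
#' @param codedMap integer matrix of class codes.
#' @param codeTable data.frame with `code` and `name` columns.
#' @param pixelSize cell edge length (area = count * pixelSize^2).
#' @return data.frame with `code`, `name`, `count`, `area`, `pct`.
#' @export
summarizeAreas <- function(codedMap, codeTable, pixelSize = 1) {
  vals <- codedMap[!is.na(codedMap)]
  if (!length(vals)) {
    warning("all-nodata map: empty area summary")
    return(data.frame(code = integer(), name = character(),
                      count = integer(), area = numeric(), pct = numeric()))
  }
  unknown <- setdiff(unique(vals), codeTable$code)
  if (length(unknown))
    stop("unknown class code(s): ", paste(unknown, collapse = ", "))
  cnt <- table(factor(vals, levels = codeTable$code))
  data.frame(code = codeTable$code, name = codeTable$name,
             count = as.integer(cnt),
             area = as.integer(cnt) * pixelSize^2,
             pct = 100 * as.integer(cnt) / length(vals))
}
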