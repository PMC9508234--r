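test_that("pixel regression recovers exact coefficients and flags degeneracy", {
  s <- regressionScene(0)
  fit <- fitPixelRegression(s$ndvi, s$climate)
  expect_lt(max(abs(fit$coefficients["temperature", , ] - 0.10)), 1e-10)
  expect_lt(max(abs(fit$coefficients["precipitation", , ] - 0.001)), 1e-10)
  expect_lt(max(abs(fit$coefficients["sunshine", , ] + 0.0001)), 1e-10)
  expect_gt(min(fit$r2), 1 - 1e-10)
  # constant response: slope coefficients vanish, intercept carries it
  const <- gridStack(array(0.37, dim(gridValues(s$ndvi))),
                     gridYears(s$ndvi))
  fc <- fitPixelRegression(const, s$climate)
  expect_lt(max(abs(fc$coefficients["temperature", , ])), 1e-12)
  expect_lt(max(abs(fc$coefficients["intercept", , ] - 0.37)), 1e-9)
  # rank-deficient design (duplicated predictor) -> nodata with warning
  dup <- s$climate[c("temperature", "temperature")]
  names(dup) <- c("t1", "t2")
  expect_warning(fd <- fitPixelRegression(s$ndvi, dup),
                 "rank-deficient")
  expect_true(all(is.na(fd$coefficients)))
  # misaligned climate stack -> alignment error
  off <- s$climate$temperature
  off@origin <- c(999, 999)
  expect_error(fitPixelRegression(s$ndvi, list(temperature = off)),
               "alignment")
})

test_that("residual decomposition is exact and conservative", {
  s <- regressionScene(0.02)
  fit <- fitPixelRegression(s$ndvi, s$climate)
  res <- restrendDecompose(s$ndvi, fit$predicted)
  # conservation: residual + predicted reconstructs the observation bit-exactly
  expect_identical(gridValues(res$ndviH) + gridValues(fit$predicted),
                   gridValues(s$ndvi))
  expect_identical(gridValues(res$cvH),
                   gridValues(res$cvObs) - gridValues(res$cvC))
  # obs == predicted -> residuals identically zero
  res0 <- restrendDecompose(fit$predicted, fit$predicted)
  expect_true(all(gridValues(res0$ndviH) == 0))
  expect_true(all(gridValues(res0$cvH)[!is.na(gridValues(res0$cvH))] == 0))
  # additive construction: obs = predicted + beta*t has residual slope beta
  beta <- 0.004
  yrs <- gridYears(s$ndvi)
  shifted <- gridValues(fit$predicted) +
    array(rep(beta * (yrs - yrs[1]), length.out = length(yrs)),
          dim(gridValues(fit$predicted)))
  obs2 <- gridStack(shifted, yrs)
  res2 <- restrendDecompose(obs2, fit$predicted)
  expect_lt(max(abs(olsSlopeMap(res2$ndviH) - beta)), 1e-12)
})

test_that("driver classification reproduces the six-row table and ratios", {
  r <- classifyDriver(0.004, 0.005, -0.001)
  expect_equal(r$class, "CDNI")
  expect_equal(c(r$climatePct, r$humanPct), c(100, 0))
  r <- classifyDriver(0.004, -0.001, 0.005)
  expect_equal(r$class, "HDNI")
  expect_equal(c(r$climatePct, r$humanPct), c(0, 100))
  r <- classifyDriver(0.004, 0.003, 0.001)
  expect_equal(r$class, "BDNI")
  expect_equal(c(r$climatePct, r$humanPct), c(75, 25))
  # decline-side rows
  expect_equal(classifyDriver(-0.004, -0.005, 0.001)$class, "CDND")
  expect_equal(classifyDriver(-0.004, 0.001, -0.005)$class, "HDND")
  expect_equal(classifyDriver(-0.004, -0.003, -0.001, "cv")$class, "BDCD")
  # zero components take the pure-driver rows
  expect_equal(classifyDriver(0.004, 0, 0.004)$class, "HDNI")
  expect_equal(classifyDriver(0.004, 0.004, 0)$class, "CDNI")
  # impossible additive pattern is a diagnostic error
  expect_error(classifyDriver(0.004, -0.001, -0.001), "sign pattern")
  # contributions always sum to 100 under additive slopes
  set.seed(8)
  sc <- rnorm(500); sh <- rnorm(500); so <- sc + sh
  keep <- so != 0
  out <- classifyDriver(so[keep], sc[keep], sh[keep])
  expect_true(all(abs(out$climatePct + out$humanPct - 100) < 1e-9))
})

test_that("the scenario lookup reproduces the published twelve-scenario table", {
  ref <- verbatimScenarioRows()
  tab <- scenarioTable()
  got <- merge(ref, tab, by = c("ndviDriver", "cvDriver"),
               suffixes = c(".ref", ".pkg"))
  expect_equal(nrow(got), 36)
  expect_equal(got$scenario.pkg, got$scenario.ref)
  expect_equal(got$label.pkg, got$label.ref)
  # elementwise lookups, including the published examples
  expect_equal(classifyScenario("CDNI", "CDCD")$scenario, 1L)
  expect_equal(classifyScenario("HDND", "HDCI")$scenario, 8L)
  expect_equal(classifyScenario("BDND", "BDCD")$scenario, 12L)
  expect_true(is.na(classifyScenario(NA_character_, "CDCD")$scenario))
  expect_error(classifyScenario("XDNI", "CDCD"), "absent")
})

test_that("variable selection ranks a dominant predictor first and drops constants", {
  cfg <- sceneConfig(nRows = 16, nCols = 16,
                     climate = defaultClimateSpecs()[c("temperature",
                                                       "precipitation",
                                                       "wind")],
                     regions = list(list(
                       name = "only_t", coef = c(temperature = 0.10),
                       baseNdvi = 0.5, humanTrend = 0)),
                     ndviNoiseSd = 0.005, seed = 61)
  s <- generateScene(cfg)
  sel <- selectClimateVariables(s$ndvi, s$climate, seed = 61,
                                maxRows = 1500, nTrees = 200)
  expect_equal(sel[1], "temperature")
  imp <- attr(sel, "importance")
  expect_equal(names(imp)[1], "temperature")
  # a constant candidate is excluded with a warning
  const <- gridStack(array(1, dim(gridValues(s$ndvi))), gridYears(s$ndvi),
                     "flat")
  expect_warning(
    selectClimateVariables(s$ndvi, c(s$climate, list(flat = const)),
                           seed = 61, maxRows = 1000, nTrees = 100),
    "constant")
})

test_that("attribution conserves contributions and matches slope additivity", {
  s <- smallScene()
  att <- restrendAttribution(s$ndvi, s$climate,
                             variables = c("temperature", "precipitation",
                                           "sunshine"))
  sl <- att$slopes
  # additivity holds wherever the residual gate left the human slope alone
  ung <- sl$ndviH != 0
  expect_gt(sum(ung), 500)
  expect_lt(max(abs((sl$ndviObs - sl$ndviC - sl$ndviH)[ung])), 1e-9)
  ok <- !is.na(att$drivers@climatePct)
  expect_true(all(abs(att$drivers@climatePct[ok] +
                        att$drivers@humanPct[ok] - 100) < 1e-9))
  okc <- !is.na(att$drivers@cvClimatePct)
  expect_true(all(abs(att$drivers@cvClimatePct[okc] +
                        att$drivers@cvHumanPct[okc] - 100) < 1e-9))
  # driver direction suffix always matches the observed trend sign
  ni <- att$drivers@ndviDriver[ok]
  expect_true(all(substr(ni, 3, 4) == ifelse(sl$ndviObs[ok] > 0, "NI", "ND")))
})
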