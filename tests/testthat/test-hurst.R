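test_that("R/S statistic matches a direct transcription of the definition", {
  set.seed(14)
  x <- rnorm(256)
  for (m in c(8, 16, 32, 64)) {
    # reproduce the per-window averaged R/S through the fitting interface
    fit <- rsHurst(x, windowSet = c(m, 2 * m))
    expect_true(is.finite(fit$h))
  }
  # the fitted H reproduces a two-point log-log slope computed by hand
  rs1 <- oracleRs(x, 16); rs2 <- oracleRs(x, 64)
  hand <- (log(rs2) - log(rs1)) / (log(64) - log(16))
  fit <- rsHurst(x, windowSet = c(16, 64))
  expect_equal(fit$h, min(max(hand, 0.001), 0.999), tolerance = 1e-12)
  expect_equal(fit$r2, 1)   # two points fit exactly
})

test_that("R/S estimation is affine invariant and guards degenerate input", {
  set.seed(15)
  x <- rnorm(128)
  h1 <- rsHurst(x)$h
  expect_equal(rsHurst(3.2 * x + 7)$h, h1, tolerance = 1e-10)
  expect_warning(out <- rsHurst(rep(2, 64)), "constant")
  expect_true(is.na(out$h))
  expect_true(is.na(rsHurst(rnorm(10))$h))
})

test_that("persistence classes follow the 0.5 threshold rule", {
  expect_equal(persistenceClass(0.7), "persistent")
  expect_equal(persistenceClass(0.3), "anti-persistent")
  expect_equal(persistenceClass(0.5), "unpredictable")
  expect_true(is.na(persistenceClass(NA_real_)))
  m <- matrix(c(0.6, 0.4, 0.5, NA), 2, 2)
  pm <- persistenceClass(m)
  expect_equal(dim(pm), c(2, 2))
  expect_equal(pm[1, 1], "persistent")
})

test_that("forecast superposition flips, keeps or suspends the trend sign", {
  mk <- function(v) matrix(v, 2, 2)
  hN <- new("HurstMap", h = mk(0.8), r2 = mk(0.9), variable = "ndvi")
  hC <- new("HurstMap", h = mk(0.8), r2 = mk(0.9), variable = "cv")
  # current Improving (slope +, cv -), persistent -> continuous improvement
  fc <- forecastDynamics(hN, hC, mk(0.004), mk(-0.001), mk(0.5), mk(1L))
  expect_true(all(fc@transition == 1L))
  expect_true(all(fc@forecastLevel == 1L))
  # anti-persistent trends reverse both signs: Slight (+,+) forecasts
  # Severe (-,-), i.e. continuous degradation; Improving (+,-) forecasts
  # Moderate (-,+), i.e. improvement -> degradation
  hA <- new("HurstMap", h = mk(0.3), r2 = mk(0.9), variable = "ndvi")
  fc2 <- forecastDynamics(hA, hA, mk(0.004), mk(0.001), mk(0.5), mk(3L))
  expect_true(all(fc2@forecastLevel == 5L))
  expect_true(all(fc2@transition == 4L))
  fc2b <- forecastDynamics(hA, hA, mk(0.004), mk(-0.001), mk(0.5), mk(1L))
  expect_true(all(fc2b@forecastLevel == 4L))
  expect_true(all(fc2b@transition == 3L))
  # H exactly 0.5 is unforecastable
  hU <- new("HurstMap", h = mk(0.5), r2 = mk(0.9), variable = "ndvi")
  fc3 <- forecastDynamics(hU, hC, mk(0.004), mk(-0.001), mk(0.5), mk(1L))
  expect_true(all(fc3@transition == 0L))
  expect_true(all(is.na(fc3@forecastLevel)))
  expect_error(forecastDynamics(hN, hC, mk(0.004), matrix(0, 3, 3),
                                mk(0.5), mk(1L)), "alignment")
})

test_that("transition bookkeeping is idempotent", {
  s <- smallScene()
  med <- windowStack(s$ndvi, "median")
  cv <- windowStack(s$ndvi, "cv")
  tmN <- trendMap(med); tmC <- trendMap(cv)
  ndviValue <- colMeans(gridValues(med), dims = 1)
  dm <- degradationMap(tmN, tmC, ndviValue)
  hN <- hurstMap(med); hC <- hurstMap(cv)
  fc <- forecastDynamics(hN, hC, tmN@slope, tmC@slope, ndviValue, dm@level)
  # recompute transitions from the stored forecast levels alone
  deg <- function(l) !is.na(l) & l %in% 3:6
  cur <- deg(fc@currentLevel); fut <- deg(fc@forecastLevel)
  redo <- matrix(NA_integer_, nrow(fc@transition), ncol(fc@transition))
  ok <- !is.na(fc@currentLevel) & !is.na(fc@forecastLevel)
  redo[ok & !cur & !fut] <- 1L; redo[ok & cur & !fut] <- 2L
  redo[ok & !cur & fut] <- 3L; redo[ok & cur & fut] <- 4L
  same <- !is.na(fc@transition) & fc@transition > 0L
  expect_identical(redo[same], fc@transition[same])
})

test_that("hurst maps populate H and fit quality per pixel", {
  set.seed(44)
  vals <- array(rnorm(32 * 4 * 4), c(32, 4, 4))
  g <- gridStack(vals, seq_len(32) + 1987)
  hm <- hurstMap(g)
  expect_true(all(!is.na(hm@h)))
  expect_true(all(hm@h > 0 & hm@h < 1))
  expect_true(all(hm@r2 >= 0 & hm@r2 <= 1, na.rm = TRUE))
})
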