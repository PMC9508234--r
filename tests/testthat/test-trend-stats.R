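test_that("Sen slope matches hand-derived and degenerate cases", {
  expect_equal(senSlope(c(5, 5, 5, 5)), 0)
  expect_equal(senSlope(2 * (1:10)), 2)
  expect_equal(senSlope(c(1, 3, 2, 5), 1:4), 7 / 6)
  expect_true(is.na(senSlope(c(3, NA, NA, NA))))
})

test_that("Mann-Kendall S, Z and p behave per the rank-test definition", {
  expect_equal(mannKendall(1:5)$s, 10)        # n(n-1)/2, all signs +1
  mkc <- mannKendall(rep(4, 6))
  expect_equal(mkc$s, 0)
  expect_equal(mkc$z, 0)
  expect_equal(mannKendall(c(1, 3, 2, 5))$s, 4)
  expect_true(is.na(mannKendall(c(1, 2, 3))$s))
  # p decreases as |z| grows
  p1 <- mannKendall(c(1, 3, 2, 5, 4, 6, 5, 8))$p
  p2 <- mannKendall(1:8)$p
  expect_lt(p2, p1)
})

test_that("Sen slope and S agree with brute-force enumeration", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(5:30, 1)
    x <- rnorm(n)
    if (i %% 3 == 0) x <- round(x)   # introduce ties
    expect_identical(senSlope(x), oracleSenSlope(x))
    expect_identical(mannKendall(x)$s, oracleMkS(x))
  }
})

test_that("trend statistics obey equivariance and monotone invariance", {
  set.seed(7)
  for (i in 1:25) {
    x <- rnorm(12)
    k <- runif(1, 0.5, 3); c0 <- rnorm(1)
    expect_equal(senSlope(k * x + c0), k * senSlope(x))
    expect_identical(mannKendall(exp(x))$s, mannKendall(x)$s)
  }
})

test_that("window CV matches the sample-sd definition and its invariances", {
  w <- matrix(1:9, 3, 3)
  expect_equal(windowCv(w)[2, 2], sqrt(7.5) / 5)
  expect_equal(windowCv(matrix(4, 3, 3))[2, 2], 0)
  expect_equal(windowCv(3 * w)[2, 2], windowCv(w)[2, 2])
  # incomplete windows and non-positive means are nodata
  expect_true(all(is.na(windowCv(w)[c(1, 3), ])))
  neg <- matrix(-1, 3, 3)
  expect_true(is.na(windowCv(neg)[2, 2]))
  withNa <- w; withNa[1, 1] <- NA
  expect_true(is.na(windowCv(withNa)[2, 2]))
})

test_that("window median is the 9-cell median, permutation invariant", {
  w <- matrix(1:9, 3, 3)
  expect_equal(windowMedian(w)[2, 2], 5)
  expect_equal(windowMedian(matrix(2.5, 3, 3))[2, 2], 2.5)
  set.seed(3)
  wp <- matrix(sample(as.vector(w)), 3, 3)
  expect_equal(windowMedian(wp)[2, 2], windowMedian(w)[2, 2])
})

test_that("trend maps recover noiseless linear trends and flip under time reversal", {
  yrs <- 2000:2014
  vals <- array(0, c(15, 4, 5))
  for (y in 1:15) vals[y, , ] <- 0.3 + 0.005 * (y - 1)
  g <- gridStack(vals, yrs)
  tm <- trendMap(g)
  expect_true(all(abs(tm@slope - 0.005) < 1e-12))
  expect_true(all(significantCells(tm)))
  set.seed(9)
  g2 <- gridStack(array(rnorm(15 * 4 * 5), c(15, 4, 5)), yrs)
  rev2 <- gridStack(gridValues(g2)[15:1, , , drop = FALSE], yrs)
  t1 <- trendMap(g2); t2 <- trendMap(rev2)
  expect_equal(t2@slope, -t1@slope)
  expect_equal(t2@sStat, -t1@sStat)
})

test_that("least-squares slope map agrees with lm and handles gaps", {
  set.seed(5)
  vals <- array(rnorm(10 * 3 * 3), c(10, 3, 3))
  vals[c(2, 5), 2, 2] <- NA
  g <- gridStack(vals, 2001:2010)
  sl <- olsSlopeMap(g)
  for (i in 1:3) for (j in 1:3) {
    y <- vals[, i, j]
    expect_equal(sl[i, j],
                 unname(coef(lm(y ~ I(2001:2010)))[2]), tolerance = 1e-10)
  }
})

test_that("correlation maps detect perfect response and degenerate series", {
  set.seed(6)
  p <- array(rnorm(12 * 3 * 3, 400, 30), c(12, 3, 3))
  ndvi <- 2 * p + 1
  gp <- gridStack(p, 2001:2012, "precipitation")
  gn <- gridStack(ndvi, 2001:2012)
  expect_true(all(abs(correlationMap(gn, gp) - 1) < 1e-12))
  const <- gridStack(array(5, c(12, 3, 3)), 2001:2012)
  expect_true(all(is.na(correlationMap(gn, const))))
  expect_error(correlationMap(gn, gridStack(p[1:10, , , drop = FALSE],
                                            2001:2010)), "years")
  # independent stacks: mean r near zero
  a <- gridStack(array(rnorm(20 * 10 * 10), c(20, 10, 10)), 2000:2019)
  b <- gridStack(array(rnorm(20 * 10 * 10), c(20, 10, 10)), 2000:2019)
  expect_lt(abs(mean(correlationMap(a, b))), 3 / sqrt(19 * 100))
})
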