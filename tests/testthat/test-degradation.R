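test_that("degradation truth table covers all sign/threshold combinations", {
  lev <- function(ns, cs, v) classifyDegradation(ns, cs, v)
  # the six defined rows
  expect_equal(lev(0.004, -0.001, 0.5), 1L)   # improving
  expect_equal(lev(0.004, 0.001, 0.15), 2L)   # regrowing
  expect_equal(lev(0.004, 0.001, 0.5), 3L)    # slight
  expect_equal(lev(-0.004, 0.001, 0.5), 4L)   # moderate
  expect_equal(lev(-0.004, -0.001, 0.5), 5L)  # severe
  expect_equal(lev(-0.004, -0.001, 0.15), 6L) # desertification
  # exhaustive: every nonzero sign pair x value side maps to exactly one level
  combos <- expand.grid(ns = c(-1, 1), cs = c(-1, 1), v = c(0.1, 0.5))
  out <- with(combos, classifyDegradation(ns * 0.01, cs * 0.01, v))
  expect_false(anyNA(out))
  expect_setequal(unique(out), 1:6)
  # value rows: only the cv>0/ndvi>0 and cv<0/ndvi<0 rows split on 0.2
  expect_equal(lev(0.01, -0.01, 0.1), lev(0.01, -0.01, 0.9))
  expect_equal(lev(-0.01, 0.01, 0.1), lev(-0.01, 0.01, 0.9))
  # boundary and degenerate handling
  expect_equal(lev(0.004, 0.001, 0.2), 3L)    # 0.2 joins the high branch
  expect_equal(lev(0, 0.001, 0.5), 0L)        # stable
  expect_equal(lev(0.004, 0, 0.5), 0L)
  expect_true(is.na(lev(NA, 1, 0.5)))
})

test_that("degraded and restored levels partition the analysed area", {
  s <- smallScene()
  med <- windowStack(s$ndvi, "median")
  cv <- windowStack(s$ndvi, "cv")
  dm <- degradationMap(trendMap(med), trendMap(cv),
                       colMeans(gridValues(med), dims = 1))
  tab <- summarizeAreas(dm@level, degradationLevels())
  expect_equal(sum(tab$pct), 100, tolerance = 1e-9)
  expect_equal(sum(tab$count), sum(!is.na(dm@level)))
  grp <- degradationLevels()$group
  expect_setequal(degradationLevels()$code[grp == "degradation"], 3:6)
  expect_setequal(degradationLevels()$code[grp == "restoration"], 1:2)
})

test_that("local Moran hot plots flag constructed clusters", {
  set.seed(31)
  n <- 20
  lev <- matrix(3L, n, n)      # everything degraded
  intens <- matrix(rnorm(n * n, 0, 0.5), n, n)
  intens[6:12, 6:12] <- rnorm(49, -4, 0.1)   # a strong low-value block
  dm <- new("DegradationMap", level = lev, ndviSlope = intens,
            cvSlope = intens, ndviValue = matrix(0.5, n, n))
  hp <- hotPlots(dm, intens, nPermutations = 199, alpha = 0.05, seed = 1)
  core <- hp@cluster[8:10, 8:10]
  expect_true(all(core == "LL"))
  # alternating stripes: interior pixels see mostly opposite-valued
  # neighbours, so local Moran's I is negative (HL/LH pattern)
  stripes <- matrix(rep(c(1, -1), length.out = n), n, n)
  hp2 <- hotPlots(dm, stripes, nPermutations = 49, seed = 2)
  expect_true(all(hp2@localI[2:(n - 1), 2:(n - 1)] < 0))
})

test_that("hot plots are calibrated under a shuffled field and refuse tiny inputs", {
  set.seed(77)
  n <- 24
  lev <- matrix(3L, n, n)
  intens <- matrix(rnorm(n * n), n, n)   # spatially unstructured
  dm <- new("DegradationMap", level = lev, ndviSlope = intens,
            cvSlope = intens, ndviValue = matrix(0.5, n, n))
  hp <- hotPlots(dm, intens, nPermutations = 199, alpha = 0.05, seed = 3)
  sigFrac <- mean(hp@cluster != "ns", na.rm = TRUE)
  expect_lt(sigFrac, 0.05 + 3 * sqrt(0.05 * 0.95 / (n * n)))
  tiny <- new("DegradationMap", level = matrix(c(rep(3L, 5), rep(1L, 20)), 5, 5),
              ndviSlope = matrix(0.1, 5, 5), cvSlope = matrix(0.1, 5, 5),
              ndviValue = matrix(0.5, 5, 5))
  expect_error(hotPlots(tiny, matrix(1, 5, 5)), ">= 10 degraded")
})
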