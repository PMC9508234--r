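test_that("ASCII grid stacks round-trip bit-exactly with nodata preserved", {
  set.seed(1)
  vals <- array(rnorm(5 * 6 * 7), c(5, 6, 7))
  vals[2, 3, 4] <- NA
  vals[, 1, 1] <- NA
  g <- gridStack(vals, 2000:2004, "ndvi", origin = c(100, 200),
                 pixelSize = 30)
  dir <- withr::local_tempdir()
  paths <- writeStack(g, file.path(dir, "ndvi_%d.asc"))
  expect_length(paths, 5)
  g2 <- readStack(paths, 2000:2004)
  expect_identical(gridValues(g2), gridValues(g))
  expect_equal(g2@origin, c(100, 200))
  expect_equal(g2@pixelSize, 30)
})

test_that("stack reading validates years and alignment", {
  g <- gridStack(array(1, c(2, 3, 3)), 2000:2001)
  dir <- withr::local_tempdir()
  paths <- writeStack(g, file.path(dir, "a_%d.asc"))
  expect_error(readStack(paths, 2000:2002), "number of")
  # different pixel size -> alignment error
  writeAsc <- grasstrend:::writeAsc
  bad <- file.path(dir, "bad.asc")
  writeAsc(matrix(1, 3, 3), bad, c(0, 0), 2)
  expect_error(readStack(c(paths[1], bad), 2000:2001), "alignment")
  # different shape
  bad2 <- file.path(dir, "bad2.asc")
  writeAsc(matrix(1, 4, 3), bad2, c(0, 0), 1)
  expect_error(readStack(c(paths[1], bad2), 2000:2001), "alignment")
})

test_that("TIFF stacks round-trip values to float precision with metadata", {
  vals <- array(runif(3 * 4 * 4), c(3, 4, 4))
  vals[1, 2, 2] <- NA
  g <- gridStack(vals, 2001:2003, "ndvi", origin = c(5, 5), pixelSize = 30)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "ndvi.tif")
  writeStack(g, p, format = "tiff")
  g2 <- readStack(p, 2001:2003)
  expect_equal(gridValues(g2), gridValues(g), tolerance = 1e-6)
  expect_identical(is.na(gridValues(g2)), is.na(gridValues(g)))
  expect_equal(g2@pixelSize, 30)
  expect_identical(gridYears(g2), 2001:2003)
})

test_that("resampling preserves constants, symmetry and categories", {
  coarse <- gridStack(matrix(7, 4, 4), 2000, pixelSize = 10)
  fine <- gridStack(matrix(0, 40, 40), 2000, pixelSize = 1)
  out <- resampleTo(coarse, fine, "bilinear")
  expect_lt(max(abs(gridValues(out) - 7)), 1e-12)
  # bilinear at the midpoint of 2x2 cell centres [[0,2],[2,4]] is 2
  src <- gridStack(matrix(c(0, 2, 2, 4), 2, 2, byrow = TRUE), 2000,
                   pixelSize = 2)
  tgt <- gridStack(matrix(0, 1, 1), 2000, origin = c(1, 1), pixelSize = 2)
  expect_equal(as.vector(gridValues(resampleTo(src, tgt, "bilinear"))), 2)
  # nearest of a categorical layer yields only original categories
  set.seed(2)
  cats <- matrix(sample(c(1, 2, 5), 36, TRUE), 6, 6)
  cg <- gridStack(cats, 2000, pixelSize = 3)
  fg <- gridStack(matrix(0, 18, 18), 2000, pixelSize = 1)
  out <- resampleTo(cg, fg, "nearest")
  expect_true(all(gridValues(out) %in% c(1, 2, 5)))
  # identity on the same grid
  g <- gridStack(matrix(rnorm(25), 5, 5), 2000)
  expect_equal(gridValues(resampleTo(g, g, "bilinear")), gridValues(g))
  expect_equal(gridValues(resampleTo(g, g, "nearest")), gridValues(g))
})

test_that("resampling rejects disjoint extents and never invents nodata", {
  a <- gridStack(matrix(1, 4, 4), 2000, origin = c(0, 0), pixelSize = 1)
  b <- gridStack(matrix(1, 4, 4), 2000, origin = c(100, 100), pixelSize = 1)
  expect_error(resampleTo(a, b), "disjoint")
  withNa <- matrix(1, 4, 4); withNa[2, 2] <- NA
  src <- gridStack(withNa, 2000, pixelSize = 1)
  out <- resampleTo(src, src, "bilinear")
  # nodata stays confined to cells whose interpolation touches it
  expect_true(is.na(gridValues(out)[1, 2, 2]))
  expect_false(anyNA(gridValues(out)[1, 4, ]))
})

test_that("masking excludes, dilates, and is idempotent", {
  g <- gridStack(array(1, c(2, 5, 5)), 2000:2001)
  allin <- gridMask(matrix(TRUE, 5, 5))
  expect_identical(gridValues(applyMask(g, allin)), gridValues(g))
  m <- matrix(TRUE, 5, 5); m[3, 3] <- FALSE
  out <- applyMask(g, gridMask(m, "road_river"), bufferPixels = 1)
  expect_equal(sum(is.na(gridValues(out))), 2 * 9)
  expect_true(all(is.na(gridValues(out)[, 2:4, 2:4])))
  out2 <- applyMask(out, gridMask(m, "road_river"), bufferPixels = 1)
  expect_identical(gridValues(out2), gridValues(out))
  expect_error(applyMask(g, gridMask(matrix(TRUE, 4, 4))), "shape")
})

test_that("GridStack validity catches malformed objects", {
  expect_error(gridStack(array(1, c(2, 3, 3)), years = c(2001, 2000)),
               "strictly increasing")
  expect_error(gridStack(array(1, c(2, 3, 3)), years = 2000),
               "length")
  expect_silent(validObject(gridStack(matrix(1, 3, 3), 2000)))
})
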