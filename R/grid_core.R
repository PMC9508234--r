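#' Construct a GridStack
#'
#' @param values numeric array `[n_years, n_rows, n_cols]` (a matrix is
#'   accepted for a single-band stack and gains a unit first dimension).
#' @param years integer vector of band years, strictly increasing.
#' @param variable,units variable name and units.
#' @param origin numeric `c(xll, yll)`, lower-left corner.
#' @param pixelSize cell edge length.
#' @param crs CRS code (informational).
#' @return A [GridStack-class] object.
#' @examples
#' g <- gridStack(array(runif(5 * 4 * 6), c(5, 4, 6)), years = 2000:2004)
#' nYears(g)
#' @export
gridStack <- function(values, years, variable = "ndvi", units = "1",
                      origin = c(0, 0), pixelSize = 1, crs = "local") {
  if (is.matrix(values)) values <- array(values, c(1L, dim(values)))
  new("GridStack", values = values, years = as.integer(years),
      variable = variable, units = units, origin = as.numeric(origin),
      pixelSize = as.numeric(pixelSize), crs = crs)
}

#' Construct a Mask
#' @param values logical matrix, `TRUE` = include.
#' @param provenance one of `"grassland"`, `"road_river"`, `"custom"`.
#' @return A [Mask-class] object.
#' @export
gridMask <- function(values, provenance = "custom") {
  storage.mode(values) <- "logical"
  new("Mask", values = values, provenance = provenance)
}

# ---- accessors --------------------------------------------------------------

#' @describeIn gridStack Extract the value array `[year, row, col]`.
#' @param x a `GridStack`.
#' @export
gridValues <- function(x) x@values

#' @describeIn gridStack Band years.
#' @export
gridYears <- function(x) x@years

#' @describeIn gridStack Number of bands (years).
#' @export
nYears <- function(x) dim(x@values)[1L]

#' @describeIn gridStack Spatial dimensions `c(rows, cols)`.
#' @export
gridDim <- function(x) dim(x@values)[2:3]

#' @describeIn gridStack One band as a matrix.
#' @param year a year present in `gridYears(x)`.
#' @export
gridBand <- function(x, year) {
  i <- match(year, x@years)
  if (is.na(i)) stop("year ", year, " not in stack")
  x@values[i, , , drop = TRUE]
}

#' @describeIn gridStack Replace the value array, keeping metadata.
#' @param values replacement array, same dimensions.
#' @export
setGridValues <- function(x, values) {
  stopifnot(identical(dim(values), dim(x@values)))
  x@values <- values
  validObject(x)
  x
}

setMethod("show", "GridStack", function(object) {
  d <- dim(object@values)
  cat(sprintf("GridStack '%s' [%s]: %d years (%d-%d), %d x %d cells\n",
              object@variable, object@units, d[1L],
              min(object@years), max(object@years), d[2L], d[3L]))
  cat(sprintf("  origin (%g, %g), pixel %g, crs %s; %.1f%% nodata\n",
              object@origin[1L], object@origin[2L], object@pixelSize,
              object@crs, 100 * mean(is.na(object@values))))
})

setMethod("show", "TrendMap", function(object) {
  n <- sum(!is.na(object@slope))
  cat(sprintf("TrendMap '%s': %d x %d cells (%d valid), alpha = %g\n",
              object@variable, nrow(object@slope), ncol(object@slope),
              n, object@alpha))
  if (n > 0)
    cat(sprintf("  slope range [%.4g, %.4g], %.1f%% significant\n",
                min(object@slope, na.rm = TRUE), max(object@slope, na.rm = TRUE),
                100 * mean(object@p < object@alpha, na.rm = TRUE)))
})

#' @describeIn trendMap Logical matrix of cells significant at `alpha`.
#' @param x a `TrendMap`.
#' @export
significantCells <- function(x) x@p < x@alpha

sameGrid <- function(a, b, tol = 1e-9) {
  identical(gridDim(a), gridDim(b)) &&
    all(abs(a@origin - b@origin) < tol) &&
    abs(a@pixelSize - b@pixelSize) < tol
}

# ---- ESRI ASCII grid I/O ----------------------------------------------------

writeAsc <- function(mat, path, origin, pixelSize, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(mat)),
    paste("nrows", nrow(mat)),
    paste("xllcorner", format(origin[1L], digits = 17)),
    paste("yllcorner", format(origin[2L], digits = 17)),
    paste("cellsize", format(pixelSize, digits = 17)),
    paste("NODATA_value", format(nodata, digits = 17))
  ), con)
  m <- mat
  m[is.na(m)] <- nodata
  for (r in seq_len(nrow(m)))
    writeLines(paste(sprintf("%.17g", m[r, ]), collapse = " "), con)
  invisible(path)
}

readAsc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  list(values = m, origin = c(hdr$xllcorner, hdr$yllcorner),
       pixelSize = hdr$cellsize)
}

#' Read an annual raster stack from disk
#'
#' Two plain formats are supported: one ESRI ASCII grid (`.asc`) file per
#' year, or a single multiband TIFF (`.tif`/`.tiff`) with a JSON sidecar
#' (`<file>.json`) holding years, origin, pixel size, CRS and the nodata
#' value.  All bands must be co-registered: same shape, origin and cell size.
#'
#' @param paths character vector of `.asc` files (one per year, in year
#'   order) or a single TIFF path.
#' @param years integer vector of band years.
#' @param variable,units,crs metadata for the resulting stack.
#' @return A [GridStack-class].
#' @seealso [writeStack()]
#' @export
readStack <- function(paths, years, variable = "ndvi", units = "1",
                      crs = "local") {
  years <- as.integer(years)
  if (length(paths) == 1L && grepl("\\.tiff?$", paths, ignore.case = TRUE))
    return(readStackTiff(paths, years, variable, units, crs))
  if (length(paths) != length(years))
    stop("number of files (", length(paths), ") != number of years (",
         length(years), ")")
  bands <- lapply(paths, readAsc)
  ref <- bands[[1L]]
  for (b in bands[-1L]) {
    if (!identical(dim(b$values), dim(ref$values)))
      stop("alignment error: band shapes differ")
    if (any(abs(b$origin - ref$origin) > 1e-9) ||
        abs(b$pixelSize - ref$pixelSize) > 1e-9)
      stop("alignment error: band transforms differ")
  }
  d <- dim(ref$values)
  vals <- array(NA_real_, c(length(years), d))
  for (i in seq_along(bands)) vals[i, , ] <- bands[[i]]$values
  gridStack(vals, years, variable, units, ref$origin, ref$pixelSize, crs)
}

readStackTiff <- function(path, years, variable, units, crs) {
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  if (!is.null(meta$years)) years <- as.integer(meta$years)
  if (length(imgs) != length(years))
    stop("number of TIFF bands (", length(imgs), ") != number of years (",
         length(years), ")")
  d <- dim(imgs[[1L]])
  vals <- array(NA_real_, c(length(years), d))
  for (i in seq_along(imgs)) vals[i, , ] <- imgs[[i]]
  vals[is.nan(vals) | vals > 0.95] <- NA
  if (!is.null(meta$range)) {
    lo <- meta$range[1L]; hi <- meta$range[2L]
    vals <- lo + vals / 0.9 * (hi - lo)
  }
  gridStack(vals, years, variable, units,
            origin = if (!is.null(meta$origin)) meta$origin else c(0, 0),
            pixelSize = if (!is.null(meta$pixelSize)) meta$pixelSize else 1,
            crs = if (!is.null(meta$crs)) meta$crs else crs)
}

#' Write an annual raster stack to disk
#'
#' The `.asc` route writes one ESRI ASCII grid per year (full double
#' precision, so a read/write round trip is bit-exact) and returns the file
#' paths.  The TIFF route writes a 32-bit float multiband TIFF plus a JSON
#' sidecar with the grid metadata; float storage quantises values to single
#' precision.
#'
#' @param stack a [GridStack-class].
#' @param path for `format = "asc"` a path template containing `%d` for the
#'   year (e.g. `"ndvi_%d.asc"`) or a directory; for `"tiff"` a `.tif` path.
#' @param format `"asc"` or `"tiff"`.
#' @return Invisibly, the written paths.
#' @export
writeStack <- function(stack, path, format = c("asc", "tiff")) {
  format <- match.arg(format)
  if (format == "tiff") {
    # the tiff writer stores samples in [0, 1]: valid values are scaled
    # into [0, 0.9] (range recorded in the sidecar) and 1.0 marks nodata
    vals <- gridValues(stack)
    lo <- min(vals, na.rm = TRUE); hi <- max(vals, na.rm = TRUE)
    if (hi <= lo) hi <- lo + 1
    imgs <- lapply(seq_len(nYears(stack)), function(i) {
      m <- 0.9 * (vals[i, , , drop = TRUE] - lo) / (hi - lo)
      m[is.na(m)] <- 1
      m
    })
    tiff::writeTIFF(imgs, path, bits.per.sample = 32L)
    jsonlite::write_json(
      list(years = stack@years, origin = stack@origin,
           pixelSize = stack@pixelSize, crs = stack@crs,
           variable = stack@variable, units = stack@units,
           range = c(lo, hi)),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  if (dir.exists(path) || !grepl("%d", path))
    path <- file.path(sub("/$", "", path),
                      paste0(stack@variable, "_%d.asc"))
  out <- character(nYears(stack))
  for (i in seq_len(nYears(stack))) {
    out[i] <- sprintf(path, stack@years[i])
    writeAsc(stack@values[i, , , drop = TRUE], out[i], stack@origin,
             stack@pixelSize)
  }
  invisible(out)
}

# ---- resampling -------------------------------------------------------------

cellCentersX <- function(stack) {
  stack@origin[1L] + (seq_len(gridDim(stack)[2L]) - 0.5) * stack@pixelSize
}
cellCentersY <- function(stack) {
  nr <- gridDim(stack)[1L]
  stack@origin[2L] + (nr - seq_len(nr) + 0.5) * stack@pixelSize
}

#' Resample a stack onto the grid of another stack
#'
#' Nearest-neighbour or bilinear resampling between two regular grids that
#' share a CRS.  Bilinear interpolation never produces values outside the
#' range of the four contributing cells, and never interpolates across
#' nodata: if any contributing cell is nodata the output cell is nodata.
#' Target cells whose centres fall outside the source extent are nodata.
#'
#' @param stack source [GridStack-class].
#' @param target a `GridStack` defining the output grid.
#' @param method `"bilinear"` (continuous fields) or `"nearest"`
#'   (categorical layers and masks).
#' @return A `GridStack` on the target grid.
#' @export
resampleTo <- function(stack, target, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  sx <- cellCentersX(stack); sy <- cellCentersY(stack)
  tx <- cellCentersX(target); ty <- cellCentersY(target)
  if (min(tx) > max(sx) + stack@pixelSize / 2 ||
      max(tx) < min(sx) - stack@pixelSize / 2 ||
      min(ty) > max(sy) + stack@pixelSize / 2 ||
      max(ty) < min(sy) - stack@pixelSize / 2)
    stop("disjoint extents: source and target grids do not overlap")
  nr <- length(ty); nc <- length(tx); ny <- nYears(stack)
  out <- array(NA_real_, c(ny, nr, nc))
  # source rows are north-to-south: sy is decreasing
  if (method == "nearest") {
    ci <- pmin(pmax(round((tx - sx[1L]) / stack@pixelSize) + 1L, 1L), length(sx))
    ri <- pmin(pmax(round((sy[1L] - ty) / stack@pixelSize) + 1L, 1L), length(sy))
    oob_c <- tx < min(sx) - stack@pixelSize / 2 | tx > max(sx) + stack@pixelSize / 2
    oob_r <- ty < min(sy) - stack@pixelSize / 2 | ty > max(sy) + stack@pixelSize / 2
    for (y in seq_len(ny)) {
      band <- stack@values[y, , , drop = TRUE]
      m <- band[ri, ci, drop = FALSE]
      m[oob_r, ] <- NA; m[, oob_c] <- NA
      out[y, , ] <- m
    }
  } else {
    # fractional position in source cell-centre coordinates, clamped to edges
    fx <- (tx - sx[1L]) / stack@pixelSize
    fy <- (sy[1L] - ty) / stack@pixelSize
    oob_c <- fx < -0.5 | fx > length(sx) - 0.5
    oob_r <- fy < -0.5 | fy > length(sy) - 0.5
    fx <- pmin(pmax(fx, 0), length(sx) - 1)
    fy <- pmin(pmax(fy, 0), length(sy) - 1)
    c0 <- pmin(floor(fx) + 1L, length(sx) - 1L); c0 <- pmax(c0, 1L)
    r0 <- pmin(floor(fy) + 1L, length(sy) - 1L); r0 <- pmax(r0, 1L)
    wx <- fx - (c0 - 1L); wy <- fy - (r0 - 1L)
    if (length(sx) == 1L) { c0 <- rep(1L, nc); wx <- rep(0, nc) }
    if (length(sy) == 1L) { r0 <- rep(1L, nr); wy <- rep(0, nr) }
    c1 <- pmin(c0 + 1L, length(sx)); r1 <- pmin(r0 + 1L, length(sy))
    WX <- matrix(wx, nr, nc, byrow = TRUE)
    WY <- matrix(wy, nr, nc)
    for (y in seq_len(ny)) {
      band <- stack@values[y, , , drop = TRUE]
      v00 <- band[r0, c0, drop = FALSE]; v01 <- band[r0, c1, drop = FALSE]
      v10 <- band[r1, c0, drop = FALSE]; v11 <- band[r1, c1, drop = FALSE]
      m <- v00 * (1 - WY) * (1 - WX) + v01 * (1 - WY) * WX +
           v10 * WY * (1 - WX) + v11 * WY * WX
      m[is.na(v00) | is.na(v01) | is.na(v10) | is.na(v11)] <- NA
      m[oob_r, ] <- NA; m[, oob_c] <- NA
      out[y, , ] <- m
    }
  }
  gridStack(out, stack@years, stack@variable, stack@units,
            target@origin, target@pixelSize, target@crs)
}

# ---- masking ----------------------------------------------------------------

dilateExclusion <- function(excl, buffer) {
  if (buffer <= 0L || !any(excl)) return(excl)
  nr <- nrow(excl); nc <- ncol(excl)
  out <- excl
  for (dr in -buffer:buffer) for (dc in -buffer:buffer) {
    if (dr == 0L && dc == 0L) next
    src_r <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    src_c <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    shifted <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr)[seq_len(nr) + dr >= 1L & seq_len(nr) + dr <= nr]
    cs <- seq_len(nc)[seq_len(nc) + dc >= 1L & seq_len(nc) + dc <= nc]
    shifted[rs, cs] <- excl[rs + dr, cs + dc]
    out <- out | shifted
  }
  out
}

#' Apply an include/exclude mask to a stack
#'
#' Cells excluded by the mask become nodata in every band.  The exclusion can
#' be dilated by `bufferPixels` (square structuring element), which is how
#' road/river exclusions are widened before the spatial-heterogeneity step.
#'
#' @param stack a [GridStack-class].
#' @param mask a [Mask-class] with the same spatial shape.
#' @param bufferPixels integer >= 0, dilation radius for the excluded set.
#' @return The masked `GridStack`.
#' @export
applyMask <- function(stack, mask, bufferPixels = 0L) {
  if (!identical(dim(mask@values), gridDim(stack)))
    stop("mask shape ", paste(dim(mask@values), collapse = "x"),
         " does not match stack shape ",
         paste(gridDim(stack), collapse = "x"))
  excl <- dilateExclusion(!mask@values, as.integer(bufferPixels))
  vals <- stack@values
  for (y in seq_len(nYears(stack))) {
    band <- vals[y, , , drop = TRUE]
    band[excl] <- NA_real_
    vals[y, , ] <- band
  }
  setGridValues(stack, vals)
}
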