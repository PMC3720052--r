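## Grid input/output, resolution changes, delta-change downscaling and
## bioclimatic predictor derivation.

#' Read a gridded layer or climate grid
#'
#' Reads a single layer (`readGrid`) or a full monthly climate grid
#' (`readClimateGrid`) from disk. Supported formats: `"ascii_grid"` (ESRI
#' ASCII, single layer only) and `"netcdf"` (CF-style lat/lon). No-data
#' values are mapped to `NA`; for climate grids the mask is restored from the
#' stored categorical layer (cells missing a mask become `"sea"`).
#' GeoTIFF is recognised but not supported by this build and raises an error.
#'
#' @param path file to read.
#' @param format one of `"ascii_grid"`, `"netcdf"`, `"geotiff"`.
#' @param what for NetCDF single-layer reads, the variable name.
#' @return `readGrid`: a [GeoLayer]; `readClimateGrid`: a [ClimateGrid].
#' @export
readGrid <- function(path, format = c("ascii_grid", "netcdf", "geotiff"),
                     what = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  switch(format,
    ascii_grid = .readAsciiGrid(path),
    netcdf = .readNetcdfLayer(path, what),
    geotiff = stop("GeoTIFF input is not supported by this build; ",
                   "use ascii_grid or netcdf"))
}

#' Write a gridded layer or climate grid
#'
#' @param object a [GeoLayer] (`writeGrid`) or [ClimateGrid]
#'   (`writeClimateGrid`).
#' @param path output file.
#' @param format `"ascii_grid"` (single layer) or `"netcdf"`.
#' @param nodata no-data sentinel written for `NA` cells (ASCII only).
#' @param varname NetCDF variable name for single layers.
#' @rdname readGrid
#' @export
writeGrid <- function(object, path, format = c("ascii_grid", "netcdf", "geotiff"),
                      nodata = -9999, varname = "layer") {
  format <- match.arg(format)
  stopifnot(is(object, "GeoLayer"))
  switch(format,
    ascii_grid = .writeAsciiGrid(object, path, nodata),
    netcdf = .writeNetcdfLayer(object, path, varname),
    geotiff = stop("GeoTIFF output is not supported by this build"))
  invisible(path)
}

## ---- ESRI ASCII grid (plain text header + rows north to south) ----------

.readAsciiGrid <- function(path) {
  lines <- readLines(path)
  keys <- c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
            "yllcenter", "cellsize", "nodata_value")
  hdr <- list()
  i <- 1
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2 || !tolower(parts[1]) %in% keys ||
        is.na(suppressWarnings(as.numeric(parts[2]))))
      break
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
    if (i > length(lines)) break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not a valid ESRI ASCII grid: missing header fields")
  if ("xllcenter" %in% names(hdr))
    hdr$xllcorner <- hdr$xllcenter - hdr$cellsize / 2
  if ("yllcenter" %in% names(hdr))
    hdr$yllcorner <- hdr$yllcenter - hdr$cellsize / 2
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else NA
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid body does not match declared dimensions")
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.na(nodata)) m[m == nodata] <- NA
  new("GeoLayer",
      lattice = gridLattice(hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                            hdr$nrows, hdr$ncols),
      values = m)
}

.writeAsciiGrid <- function(layer, path, nodata = -9999) {
  lt <- layer@lattice
  m <- layer@values
  storage.mode(m) <- "double"
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", lt@ncol),
    sprintf("nrows %d", lt@nrow),
    sprintf("xllcorner %.10g", lt@xll),
    sprintf("yllcorner %.10g", lt@yll),
    sprintf("cellsize %.10g", lt@cellsize),
    sprintf("NODATA_value %g", nodata)), con)
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

## ---- NetCDF (CF-style lat/lon via ncdf4) --------------------------------

.ncLatticeDims <- function(lattice) {
  lon <- ncdf4::ncdim_def("lon", "degrees_east", lonCenters(lattice))
  # stored south-to-north per CF convention; matrices are flipped on write
  lat <- ncdf4::ncdim_def("lat", "degrees_north", rev(latCenters(lattice)))
  list(lon = lon, lat = lat)
}

## matrix (row 1 = north) -> nc array [lon, lat(SN)]
.toNc <- function(m) t(m[nrow(m):1, , drop = FALSE])
.fromNc <- function(a) {
  m <- t(a)
  m[nrow(m):1, , drop = FALSE]
}

.latticeFromNc <- function(nc) {
  lonv <- nc$dim$lon$vals
  latv <- nc$dim$lat$vals
  cs <- abs(diff(lonv[1:2]))
  gridLattice(min(lonv) - cs / 2, min(latv) - cs / 2, cs,
              length(latv), length(lonv))
}

.writeNetcdfLayer <- function(layer, path, varname = "layer") {
  dims <- .ncLatticeDims(layer@lattice)
  var <- ncdf4::ncvar_def(varname, "", list(dims$lon, dims$lat),
                          missval = -9999, prec = "double")
  nc <- ncdf4::nc_create(path, var)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, var, .toNc(layer@values))
}

.readNetcdfLayer <- function(path, what = NULL) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (is.null(what)) what <- names(nc$var)[1]
  lattice <- .latticeFromNc(nc)
  vals <- .fromNc(ncdf4::ncvar_get(nc, what, collapse_degen = FALSE)[, , drop = TRUE])
  new("GeoLayer", lattice = lattice, values = vals)
}

#' @rdname readGrid
#' @export
writeClimateGrid <- function(object, path) {
  stopifnot(is(object, "ClimateGrid"))
  lt <- object@lattice
  dims <- .ncLatticeDims(lt)
  month <- ncdf4::ncdim_def("month", "month", 1:12)
  vt <- ncdf4::ncvar_def("temperature", "degC",
                         list(dims$lon, dims$lat, month), missval = -9999,
                         prec = "double")
  vp <- ncdf4::ncvar_def("precipitation", "mm",
                         list(dims$lon, dims$lat, month), missval = -9999,
                         prec = "double")
  vm <- ncdf4::ncvar_def("mask", "category", list(dims$lon, dims$lat),
                         missval = -1, prec = "integer")
  ve <- ncdf4::ncvar_def("ref_elevation", "m", list(dims$lon, dims$lat),
                         missval = -9999, prec = "double")
  nc <- ncdf4::nc_create(path, list(vt, vp, vm, ve))
  on.exit(ncdf4::nc_close(nc))
  tArr <- array(NA_real_, c(lt@ncol, lt@nrow, 12))
  pArr <- tArr
  for (m in 1:12) {
    tArr[, , m] <- .toNc(object@temperature[, , m])
    pArr[, , m] <- .toNc(object@precipitation[, , m])
  }
  ncdf4::ncvar_put(nc, vt, tArr)
  ncdf4::ncvar_put(nc, vp, pArr)
  ncdf4::ncvar_put(nc, vm, .toNc(matrix(match(object@mask, .MASK_LEVELS),
                                        lt@nrow, lt@ncol)))
  ncdf4::ncvar_put(nc, ve, .toNc(object@refElevation))
  ncdf4::ncatt_put(nc, 0, "label", object@label)
  invisible(path)
}

#' @rdname readGrid
#' @export
readClimateGrid <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (!all(c("temperature", "precipitation") %in% names(nc$var)))
    stop("NetCDF file does not contain temperature and precipitation stacks")
  if (nc$dim$month$len != 12)
    stop("climate grid must carry exactly 12 monthly layers, found ",
         nc$dim$month$len)
  lt <- .latticeFromNc(nc)
  d <- c(lt@nrow, lt@ncol)
  tArr <- array(NA_real_, c(d, 12L))
  pArr <- tArr
  rawT <- ncdf4::ncvar_get(nc, "temperature", collapse_degen = FALSE)
  rawP <- ncdf4::ncvar_get(nc, "precipitation", collapse_degen = FALSE)
  for (m in 1:12) {
    tArr[, , m] <- .fromNc(rawT[, , m])
    pArr[, , m] <- .fromNc(rawP[, , m])
  }
  maskIdx <- .fromNc(ncdf4::ncvar_get(nc, "mask", collapse_degen = FALSE)[, , drop = TRUE])
  mask <- matrix(.MASK_LEVELS[ifelse(is.na(maskIdx), 3L, maskIdx)], d[1], d[2])
  elev <- .fromNc(ncdf4::ncvar_get(nc, "ref_elevation", collapse_degen = FALSE)[, , drop = TRUE])
  lab <- ncdf4::ncatt_get(nc, 0, "label")
  new("ClimateGrid", lattice = lt, temperature = tArr, precipitation = pArr,
      mask = mask, refElevation = elev,
      label = if (lab$hasatt) lab$value else "")
}

## ---- resolution changes --------------------------------------------------

.disaggregateMatrix <- function(m, f) {
  m[rep(seq_len(nrow(m)), each = f), rep(seq_len(ncol(m)), each = f),
    drop = FALSE]
}

.aggregateMatrixMean <- function(m, f) {
  if (nrow(m) %% f != 0 || ncol(m) %% f != 0)
    stop("dimensions not divisible by the aggregation factor")
  nr <- nrow(m) %/% f
  nc <- ncol(m) %/% f
  out <- matrix(NA_real_, nr, nc)
  ri <- (seq_len(nrow(m)) - 1L) %/% f + 1L
  ci <- (seq_len(ncol(m)) - 1L) %/% f + 1L
  grp <- ri[row(m)] + (ci[col(m)] - 1L) * nr
  sums <- tapply(as.numeric(m), grp, function(x) {
    x <- x[!is.na(x)]
    if (length(x)) mean(x) else NA_real_
  })
  out[as.integer(names(sums))] <- as.numeric(sums)
  out
}

#' Change the resolution of a layer
#'
#' `disaggregate` replicates each parent cell into `factor^2` children with
#' no interpolation (the conservative default); `aggregate_mean` averages the
#' non-missing children of each block (a block with no data stays missing).
#' Disaggregating and then aggregating with the same factor is the identity.
#'
#' @param layer a [GeoLayer], [ClimateGrid] or plain matrix.
#' @param factor integer resolution factor (>= 1).
#' @param mode `"disaggregate"` or `"aggregate_mean"`.
#' @return object of the same class on the rescaled lattice.
#' @export
changeResolution <- function(layer, factor,
                             mode = c("disaggregate", "aggregate_mean")) {
  mode <- match.arg(mode)
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  if (factor == 1L) return(layer)
  if (is.matrix(layer)) {
    return(if (mode == "disaggregate") .disaggregateMatrix(layer, factor)
           else .aggregateMatrixMean(layer, factor))
  }
  if (is(layer, "ClimateGrid")) return(.changeResolutionClimate(layer, factor, mode))
  stopifnot(is(layer, "GeoLayer"))
  lt <- layer@lattice
  if (mode == "disaggregate") {
    newLt <- gridLattice(lt@xll, lt@yll, lt@cellsize / factor,
                         lt@nrow * factor, lt@ncol * factor)
    new(class(layer), lattice = newLt,
        values = .disaggregateMatrix(layer@values, factor))
  } else {
    if (lt@nrow %% factor != 0 || lt@ncol %% factor != 0)
      stop("dimensions not divisible by the aggregation factor")
    newLt <- gridLattice(lt@xll, lt@yll, lt@cellsize * factor,
                         lt@nrow %/% factor, lt@ncol %/% factor)
    new(class(layer), lattice = newLt,
        values = .aggregateMatrixMean(layer@values, factor))
  }
}

.majorityMask <- function(mask, f) {
  nr <- nrow(mask) %/% f
  nc <- ncol(mask) %/% f
  out <- matrix("sea", nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    blk <- mask[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)]
    tab <- table(factor(blk, levels = .MASK_LEVELS))
    out[i, j] <- .MASK_LEVELS[which.max(tab)]  # ties resolve land > ice > sea
  }
  out
}

.changeResolutionClimate <- function(grid, f, mode) {
  lt <- grid@lattice
  if (mode == "disaggregate") {
    newLt <- gridLattice(lt@xll, lt@yll, lt@cellsize / f,
                         lt@nrow * f, lt@ncol * f)
    dm <- function(m) .disaggregateMatrix(m, f)
  } else {
    if (lt@nrow %% f != 0 || lt@ncol %% f != 0)
      stop("dimensions not divisible by the aggregation factor")
    newLt <- gridLattice(lt@xll, lt@yll, lt@cellsize * f,
                         lt@nrow %/% f, lt@ncol %/% f)
    dm <- function(m) .aggregateMatrixMean(m, f)
  }
  d <- c(newLt@nrow, newLt@ncol)
  tArr <- array(NA_real_, c(d, 12L)); pArr <- tArr
  for (m in 1:12) {
    tArr[, , m] <- dm(grid@temperature[, , m])
    pArr[, , m] <- dm(grid@precipitation[, , m])
  }
  mask <- if (mode == "disaggregate") .disaggregateMatrix(grid@mask, f)
          else .majorityMask(grid@mask, f)
  new("ClimateGrid", lattice = newLt, temperature = tArr,
      precipitation = pArr, mask = mask, refElevation = dm(grid@refElevation),
      label = grid@label)
}

## ---- delta-change (anomaly) downscaling ----------------------------------

## bilinear interpolation of a coarse field (matrix, row 1 = north) to
## arbitrary lat/lon points; query points are clamped to the coarse
## cell-centre hull (constant extension at the margins).
.bilinearAt <- function(coarseLattice, field, lat, lon) {
  xs <- lonCenters(coarseLattice)
  ys <- rev(latCenters(coarseLattice))          # ascending for interp2
  Z <- field[nrow(field):1, , drop = FALSE]     # rows south to north
  lon <- pmin(pmax(lon, min(xs)), max(xs))
  lat <- pmin(pmax(lat, min(ys)), max(ys))
  if (length(xs) == 1 || length(ys) == 1) {
    # degenerate 1-cell axis: constant along that axis
    return(rep(Z[1, 1], length(lat)))
  }
  pracma::interp2(xs, ys, Z, lon, lat, method = "linear")
}

.fineAnomaly <- function(coarseLattice, coarseField, fineLattice) {
  lat <- latCenters(fineLattice)
  lon <- lonCenters(fineLattice)
  pts <- expand.grid(lat = lat, lon = lon)      # column-major matches matrix
  matrix(.bilinearAt(coarseLattice, coarseField, pts$lat, pts$lon),
         fineLattice@nrow, fineLattice@ncol)
}

#' Delta-change downscaling of a coarse climate scenario
#'
#' Applies the anomaly (delta-change) method: per month, the coarse anomaly
#' `scenario - reference` is interpolated bilinearly to the fine lattice and
#' added to the fine baseline temperature; precipitation uses the coarse
#' ratio `scenario / reference`, except where the coarse reference is at or
#' below `minRefPrecip` (0.1 mm), where the anomaly is applied additively to
#' avoid division blow-ups. Output precipitation is floored at zero. When
#' scenario equals reference the fine baseline is returned unchanged.
#'
#' @param coarseReference,coarseScenario [ClimateGrid]s on a shared coarse
#'   lattice.
#' @param fineBaseline [ClimateGrid] whose extent lies within the coarse grid.
#' @param minRefPrecip coarse reference precipitation (mm) at or below which
#'   the precipitation anomaly is treated additively.
#' @return a [ClimateGrid] on the fine lattice.
#' @export
deltaDownscale <- function(coarseReference, coarseScenario, fineBaseline,
                           minRefPrecip = 0.1) {
  stopifnot(is(coarseReference, "ClimateGrid"),
            is(coarseScenario, "ClimateGrid"),
            is(fineBaseline, "ClimateGrid"))
  if (!.sameLattice(coarseReference@lattice, coarseScenario@lattice))
    stop("coarse reference and scenario must share a lattice")
  clt <- coarseReference@lattice
  flt <- fineBaseline@lattice
  tol <- 1e-6
  if (flt@xll < clt@xll - tol || flt@yll < clt@yll - tol ||
      flt@xll + flt@ncol * flt@cellsize > clt@xll + clt@ncol * clt@cellsize + tol ||
      flt@yll + flt@nrow * flt@cellsize > clt@yll + clt@nrow * clt@cellsize + tol)
    stop("fine baseline does not nest within the coarse lattice")
  d <- c(flt@nrow, flt@ncol)
  tArr <- array(NA_real_, c(d, 12L)); pArr <- tArr
  for (m in 1:12) {
    dT <- coarseScenario@temperature[, , m] - coarseReference@temperature[, , m]
    tArr[, , m] <- fineBaseline@temperature[, , m] + .fineAnomaly(clt, dT, flt)
    refP <- coarseReference@precipitation[, , m]
    scnP <- coarseScenario@precipitation[, , m]
    ratio <- ifelse(refP > minRefPrecip, scnP / refP, NA_real_)
    addl <- scnP - refP
    fr <- .fineAnomaly(clt, ratio, flt)
    fa <- .fineAnomaly(clt, addl, flt)
    base <- fineBaseline@precipitation[, , m]
    pArr[, , m] <- pmax(0, ifelse(is.na(fr), base + fa, base * fr))
  }
  new("ClimateGrid", lattice = flt, temperature = tArr, precipitation = pArr,
      mask = fineBaseline@mask, refElevation = fineBaseline@refElevation,
      label = coarseScenario@label)
}

## ---- bioclimatic predictors ----------------------------------------------

#' Derive the three bioclimatic predictors
#'
#' Computes, from 12 monthly layers: the mean temperature of the configured
#' summer months (default June-August), the temperature of the coldest month
#' (minimum over the 12 monthly means), and the annual precipitation sum.
#' Adding a spatially uniform constant to all monthly temperatures shifts
#' both temperature predictors by that constant and leaves precipitation
#' unchanged.
#'
#' @param grid a [ClimateGrid].
#' @param summerMonths integer months defining "summer" (default `6:8`).
#' @return a [BioclimLayers].
#' @export
deriveBioclim <- function(grid, summerMonths = 6:8) {
  stopifnot(is(grid, "ClimateGrid"))
  summerMonths <- as.integer(summerMonths)
  if (length(summerMonths) == 0)
    stop("summer-month set must not be empty")
  if (any(summerMonths < 1 | summerMonths > 12))
    stop("summer months must lie in 1..12")
  summerT <- apply(grid@temperature[, , summerMonths, drop = FALSE],
                   c(1, 2), mean)
  coldestT <- apply(grid@temperature, c(1, 2), min)
  annualP <- apply(grid@precipitation, c(1, 2), sum)
  new("BioclimLayers", lattice = grid@lattice, summerT = summerT,
      coldestT = coldestT, annualP = annualP, mask = grid@mask)
}

#' Extract predictor values at point locations
#'
#' Looks up the three bioclimatic predictors at the grid cells enclosing the
#' given coordinates. Points outside the lattice return `NA` rows.
#'
#' @param bioclim a [BioclimLayers].
#' @param lat,lon coordinates in degrees.
#' @return data frame with columns `summerT`, `coldestT`, `annualP`.
#' @export
extractPredictors <- function(bioclim, lat, lon) {
  lt <- bioclim@lattice
  j <- floor((lon - lt@xll) / lt@cellsize) + 1
  iFromS <- floor((lat - lt@yll) / lt@cellsize) + 1
  i <- lt@nrow - iFromS + 1
  ok <- i >= 1 & i <= lt@nrow & j >= 1 & j <= lt@ncol & !is.na(i) & !is.na(j)
  out <- data.frame(summerT = rep(NA_real_, length(lat)),
                    coldestT = NA_real_, annualP = NA_real_)
  sel <- cbind(i[ok], j[ok])
  out$summerT[ok] <- bioclim@summerT[sel]
  out$coldestT[ok] <- bioclim@coldestT[sel]
  out$annualP[ok] <- bioclim@annualP[sel]
  out
}

#' Map point locations to grid cell indices
#'
#' @param lattice a [GridLattice].
#' @param lat,lon coordinates in degrees.
#' @return integer matrix with columns `row`, `col` (`NA` outside the grid).
#' @export
cellIndexOf <- function(lattice, lat, lon) {
  j <- as.integer(floor((lon - lattice@xll) / lattice@cellsize) + 1)
  iFromS <- as.integer(floor((lat - lattice@yll) / lattice@cellsize) + 1)
  i <- lattice@nrow - iFromS + 1L
  bad <- i < 1L | i > lattice@nrow | j < 1L | j > lattice@ncol
  i[bad] <- NA_integer_; j[bad] <- NA_integer_
  cbind(row = i, col = j)
}
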