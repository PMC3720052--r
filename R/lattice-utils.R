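## Spherical geometry and lattice helpers. All distances on the WGS84
## authalic sphere, R = 6371.0088 km; grid registration is cell-centre,
## row 1 = northernmost.

.EARTH_RADIUS_KM <- 6371.0088

#' Construct a grid lattice
#'
#' @param xll,yll longitude/latitude of the lower-left grid corner (degrees).
#' @param cellsize cell edge length in degrees.
#' @param nrow,ncol grid dimensions.
#' @return a [GridLattice].
#' @export
gridLattice <- function(xll, yll, cellsize, nrow, ncol) {
  new("GridLattice", xll = as.numeric(xll), yll = as.numeric(yll),
      cellsize = as.numeric(cellsize), nrow = as.integer(nrow),
      ncol = as.integer(ncol))
}

#' Lattice accessors
#'
#' `latCenters()`/`lonCenters()` return cell-centre coordinates (row 1 is the
#' northernmost row); `cellSize()` the cell edge in degrees; `gridDims()` the
#' `c(nrow, ncol)` dimensions; `cellAreasKm2()` the per-cell spherical
#' quadrilateral areas.
#'
#' @param lattice a [GridLattice].
#' @return numeric vectors/matrix as described.
#' @export
latCenters <- function(lattice) {
  lattice@yll + (lattice@nrow - seq_len(lattice@nrow) + 0.5) * lattice@cellsize
}

#' @rdname latCenters
#' @export
lonCenters <- function(lattice) {
  lattice@xll + (seq_len(lattice@ncol) - 0.5) * lattice@cellsize
}

#' @rdname latCenters
#' @export
cellSize <- function(lattice) lattice@cellsize

#' @rdname latCenters
#' @export
gridDims <- function(lattice) c(lattice@nrow, lattice@ncol)

#' @rdname latCenters
#' @export
cellAreasKm2 <- function(lattice) {
  cs <- lattice@cellsize
  lat <- latCenters(lattice)
  top <- pmin(lat + cs / 2, 90) * pi / 180
  bot <- pmax(lat - cs / 2, -90) * pi / 180
  rowArea <- .EARTH_RADIUS_KM^2 * (cs * pi / 180) * (sin(top) - sin(bot))
  matrix(rowArea, lattice@nrow, lattice@ncol)
}

## cell-centre coordinate matrix (lon, lat) for a logical selection
.cellCoords <- function(lattice, cells = NULL) {
  lat <- latCenters(lattice)
  lon <- lonCenters(lattice)
  if (is.null(cells)) {
    cbind(lon = rep(lon, each = lattice@nrow),
          lat = rep(lat, times = lattice@ncol))
  } else {
    idx <- which(cells)
    i <- (idx - 1L) %% lattice@nrow + 1L
    j <- (idx - 1L) %/% lattice@nrow + 1L
    cbind(lon = lon[j], lat = lat[i])
  }
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on the authalic sphere (R = 6371.0088 km). Vectorized
#' over record pairs.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees.
#' @return distances in km.
#' @export
haversineKm <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = .EARTH_RADIUS_KM * 1000) / 1000
}

## all-pairs haversine distance matrix (km) between coordinate sets with
## columns (lon, lat)
.haversineCrossKm <- function(a, b) {
  la1 <- a[, "lat"] * pi / 180; lo1 <- a[, "lon"] * pi / 180
  la2 <- b[, "lat"] * pi / 180; lo2 <- b[, "lon"] * pi / 180
  dlat <- outer(la1, la2, "-") / 2
  dlon <- outer(lo1, lo2, "-") / 2
  h <- sin(dlat)^2 + outer(cos(la1), cos(la2)) * sin(dlon)^2
  2 * .EARTH_RADIUS_KM * asin(sqrt(pmin(h, 1)))
}

## Lambert azimuthal equal-area projection (km) anchored at (lat0, lon0);
## used to build equal-area block lattices for thinning and sampling.
.laeaForward <- function(lat, lon, lat0, lon0) {
  R <- .EARTH_RADIUS_KM
  phi <- lat * pi / 180; lam <- lon * pi / 180
  phi0 <- lat0 * pi / 180; lam0 <- lon0 * pi / 180
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  k <- sqrt(2 / denom)
  cbind(x = R * k * cos(phi) * sin(lam - lam0),
        y = R * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0)))
}

.laeaInverse <- function(x, y, lat0, lon0) {
  R <- .EARTH_RADIUS_KM
  phi0 <- lat0 * pi / 180; lam0 <- lon0 * pi / 180
  rho <- sqrt(x^2 + y^2)
  out <- cbind(lat = rep(lat0, length(x)), lon = rep(lon0, length(x)))
  nz <- rho > 0
  if (any(nz)) {
    cc <- 2 * asin(pmin(1, rho[nz] / (2 * R)))
    phi <- asin(cos(cc) * sin(phi0) + y[nz] * sin(cc) * cos(phi0) / rho[nz])
    lam <- lam0 + atan2(x[nz] * sin(cc),
                        rho[nz] * cos(phi0) * cos(cc) - y[nz] * sin(phi0) * sin(cc))
    out[nz, "lat"] <- phi * 180 / pi
    out[nz, "lon"] <- ((lam * 180 / pi + 180) %% 360) - 180
  }
  out
}

## Block index along one projected axis; a point exactly on a block boundary
## is assigned to the lower-index block.
.blockIndex <- function(v, widthKm) as.integer(ceiling(v / widthKm) - 1)

## integer nesting factor of a fine lattice inside a coarse one; errors if
## the lattices do not nest (shared corner, integer cell-size ratio).
.nestingFactor <- function(coarse, fine) {
  f <- coarse@cellsize / fine@cellsize
  if (abs(f - round(f)) > 1e-6)
    stop("fine lattice cell size is not an integer refinement of the coarse one")
  f <- as.integer(round(f))
  tol <- fine@cellsize * 1e-6
  if (abs(coarse@xll - fine@xll) > tol || abs(coarse@yll - fine@yll) > tol)
    stop("lattices do not share a lower-left corner")
  if (fine@nrow != coarse@nrow * f || fine@ncol != coarse@ncol * f)
    stop("fine lattice extent does not match the coarse lattice")
  f
}

.sameLattice <- function(a, b, tol = 1e-9) {
  abs(a@xll - b@xll) < tol && abs(a@yll - b@yll) < tol &&
    abs(a@cellsize - b@cellsize) < tol && a@nrow == b@nrow && a@ncol == b@ncol
}

#' @export
setMethod("show", "GridLattice", function(object) {
  cat(sprintf("GridLattice: %d x %d cells of %g deg, lower-left (%g, %g)\n",
              object@nrow, object@ncol, object@cellsize,
              object@xll, object@yll))
})

#' @export
setMethod("show", "GeoLayer", function(object) {
  v <- object@values
  cat(sprintf("%s on %d x %d lattice (%g deg); range [%g, %g], %d missing\n",
              class(object), nrow(v), ncol(v), object@lattice@cellsize,
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
})

#' @export
setMethod("show", "ClimateGrid", function(object) {
  cat(sprintf(
    "ClimateGrid%s: %d x %d cells of %g deg; %d land, %d ice, %d sea\n",
    if (nzchar(object@label)) paste0(" [", object@label, "]") else "",
    object@lattice@nrow, object@lattice@ncol, object@lattice@cellsize,
    sum(object@mask == "land"), sum(object@mask == "ice"),
    sum(object@mask == "sea")))
  jja <- apply(object@temperature[, , 6:8, drop = FALSE], c(1, 2), mean)
  cat(sprintf("  JJA mean T on land: %.2f degC (mean)\n",
              mean(jja[object@mask == "land"], na.rm = TRUE)))
})

#' @export
setMethod("show", "BioclimLayers", function(object) {
  land <- object@mask == "land"
  cat(sprintf("BioclimLayers on %d x %d lattice; land means: summer %.2f degC, coldest %.2f degC, precip %.0f mm\n",
              object@lattice@nrow, object@lattice@ncol,
              mean(object@summerT[land], na.rm = TRUE),
              mean(object@coldestT[land], na.rm = TRUE),
              mean(object@annualP[land], na.rm = TRUE)))
})

#' @export
setMethod("show", "TreelineSurface", function(object) {
  z <- object@elevation
  cat(sprintf("TreelineSurface%s: %d/%d cells with a treeline; median %g m\n",
              if (nzchar(object@label)) paste0(" [", object@label, "]") else "",
              sum(!is.na(z)), length(z),
              if (any(!is.na(z))) stats::median(z, na.rm = TRUE) else NA))
})

#' @export
setMethod("show", "SuitabilitySeries", function(object) {
  cat(sprintf("SuitabilitySeries for '%s': %d slices (%s)\n",
              object@species, length(object@grids),
              paste(object@labels, collapse = ", ")))
})

#' @export
setMethod("show", "SpreadState", function(object) {
  n <- length(object@occupancy)
  cat(sprintf("SpreadState: %d steps; %d cells initially occupied, %d finally\n",
              n - 1L, sum(object@occupancy[[1]]), sum(object@occupancy[[n]])))
})

#' @export
setMethod("show", "ModelFit", function(object) {
  ev <- object@evaluation
  cat(sprintf("ModelFit [%s]: threshold %.4g; AUC %.3f, TSS %.3f, sensitivity %.3f\n",
              object@algorithm, object@threshold,
              ev["auc"], ev["tss"], ev["sensitivity"]))
})

#' @export
setMethod("show", "EnsembleProjection", function(object) {
  cat(sprintf("EnsembleProjection: majority >= %g; %d cells in majority layer\n",
              object@majority, sum(object@layer, na.rm = TRUE)))
})

#' @export
setMethod("show", "SyntheticWorld", function(object) {
  cat("SyntheticWorld\n  ")
  show(object@climate)
  cat(sprintf("  truth: gradient %g degC/deg lat, lapse %g K/m, amplitude %g degC, noise sd %g, seed %s\n",
              object@truth$gradient, object@truth$lapse,
              object@truth$amplitude, object@truth$noiseSd,
              format(object@truth$seed)))
})

#' @export
setMethod("show", "VirtualSpecies", function(object) {
  cat(sprintf("VirtualSpecies: %d presences, prevalence %.3f, seed %s\n",
              nrow(object@occurrences), object@prevalence,
              format(object@seed)))
})

#' @export
setMethod("show", "OccurrenceSet", function(object) {
  cat(sprintf("OccurrenceSet: %d presences, %d pseudo-absences\n",
              nrow(object@presences), nrow(object@pseudoAbsences)))
})

#' @export
setMethod("show", "AnalogMap", function(object) {
  cat(sprintf("AnalogMap [%s] at breadth %g%%: mean analog area %.2f%% of %.0f km2\n",
              object@direction, object@breadth,
              mean(object@areaPct, na.rm = TRUE), object@referenceAreaKm2))
})

## Simple accessors -------------------------------------------------------

#' Grid content accessors
#'
#' Accessor generics for the gridded classes: `gridValues()` returns the
#' value matrix of a [GeoLayer]; `gridMask()` the land/ice/sea mask;
#' `monthlyTemperature()`/`monthlyPrecipitation()` the 12-layer arrays of a
#' [ClimateGrid]; `treelineElevation()` the treeline matrix; `sliceLabel()`
#' the slice/scenario label.
#'
#' @param object a gridded object.
#' @export
setGeneric("gridValues", function(object) standardGeneric("gridValues"))
#' @rdname gridValues
#' @export
setMethod("gridValues", "GeoLayer", function(object) object@values)

#' @rdname gridValues
#' @export
setGeneric("gridMask", function(object) standardGeneric("gridMask"))
#' @rdname gridValues
#' @export
setMethod("gridMask", "ClimateGrid", function(object) object@mask)
#' @rdname gridValues
#' @export
setMethod("gridMask", "BioclimLayers", function(object) object@mask)

#' @rdname gridValues
#' @export
setGeneric("monthlyTemperature", function(object) standardGeneric("monthlyTemperature"))
#' @rdname gridValues
#' @export
setMethod("monthlyTemperature", "ClimateGrid", function(object) object@temperature)

#' @rdname gridValues
#' @export
setGeneric("monthlyPrecipitation", function(object) standardGeneric("monthlyPrecipitation"))
#' @rdname gridValues
#' @export
setMethod("monthlyPrecipitation", "ClimateGrid", function(object) object@precipitation)

#' @rdname gridValues
#' @export
setGeneric("treelineElevation", function(object) standardGeneric("treelineElevation"))
#' @rdname gridValues
#' @export
setMethod("treelineElevation", "TreelineSurface", function(object) object@elevation)

#' @rdname gridValues
#' @export
setGeneric("sliceLabel", function(object) standardGeneric("sliceLabel"))
#' @rdname gridValues
#' @export
setMethod("sliceLabel", "ClimateGrid", function(object) object@label)

#' @rdname gridValues
#' @export
setGeneric("latticeOf", function(object) standardGeneric("latticeOf"))
#' @rdname gridValues
#' @export
setMethod("latticeOf", "GeoLayer", function(object) object@lattice)
#' @rdname gridValues
#' @export
setMethod("latticeOf", "ClimateGrid", function(object) object@lattice)
#' @rdname gridValues
#' @export
setMethod("latticeOf", "BioclimLayers", function(object) object@lattice)
#' @rdname gridValues
#' @export
setMethod("latticeOf", "TreelineSurface", function(object) object@lattice)
#' @rdname gridValues
#' @export
setMethod("latticeOf", "SuitabilitySeries", function(object) object@lattice)
#' @rdname gridValues
#' @export
setMethod("latticeOf", "SpreadState", function(object) object@lattice)
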