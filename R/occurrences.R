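## Occurrence-record hygiene: coordinate-precision estimation and filtering,
## equal-area block thinning, range-outline presence sampling and
## pseudo-absence sampling.

#' Build an occurrence record table
#'
#' Validates and assembles the standard occurrence data frame used across the
#' package: species id, coordinates in degrees, the number of decimal digits
#' reported for each axis, and the record source.
#'
#' @param species species id (recycled).
#' @param lat,lon coordinates (degrees).
#' @param digitsLat,digitsLon decimal digits of the reported latitude and
#'   longitude (non-negative integers).
#' @param source record source: `"observation"`, `"specimen"`, `"dotmap"` or
#'   `"outline_sample"`.
#' @return data frame with columns `species`, `lat`, `lon`, `digits_lat`,
#'   `digits_lon`, `source`.
#' @export
occurrenceRecords <- function(species, lat, lon, digitsLat, digitsLon,
                              source = "observation") {
  if (any(abs(lat) > 90) || any(abs(lon) > 180))
    stop("coordinates out of range")
  if (any(digitsLat < 0) || any(digitsLon < 0))
    stop("digit counts must be non-negative")
  data.frame(species = species, lat = lat, lon = lon,
             digits_lat = as.integer(digitsLat),
             digits_lon = as.integer(digitsLon), source = source)
}

#' Coordinate precision from reported decimal digits
#'
#' The horizontal precision of a printed coordinate pair is taken as the
#' great-circle (haversine) distance between the reported position and the
#' position displaced by half the last reported digit on both axes jointly,
#' i.e. `(lat + 0.5 * 10^-digitsLat, lon + 0.5 * 10^-digitsLon)`. This is the
#' half-step ambiguity of the printed coordinates at that point on the
#' sphere; it shrinks with more digits and, in its longitude component, with
#' increasing latitude.
#'
#' @param records occurrence data frame (see [occurrenceRecords()]), or
#'   `NULL` to pass coordinates directly.
#' @param lat,lon,digitsLat,digitsLon used when `records` is `NULL`.
#' @return precision in km per record.
#' @export
coordinatePrecision <- function(records = NULL, lat, lon, digitsLat,
                                digitsLon) {
  if (!is.null(records)) {
    lat <- records$lat; lon <- records$lon
    digitsLat <- records$digits_lat; digitsLon <- records$digits_lon
  }
  dLat <- 0.5 * 10^(-digitsLat)
  dLon <- 0.5 * 10^(-digitsLon)
  haversineKm(lat, lon, pmin(lat + dLat, 90), lon + dLon)
}

#' Filter records by coordinate precision
#'
#' Keeps records whose estimated precision is at most `maxKm` (default 8 km,
#' the grain of 5-arc-minute climate data). The number of discarded records
#' is reported as a message and attached as attribute `"discarded"`.
#'
#' @param records occurrence data frame.
#' @param maxKm precision cutoff in km.
#' @return the retained records, with a `precision_km` column added.
#' @export
filterByPrecision <- function(records, maxKm = 8) {
  if (nrow(records) == 0) {
    records$precision_km <- numeric(0)
    attr(records, "discarded") <- 0L
    return(records)
  }
  records$precision_km <- coordinatePrecision(records)
  keep <- records$precision_km <= maxKm
  out <- records[keep, , drop = FALSE]
  attr(out, "discarded") <- sum(!keep)
  message(sum(!keep), " of ", nrow(records),
          " records discarded at the ", maxKm, " km precision cutoff")
  out
}

## assign records to equal-area blocks: project into a Lambert azimuthal
## equal-area plane anchored at the record centroid, then bin into
## blockKm-sized squares (boundary points go to the lower-index block).
.blockIds <- function(lat, lon, blockKm, anchor = NULL) {
  if (is.null(anchor)) anchor <- c(lat = mean(lat), lon = mean(lon))
  xy <- .laeaForward(lat, lon, anchor["lat"], anchor["lon"])
  out <- paste(.blockIndex(xy[, "x"], blockKm), .blockIndex(xy[, "y"], blockKm))
  attr(out, "anchor") <- anchor
  out
}

#' Spatially thin records on an equal-area block lattice
#'
#' Bins records into `blockKm x blockKm` blocks of a local equal-area
#' projection anchored at the record centroid and retains at most
#' `maxPerBlock` records per block by a seeded uniform draw without
#' replacement. Deterministic for a given seed.
#'
#' @param records occurrence data frame.
#' @param blockKm block edge length in km (default 100).
#' @param maxPerBlock maximum records retained per block (default 3).
#' @param seed integer random seed.
#' @return the retained records, in their original order.
#' @export
spatialThin <- function(records, blockKm = 100, maxPerBlock = 3, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(blockKm > 0, maxPerBlock >= 1)
  if (nrow(records) <= 1) return(records)
  ids <- .blockIds(records$lat, records$lon, blockKm)
  set.seed(seed)
  keep <- logical(nrow(records))
  for (b in sort(unique(ids))) {
    idx <- which(ids == b)
    if (length(idx) > maxPerBlock) idx <- sample(idx, maxPerBlock)
    keep[idx] <- TRUE
  }
  out <- records[keep, , drop = FALSE]
  attr(out, "block_anchor") <- attr(ids, "anchor")
  out
}

## even-odd point-in-polygon test via sp; polygon = matrix with columns
## (lon, lat) or projected (x, y)
.inPolygon <- function(px, py, poly) {
  sp::point.in.polygon(px, py, poly[, 1], poly[, 2]) > 0
}

#' Geographically stratified presence sampling within a range outline
#'
#' Samples one presence per occupied `blockKm x blockKm` equal-area block
#' inside the polygon: candidate points are drawn uniformly within each block
#' (in the projected plane) and accepted when they fall inside the outline;
#' blocks whose intersection with the outline is not hit within `maxTries`
#' draws yield no point.
#'
#' @param outline polygon vertex matrix with columns `lon`, `lat` (closed or
#'   open ring).
#' @param blockKm block edge length in km (default 100).
#' @param species species id for the returned records.
#' @param seed integer random seed.
#' @param maxTries rejection-sampling attempts per block.
#' @return occurrence data frame with `source = "outline_sample"`.
#' @export
sampleOutline <- function(outline, blockKm = 100, species = "sp", seed,
                          maxTries = 200) {
  if (missing(seed)) stop("a seed is required")
  outline <- as.matrix(outline)
  if (nrow(outline) < 3 || any(!is.finite(outline)))
    stop("degenerate polygon outline")
  anchor <- c(lat = mean(outline[, 2]), lon = mean(outline[, 1]))
  polyXY <- .laeaForward(outline[, 2], outline[, 1], anchor["lat"],
                         anchor["lon"])
  bx <- range(.blockIndex(polyXY[, "x"], blockKm))
  by <- range(.blockIndex(polyXY[, "y"], blockKm))
  set.seed(seed)
  pts <- NULL
  for (ix in bx[1]:bx[2]) for (iy in by[1]:by[2]) {
    for (k in seq_len(maxTries)) {
      x <- stats::runif(1, ix * blockKm, (ix + 1) * blockKm)
      y <- stats::runif(1, iy * blockKm, (iy + 1) * blockKm)
      if (.inPolygon(x, y, polyXY)) {
        pts <- rbind(pts, c(x, y))
        break
      }
    }
  }
  if (is.null(pts)) {
    return(occurrenceRecords(character(), numeric(), numeric(), integer(),
                             integer(), character()))
  }
  ll <- .laeaInverse(pts[, 1], pts[, 2], anchor["lat"], anchor["lon"])
  occurrenceRecords(species, ll[, "lat"], ll[, "lon"], 6L, 6L,
                    "outline_sample")
}

#' Pseudo-absence sampling outside a range outline
#'
#' Samples one absence per occupied equal-area block among candidate points
#' that lie outside the range outline and inside the allowed continental
#' mask. Candidates are the centres of `TRUE` cells of `continentMask`.
#'
#' @param outline polygon vertex matrix with columns `lon`, `lat`.
#' @param continentMask a [GeoLayer] with logical values (`TRUE` = allowed
#'   land).
#' @param blockKm block edge length in km (default 100).
#' @param species species id for the returned records.
#' @param seed integer random seed.
#' @return occurrence data frame with `source = "pseudo_absence"`.
#' @export
samplePseudoAbsences <- function(outline, continentMask, blockKm = 100,
                                 species = "sp", seed) {
  if (missing(seed)) stop("a seed is required")
  outline <- as.matrix(outline)
  if (nrow(outline) < 3) stop("degenerate polygon outline")
  stopifnot(is(continentMask, "GeoLayer"))
  allowed <- continentMask@values
  allowed[is.na(allowed)] <- FALSE
  coords <- .cellCoords(continentMask@lattice, allowed == TRUE)
  if (nrow(coords) == 0)
    return(occurrenceRecords(character(), numeric(), numeric(), integer(),
                             integer(), character()))
  outside <- !.inPolygon(coords[, "lon"], coords[, "lat"], outline)
  coords <- coords[outside, , drop = FALSE]
  if (nrow(coords) == 0)
    return(occurrenceRecords(character(), numeric(), numeric(), integer(),
                             integer(), character()))
  ids <- .blockIds(coords[, "lat"], coords[, "lon"], blockKm)
  set.seed(seed)
  pick <- vapply(split(seq_len(nrow(coords)), ids), function(idx) {
    if (length(idx) == 1) idx else sample(idx, 1)
  }, integer(1))
  out <- occurrenceRecords(species, coords[pick, "lat"], coords[pick, "lon"],
                           6L, 6L, "pseudo_absence")
  attr(out, "block_anchor") <- attr(ids, "anchor")
  out
}

#' Assemble an occurrence set
#'
#' @param presences,pseudoAbsences occurrence data frames.
#' @param notes provenance notes.
#' @return an [OccurrenceSet].
#' @export
occurrenceSet <- function(presences, pseudoAbsences, notes = character()) {
  new("OccurrenceSet", presences = presences,
      pseudoAbsences = pseudoAbsences, notes = notes)
}
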