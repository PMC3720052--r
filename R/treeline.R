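## Potential-treeline algorithm: monthly-to-daily interpolation, the two
## growing-season criteria, a lapse-rate elevation scan, and below-treeline
## masks on a DEM.

.MONTH_DAYS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

#' Month mid-point days of the fixed 365-day year
#'
#' Cumulative day centre of each month (e.g. 15.5 for January).
#'
#' @return numeric vector of length 12.
#' @export
monthMidpoints <- function() cumsum(.MONTH_DAYS) - .MONTH_DAYS / 2

#' Treeline algorithm parameters
#'
#' Defaults encode the thermal tree-life-form criterion: a growing season of
#' at least `minSeasonDays` days with daily mean temperature at or above
#' `dayThreshold`, whose mean is at least `seasonMeanThreshold`; the
#' elevation scan runs from `zMin` to `zMax` in `zStep` increments using the
#' standard adiabatic lapse rate (0.55 K per 100 m). Equality at either
#' threshold qualifies. `seasonDefinition = "all_days"` counts every
#' qualifying day of the year; `"longest_run"` restricts the season to the
#' longest contiguous run of qualifying days (December wraps to January).
#'
#' @param minSeasonDays minimum season length in days (default 94).
#' @param dayThreshold daily mean temperature threshold, degrees C (default
#'   0.9).
#' @param seasonMeanThreshold required season mean temperature, degrees C
#'   (default 6.4).
#' @param lapseRate K per metre (default 0.0055).
#' @param zMin,zMax,zStep elevation scan range and step in metres
#'   (defaults 0, 2000, 25).
#' @param seasonDefinition `"all_days"` or `"longest_run"`.
#' @return named list of validated parameters.
#' @export
treelineParams <- function(minSeasonDays = 94, dayThreshold = 0.9,
                           seasonMeanThreshold = 6.4, lapseRate = 0.0055,
                           zMin = 0, zMax = 2000, zStep = 25,
                           seasonDefinition = c("all_days", "longest_run")) {
  seasonDefinition <- match.arg(seasonDefinition)
  stopifnot(is.finite(dayThreshold), is.finite(seasonMeanThreshold),
            zStep > 0, zMin <= zMax, minSeasonDays >= 1)
  list(minSeasonDays = minSeasonDays, dayThreshold = dayThreshold,
       seasonMeanThreshold = seasonMeanThreshold, lapseRate = lapseRate,
       zMin = zMin, zMax = zMax, zStep = zStep,
       seasonDefinition = seasonDefinition)
}

#' Daily mean temperatures from monthly means
#'
#' Piecewise-linear interpolation between successive month mid-points on a
#' fixed 365-day year, wrapping December to January. The interpolant passes
#' exactly through each monthly mean at that month's mid-point, and daily
#' values never leave the range of the monthly means.
#'
#' @param monthly 12 finite monthly mean temperatures.
#' @param at days at which to evaluate (default the 365 integer days).
#' @return numeric vector of daily means.
#' @export
monthlyToDaily <- function(monthly, at = seq_len(365)) {
  if (length(monthly) != 12 || any(!is.finite(monthly)))
    stop("monthly series must be 12 finite values")
  mids <- monthMidpoints()
  x <- c(mids[12] - 365, mids, mids[1] + 365)
  y <- c(monthly[12], monthly, monthly[1])
  stats::approx(x, y, xout = at, method = "linear")$y
}

## longest contiguous run of TRUE with wraparound; returns indices
.longestRunIdx <- function(q) {
  n <- length(q)
  if (all(q)) return(seq_len(n))
  if (!any(q)) return(integer())
  qq <- c(q, q)
  r <- rle(qq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values & starts <= n)
  best <- runs[which.max(pmin(r$lengths[runs], n))]
  idx <- seq(starts[best], length.out = min(r$lengths[best], n))
  (idx - 1L) %% n + 1L
}

#' Growing-season statistics of a daily series
#'
#' Under the default season definition the growing season is the set of all
#' days whose mean is at or above the daily threshold; returns its length and
#' its mean temperature (`NA` when no day qualifies).
#'
#' @param daily 365 daily mean temperatures.
#' @param params a [treelineParams()] list.
#' @return named numeric `c(length, mean)`.
#' @export
seasonStats <- function(daily, params = treelineParams()) {
  if (length(daily) != 365) stop("daily series must have 365 values")
  q <- daily >= params$dayThreshold
  idx <- if (params$seasonDefinition == "all_days") which(q)
         else .longestRunIdx(q)
  if (length(idx) == 0) return(c(length = 0, mean = NA_real_))
  c(length = length(idx), mean = mean(daily[idx]))
}

#' Potential treeline elevation for one climate cell
#'
#' Scans elevations `zMin, zMin + zStep, ..., zMax`; at each, the daily
#' series implied by the monthly means is shifted by
#' `-lapseRate * (z - referenceElevation)` and the two growing-season
#' criteria are evaluated. The highest qualifying elevation is returned,
#' `NA` if none qualifies. Thresholds are inclusive ("minimum of",
#' "at least").
#'
#' @param monthly 12 monthly mean temperatures valid at
#'   `referenceElevation`.
#' @param referenceElevation elevation (m) at which the climate applies;
#'   0 reproduces a literal sea-level-datum scan.
#' @param params a [treelineParams()] list.
#' @return treeline elevation in metres, or `NA`.
#' @export
potentialTreeline <- function(monthly, referenceElevation = 0,
                              params = treelineParams()) {
  daily <- monthlyToDaily(monthly)
  zs <- seq(params$zMin, params$zMax, by = params$zStep)
  shifts <- -params$lapseRate * (zs - referenceElevation)
  M <- outer(daily, shifts, "+")          # 365 x n_z
  if (params$seasonDefinition == "all_days") {
    Q <- M >= params$dayThreshold
    n <- colSums(Q)
    sm <- colSums(M * Q) / ifelse(n > 0, n, NA)
    ok <- n >= params$minSeasonDays & !is.na(sm) &
      sm >= params$seasonMeanThreshold
  } else {
    ok <- vapply(seq_along(zs), function(k) {
      s <- seasonStats(M[, k], params)
      s["length"] >= params$minSeasonDays && !is.na(s["mean"]) &&
        s["mean"] >= params$seasonMeanThreshold
    }, logical(1))
  }
  if (!any(ok)) return(NA_real_)
  zs[max(which(ok))]
}

#' Potential-treeline surface over a climate grid
#'
#' Applies [potentialTreeline()] to every land cell. The reference elevation
#' is the grid's `refElevation` layer by default; `reference = "sea_level"`
#' scans absolute elevations from a zero datum instead.
#'
#' @param climate a [ClimateGrid].
#' @param params a [treelineParams()] list.
#' @param reference `"grid"` (use the climate surface's reference elevation)
#'   or `"sea_level"`.
#' @return a [TreelineSurface]; non-land cells are `NA`.
#' @export
treelineSurface <- function(climate, params = treelineParams(),
                            reference = c("grid", "sea_level")) {
  stopifnot(is(climate, "ClimateGrid"))
  reference <- match.arg(reference)
  lt <- climate@lattice
  out <- matrix(NA_real_, lt@nrow, lt@ncol)
  land <- which(climate@mask == "land")
  n <- lt@nrow * lt@ncol
  tFlat <- matrix(climate@temperature, n, 12L)
  refE <- if (reference == "grid") climate@refElevation else
    matrix(0, lt@nrow, lt@ncol)
  for (idx in land)
    out[idx] <- potentialTreeline(tFlat[idx, ], refE[idx], params)
  new("TreelineSurface", lattice = lt, elevation = out,
      params = params, label = climate@label)
}

#' Below-treeline mask on a DEM
#'
#' A DEM cell is below the treeline iff its enclosing climate cell has a
#' treeline, the DEM elevation does not exceed that treeline, and the surface
#' mask classifies the cell as land (ice and sea are excluded). The DEM must
#' nest exactly within the climate lattice. A finer DEM resolves sub-cell
#' valleys and can only find at least as much below-treeline terrain as a
#' coarse DEM built by averaging it.
#'
#' @param surface a [TreelineSurface].
#' @param dem an [ElevationGrid] nesting within the surface lattice.
#' @param surfaceMask land/ice/sea character matrix at either the climate or
#'   the DEM resolution (default: all land).
#' @return a [GeoLayer] of logicals on the DEM lattice.
#' @export
belowTreelineMask <- function(surface, dem, surfaceMask = NULL) {
  stopifnot(is(surface, "TreelineSurface"), is(dem, "ElevationGrid"))
  f <- .nestingFactor(surface@lattice, dem@lattice)
  demLt <- dem@lattice
  tl <- .disaggregateMatrix(surface@elevation, f)
  if (is.null(surfaceMask)) {
    landFine <- matrix(TRUE, demLt@nrow, demLt@ncol)
  } else {
    if (identical(dim(surfaceMask), gridDims(surface@lattice)))
      surfaceMask <- .disaggregateMatrix(surfaceMask, f)
    if (!identical(dim(surfaceMask), gridDims(demLt)))
      stop("surface mask matches neither the climate nor the DEM lattice")
    landFine <- surfaceMask == "land"
  }
  below <- !is.na(tl) & !is.na(dem@values) & dem@values <= tl & landFine
  new("GeoLayer", lattice = demLt, values = below)
}

#' Per-cell agreement count across boolean layers
#'
#' Counts, per cell, how many of the given layers are `TRUE` (e.g. the number
#' of climate models projecting suitable conditions).
#'
#' @param layers list of logical matrices (or [GeoLayer]s) on one lattice.
#' @return integer matrix of counts in `0..length(layers)`.
#' @export
layerAgreement <- function(layers) {
  if (length(layers) == 0) stop("no layers given")
  mats <- lapply(layers, function(l) {
    m <- if (is(l, "GeoLayer")) l@values else l
    stopifnot(is.logical(m) || all(m %in% c(0, 1, NA)))
    m
  })
  d <- dim(mats[[1]])
  for (m in mats) if (!identical(dim(m), d)) stop("layer shapes differ")
  out <- Reduce(`+`, lapply(mats, function(m) {
    m[is.na(m)] <- FALSE
    m * 1L
  }))
  storage.mode(out) <- "integer"
  out
}
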