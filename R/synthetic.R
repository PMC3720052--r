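## Synthetic worlds, warming trajectories and virtual species. These stand in
## for gridded climatologies, circulation-model slices and archived
## occurrence records, with every generating parameter recorded so downstream
## estimates can be checked against known truth.

## smooth a random field with a 3x3 box kernel, `passes` times (reflecting
## edges); keeps the field deterministic for a given input matrix.
.smooth3x3 <- function(m, passes = 3) {
  for (k in seq_len(passes)) {
    padded <- m[c(1, seq_len(nrow(m)), nrow(m)),
                c(1, seq_len(ncol(m)), ncol(m))]
    acc <- matrix(0, nrow(m), ncol(m))
    for (di in 0:2) for (dj in 0:2)
      acc <- acc + padded[di + seq_len(nrow(m)), dj + seq_len(ncol(m))]
    m <- acc / 9
  }
  m
}

#' Generate a synthetic world
#'
#' Builds a [ClimateGrid]/[ElevationGrid] pair with known structure. Monthly
#' temperature follows
#' `T(month, cell) = tBase - gradient * (lat - min lat) - lapse * elevation +
#'  amplitude * cos(2 * pi * (month - 7) / 12) + noise`,
#' so July is the warmest month (Northern Hemisphere convention). The DEM is
#' smoothed random relief scaled to `relief` metres; monthly precipitation is
#' `pBase` with a linear latitudinal trend, floored at zero. Cells above
#' `iceAbove` metres are masked as ice. Regenerating with the same seed
#' reproduces every layer bit-identically.
#'
#' @param nRows,nCols grid dimensions.
#' @param latRange latitudinal span in degrees (southern, northern edge).
#' @param lonStart western grid edge (degrees).
#' @param cellsize cell size in degrees (default spans `latRange` over
#'   `nRows` cells).
#' @param tBase mean annual temperature at the southern edge at sea level
#'   (degrees C); the default 4 gives a subarctic south grading into Arctic
#'   tundra northward.
#' @param gradient latitudinal cooling (degrees C per degree latitude).
#' @param amplitude seasonal half-amplitude (degrees C).
#' @param lapse adiabatic lapse rate (K per metre, default 0.0055).
#' @param relief DEM relief scale (m); 0 gives a flat world at sea level.
#' @param noiseSd cell-level temperature noise standard deviation (degrees C).
#' @param pBase mean monthly precipitation at the southern edge (mm).
#' @param pGradient precipitation trend (mm per degree latitude).
#' @param iceAbove elevation (m) above which cells are masked as ice.
#' @param demFactor integer refinement of the DEM relative to the climate
#'   lattice (1 = same resolution).
#' @param seed integer random seed (required).
#' @return a [SyntheticWorld].
#' @export
makeWorld <- function(nRows = 40, nCols = 40, latRange = c(60, 72),
                      lonStart = -52, cellsize = diff(latRange) / nRows,
                      tBase = 4, gradient = 0.8, amplitude = 12,
                      lapse = 0.0055, relief = 600, noiseSd = 0.3,
                      pBase = 60, pGradient = -1.5, iceAbove = Inf,
                      demFactor = 1L, seed) {
  if (missing(seed)) stop("a seed is required")
  if (nRows < 1 || nCols < 1) stop("grid dimensions must be positive")
  demFactor <- as.integer(demFactor)
  set.seed(seed)
  lt <- gridLattice(lonStart, latRange[1], cellsize, nRows, nCols)
  demLt <- gridLattice(lonStart, latRange[1], cellsize / demFactor,
                       nRows * demFactor, nCols * demFactor)
  demRaw <- matrix(stats::runif(demLt@nrow * demLt@ncol), demLt@nrow)
  demVals <- if (relief > 0) {
    sm <- .smooth3x3(demRaw, passes = 3 + demFactor)
    sm <- sm - min(sm)
    sm / max(max(sm), 1e-12) * relief
  } else matrix(0, demLt@nrow, demLt@ncol)
  dem <- new("ElevationGrid", lattice = demLt, values = demVals)
  # reference elevation of the climate surface = DEM aggregated to the
  # climate lattice
  refElev <- if (demFactor > 1L) .aggregateMatrixMean(demVals, demFactor)
             else demVals
  lat <- matrix(latCenters(lt), nRows, nCols)
  d <- c(nRows, nCols)
  tArr <- array(NA_real_, c(d, 12L))
  pArr <- array(NA_real_, c(d, 12L))
  annualMean <- tBase - gradient * (lat - latRange[1]) - lapse * refElev
  for (m in 1:12) {
    noise <- if (noiseSd > 0) matrix(stats::rnorm(nRows * nCols, 0, noiseSd),
                                     nRows) else 0
    tArr[, , m] <- annualMean + amplitude * cos(2 * pi * (m - 7) / 12) + noise
    pArr[, , m] <- pmax(0, pBase + pGradient * (lat - latRange[1]))
  }
  mask <- matrix("land", nRows, nCols)
  mask[refElev > iceAbove] <- "ice"
  climate <- new("ClimateGrid", lattice = lt, temperature = tArr,
                 precipitation = pArr, mask = mask, refElevation = refElev,
                 label = "baseline")
  new("SyntheticWorld", climate = climate, dem = dem,
      truth = list(tBase = tBase, gradient = gradient, amplitude = amplitude,
                   lapse = lapse, relief = relief, noiseSd = noiseSd,
                   pBase = pBase, pGradient = pGradient, seed = seed))
}

#' Build a warming trajectory of climate slices
#'
#' Applies a uniform temperature offset per time slice to the world's
#' baseline climate, emulating glacial-to-future climate sequences
#' (e.g. 21, 15, 12, 9, 6, 4, 2 kyr ago and future decades). Labels are
#' preserved in each slice's metadata; precipitation is unchanged.
#'
#' @param world a [SyntheticWorld] (or a baseline [ClimateGrid]).
#' @param sliceOffsets named numeric vector of temperature offsets (degrees
#'   C); names become slice labels.
#' @return named list of [ClimateGrid]s, in the given order.
#' @export
makeTrajectory <- function(world, sliceOffsets) {
  base <- if (is(world, "SyntheticWorld")) world@climate else world
  stopifnot(is(base, "ClimateGrid"))
  if (!all(is.finite(sliceOffsets))) stop("offsets must be finite")
  labs <- names(sliceOffsets)
  if (is.null(labs)) labs <- as.character(seq_along(sliceOffsets))
  out <- vector("list", length(sliceOffsets))
  names(out) <- labs
  for (k in seq_along(sliceOffsets)) {
    g <- base
    g@temperature <- base@temperature + sliceOffsets[[k]]
    g@label <- labs[k]
    out[[k]] <- g
  }
  out
}

#' Create a virtual species with a known rectilinear niche
#'
#' Truth-suitable cells are the land cells whose bioclimatic predictors all
#' lie inside `bounds`. Presences are drawn (with replacement) from
#' truth-suitable cells, uniformly or weighted by `biasModel`; each record
#' gets a uniform within-cell jitter (so the undegraded point still lies in
#' its truth-suitable cell) and its coordinates are then rounded to
#' per-record decimal digit counts drawn from `digitModel`, emulating the
#' precision heterogeneity of archive occurrence data.
#'
#' @param world a [SyntheticWorld].
#' @param bounds numeric matrix `2 x p`, rows `lo`/`hi`, columns named after
#'   predictors (`summerT`, `coldestT`, `annualP`); predictors omitted from
#'   `bounds` are unconstrained.
#' @param nPresence number of presence records.
#' @param digitModel either a single integer (all records share that digit
#'   count) or a function `n -> integer vector` of per-record digit counts.
#' @param biasModel optional non-negative weight matrix on the climate
#'   lattice (sampling bias); default uniform.
#' @param species species label.
#' @param summerMonths passed to [deriveBioclim()].
#' @param seed integer random seed (required).
#' @return a [VirtualSpecies].
#' @export
makeVirtualSpecies <- function(world, bounds, nPresence = 200,
                               digitModel = 4L, biasModel = NULL,
                               species = "virtualis", summerMonths = 6:8,
                               seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(is(world, "SyntheticWorld"))
  bio <- deriveBioclim(world@climate, summerMonths)
  lt <- bio@lattice
  vars <- c("summerT", "coldestT", "annualP")
  if (is.null(colnames(bounds)) || !all(colnames(bounds) %in% vars))
    colnames(bounds) <- vars[seq_len(ncol(bounds))]
  if (is.null(rownames(bounds))) rownames(bounds) <- c("lo", "hi")
  vals <- list(summerT = bio@summerT, coldestT = bio@coldestT,
               annualP = bio@annualP)
  suitable <- world@climate@mask == "land"
  for (v in colnames(bounds)) {
    suitable <- suitable & !is.na(vals[[v]]) &
      vals[[v]] >= bounds["lo", v] & vals[[v]] <= bounds["hi", v]
  }
  if (!any(suitable))
    stop("niche bounds overlap no land cell's realized climate")
  prevalence <- sum(suitable) / sum(world@climate@mask == "land")
  set.seed(seed)
  occ <- data.frame(species = character(), lat = numeric(), lon = numeric(),
                    digits_lat = integer(), digits_lon = integer(),
                    source = character(), lat_true = numeric(),
                    lon_true = numeric())
  if (nPresence > 0) {
    idx <- which(suitable)
    w <- if (is.null(biasModel)) rep(1, length(idx)) else {
      stopifnot(identical(dim(biasModel), gridDims(lt)))
      biasModel[idx]
    }
    pick <- sample(idx, nPresence, replace = TRUE, prob = w)
    i <- (pick - 1L) %% lt@nrow + 1L
    j <- (pick - 1L) %/% lt@nrow + 1L
    cs <- lt@cellsize
    latT <- latCenters(lt)[i] + stats::runif(nPresence, -cs / 2, cs / 2) * 0.999
    lonT <- lonCenters(lt)[j] + stats::runif(nPresence, -cs / 2, cs / 2) * 0.999
    digits <- if (is.function(digitModel)) as.integer(digitModel(nPresence))
              else rep(as.integer(digitModel), nPresence)
    occ <- data.frame(species = species, lat = round(latT, digits),
                      lon = round(lonT, digits), digits_lat = digits,
                      digits_lon = digits, source = "observation",
                      lat_true = latT, lon_true = lonT)
  }
  new("VirtualSpecies", bounds = bounds, occurrences = occ,
      truthMask = suitable, prevalence = prevalence, seed = seed)
}
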