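## Range dynamics: suitable-area time series, first-suitable times,
## immigration lags, distance-based colonization/lag/required-rate maps, and
## a seeded cellular-automaton dispersal simulation with decadal steps.

#' Build a suitability series
#'
#' @param lattice the shared [GridLattice].
#' @param labels slice labels.
#' @param times slice times in years before 2000 (positive past, negative
#'   future), strictly decreasing (oldest first).
#' @param grids list of logical suitability matrices.
#' @param species species id.
#' @return a [SuitabilitySeries].
#' @export
suitabilitySeries <- function(lattice, labels, times, grids, species = "") {
  grids <- lapply(grids, function(g) { g[is.na(g)] <- FALSE; g })
  new("SuitabilitySeries", lattice = lattice, labels = as.character(labels),
      times = as.numeric(times), grids = grids, species = species)
}

#' Suitable-cell counts per time slice
#'
#' @param series a [SuitabilitySeries].
#' @return data frame with columns `label`, `time` (years before 2000) and
#'   `count`.
#' @export
suitableCellCounts <- function(series) {
  stopifnot(is(series, "SuitabilitySeries"))
  data.frame(label = series@labels, time = series@times,
             count = vapply(series@grids, sum, numeric(1)))
}

#' First time slice with suitable climate
#'
#' Earliest slice (largest years-before-2000) whose suitable-cell count
#' reaches `minCells`.
#'
#' @param series a [SuitabilitySeries].
#' @param minCells minimum suitable cells (default 1).
#' @return one-row data frame (`label`, `time`, `count`), or zero rows when
#'   no slice ever qualifies.
#' @export
firstSuitableTime <- function(series, minCells = 1) {
  counts <- suitableCellCounts(series)
  hit <- which(counts$count >= minCells)
  counts[hit[1], , drop = FALSE][seq_len(min(1, length(hit))), ]
}

#' Immigration lag from first-suitable and arrival dates
#'
#' Lag in years between the time climate first became suitable in the region
#' and the (pollen-dated) species arrival: `(firstSuitable - arrival) * 1000`
#' with both dates in kyr BP. An arrival predating first suitability is
#' flagged with a warning and returns `NA` (the lag would be negative).
#'
#' @param firstSuitableKyr first-suitable date, kyr BP.
#' @param arrivalKyr pollen-based arrival date, kyr BP.
#' @return lag in years (vectorized).
#' @export
immigrationLag <- function(firstSuitableKyr, arrivalKyr) {
  lag <- (firstSuitableKyr - arrivalKyr) * 1000
  bad <- !is.na(lag) & lag < 0
  if (any(bad)) {
    warning(sum(bad), " record(s) with arrival before first suitability; ",
            "lag set to NA")
    lag[bad] <- NA_real_
  }
  lag
}

#' Distance from every cell to the occupied front
#'
#' `"great_circle"`: haversine distance from each target cell centre to the
#' nearest occupied cell centre. `"land_path"`: length of the shortest
#' 8-neighbour path over non-barrier land cells, with great-circle step
#' lengths (always at least the great-circle distance).
#'
#' @param occupied logical matrix of currently occupied cells (non-empty).
#' @param lattice the [GridLattice].
#' @param target logical matrix of cells to evaluate (default: all cells).
#' @param mode `"great_circle"` or `"land_path"`.
#' @param traversable logical matrix of cells a land path may cross
#'   (required for `"land_path"`; occupied and target cells must be
#'   traversable).
#' @return numeric matrix of distances in km (`NA` outside `target` or when
#'   unreachable).
#' @export
distanceToFront <- function(occupied, lattice, target = NULL,
                            mode = c("great_circle", "land_path"),
                            traversable = NULL) {
  mode <- match.arg(mode)
  if (!any(occupied)) stop("occupied set is empty")
  d <- gridDims(lattice)
  if (is.null(target)) target <- matrix(TRUE, d[1], d[2])
  out <- matrix(NA_real_, d[1], d[2])
  if (!any(target)) return(out)
  if (mode == "great_circle") {
    occXY <- .cellCoords(lattice, occupied)
    tgtXY <- .cellCoords(lattice, target)
    dm <- .haversineCrossKm(tgtXY, occXY)
    out[which(target)] <- apply(dm, 1, min)
  } else {
    if (is.null(traversable)) stop("land_path mode needs a traversable mask")
    out[which(target)] <- .landPathDistance(occupied, target, traversable,
                                            lattice)
  }
  out
}

## shortest-path distances over the 8-neighbour graph of traversable cells
.landPathDistance <- function(occupied, target, traversable, lattice) {
  d <- gridDims(lattice)
  allow <- traversable | occupied   # sources are always reachable from themselves
  idx <- which(allow)
  vid <- matrix(NA_integer_, d[1], d[2])
  vid[idx] <- seq_along(idx)
  lat <- latCenters(lattice); lon <- lonCenters(lattice)
  edges <- NULL; wts <- NULL
  offs <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1))  # undirected: 4 of 8
  i <- (idx - 1L) %% d[1] + 1L
  j <- (idx - 1L) %/% d[1] + 1L
  for (k in seq_len(nrow(offs))) {
    ii <- i + offs[k, 1]; jj <- j + offs[k, 2]
    ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2]
    ok[ok] <- !is.na(vid[cbind(ii[ok], jj[ok])])
    if (!any(ok)) next
    from <- vid[cbind(i[ok], j[ok])]
    to <- vid[cbind(ii[ok], jj[ok])]
    w <- haversineKm(lat[i[ok]], lon[j[ok]], lat[ii[ok]], lon[jj[ok]])
    edges <- c(edges, rbind(from, to))
    wts <- c(wts, w)
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, edges, weight = wts)
  src <- vid[which(occupied)]
  tgtIdx <- which(target)
  tgtV <- vid[tgtIdx]
  res <- rep(NA_real_, length(tgtIdx))
  reach <- !is.na(tgtV)
  if (any(reach)) {
    dm <- igraph::distances(g, v = tgtV[reach], to = src)
    res[reach] <- apply(dm, 1, min)
  }
  res[is.infinite(res)] <- NA_real_
  res
}

#' Distance-based colonization, lag and required-rate maps
#'
#' Given a distance map from the current range front (km), a future suitable
#' mask, a migration rate (km/yr) and a horizon (years):
#' `likelyColonized()` marks the suitable cells whose distance is at most
#' `rate * horizon`; `migrationLagMap()` gives the time (years) to reach each
#' suitable cell at the given rate (`distance / rate`); `requiredRateMap()`
#' the rate (km/yr) needed to reach it within the horizon
#' (`distance / horizon`). The two maps reproduce the distance map exactly
#' when multiplied back by rate and horizon respectively, and
#' `likelyColonized()` is inclusion-monotone in both rate and horizon.
#'
#' @param distanceKm distance map from [distanceToFront()].
#' @param suitable logical matrix of (future) suitable cells.
#' @param rate migration rate, km per year (> 0).
#' @param horizon time horizon in years (> 0).
#' @return `likelyColonized`: logical matrix; the maps: numeric matrices
#'   (`NA` off the suitable mask).
#' @export
likelyColonized <- function(distanceKm, suitable, rate, horizon) {
  stopifnot(rate > 0, horizon > 0)
  suitable & !is.na(distanceKm) & distanceKm <= rate * horizon
}

#' @rdname likelyColonized
#' @export
migrationLagMap <- function(distanceKm, suitable, rate) {
  stopifnot(rate > 0)
  out <- distanceKm / rate
  out[!suitable] <- NA_real_
  out
}

#' @rdname likelyColonized
#' @export
requiredRateMap <- function(distanceKm, suitable, horizon) {
  stopifnot(horizon > 0)
  out <- distanceKm / horizon
  out[!suitable] <- NA_real_
  out
}

#' Species-level range-expansion summary
#'
#' Convenience wrapper: computes the front distance and reports the lag to
#' reach all suitable area (maximum cellwise lag, with the median as a
#' secondary summary), the required rate to reach all suitable area by the
#' horizon (maximum cellwise required rate), and the fraction of suitable
#' area likely colonized.
#'
#' @param current logical matrix, current range.
#' @param suitable logical matrix, future suitable cells.
#' @param lattice the [GridLattice].
#' @param rate migration rate (km/yr).
#' @param horizon horizon (years).
#' @param mode,traversable passed to [distanceToFront()].
#' @return named list of summaries plus the component maps.
#' @export
rangeExpansionSummary <- function(current, suitable, lattice, rate, horizon,
                                  mode = "great_circle", traversable = NULL) {
  dist <- distanceToFront(current, lattice, mode = mode,
                          traversable = traversable)
  lag <- migrationLagMap(dist, suitable, rate)
  rr <- requiredRateMap(dist, suitable, horizon)
  col <- likelyColonized(dist, suitable, rate, horizon)
  list(distanceKm = dist, lagYears = lag, requiredRate = rr,
       colonized = col,
       lagToAllYears = suppressWarnings(max(lag, na.rm = TRUE)),
       lagMedianYears = stats::median(lag, na.rm = TRUE),
       requiredRateToAll = suppressWarnings(max(rr, na.rm = TRUE)),
       colonizedFraction = if (any(suitable)) sum(col) / sum(suitable) else NA)
}

#' Dispersal parameters for the spread simulation
#'
#' @param kernel data frame with columns `distance` (distance class in cell
#'   units, integer) and `prob` (colonization probability per source-target
#'   pair per step, in `[0, 1]`).
#' @param maturity steps a newly colonized cell waits before emitting
#'   propagules (default 0 = immediately).
#' @param stepYears length of one simulation step in years (default 10,
#'   decadal steps).
#' @param seed integer random seed.
#' @return validated parameter list.
#' @export
dispersalParams <- function(kernel, maturity = 0, stepYears = 10, seed) {
  if (missing(seed)) stop("a seed is required")
  if (is.null(kernel) || nrow(kernel) == 0) stop("kernel must not be empty")
  stopifnot(all(c("distance", "prob") %in% names(kernel)),
            all(kernel$prob >= 0 & kernel$prob <= 1),
            all(kernel$distance >= 0), maturity >= 0)
  list(kernel = kernel, maxDistance = max(kernel$distance),
       maturity = maturity, stepYears = stepYears, seed = seed)
}

## offsets within the kernel radius, with per-offset colonization
## probability; distance class = Euclidean cell distance rounded to the
## nearest integer (a radius-1 class covers all 8 neighbours)
.kernelOffsets <- function(kernel) {
  r <- max(kernel$distance)
  if (r < 1) return(NULL)
  off <- expand.grid(di = -r:r, dj = -r:r)
  off <- off[!(off$di == 0 & off$dj == 0), ]
  off$class <- round(sqrt(off$di^2 + off$dj^2))
  off <- off[off$class %in% kernel$distance & off$class >= 1, ]
  off$prob <- kernel$prob[match(off$class, kernel$distance)]
  off
}

#' Cellular-automaton dispersal simulation
#'
#' Seeded stochastic spread over a grid. Each step: (1) occupied cells that
#' are unsuitable this step die, suitable ones persist; (2) every occupied
#' cell at least `maturity` steps old attempts to colonize each empty,
#' suitable, non-barrier cell within the kernel radius, succeeding with the
#' kernel's distance-class probability (independent Bernoulli draws per
#' source-target pair). A cell colonized by any source that step becomes
#' occupied with age 0. Initially occupied cells are treated as mature.
#' Identical seeds replay bit-identically.
#'
#' @param initial logical matrix of initially occupied cells.
#' @param suitability list of logical matrices (one per step), or a single
#'   matrix with `nSteps`.
#' @param params a [dispersalParams()] list.
#' @param lattice the [GridLattice].
#' @param barrier optional logical matrix of impassable cells.
#' @param nSteps number of steps when `suitability` is a single matrix.
#' @return a [SpreadState].
#' @export
simulateSpread <- function(initial, suitability, params, lattice,
                           barrier = NULL, nSteps = NULL) {
  if (is.matrix(suitability)) {
    if (is.null(nSteps)) stop("nSteps needed with static suitability")
    suitability <- rep(list(suitability), nSteps)
  }
  d <- gridDims(lattice)
  stopifnot(identical(dim(initial), d))
  for (s in suitability) if (!identical(dim(s), d))
    stop("suitability grids do not match the lattice")
  if (is.null(barrier)) barrier <- matrix(FALSE, d[1], d[2])
  offs <- .kernelOffsets(params$kernel)
  set.seed(params$seed)
  occ <- initial & !barrier
  age <- matrix(NA_real_, d[1], d[2])
  age[occ] <- params$maturity          # initial occupants are mature
  colStep <- matrix(NA_integer_, d[1], d[2])
  colStep[occ] <- 0L
  history <- vector("list", length(suitability) + 1L)
  history[[1]] <- occ
  for (t in seq_along(suitability)) {
    suit <- suitability[[t]] & !is.na(suitability[[t]])
    died <- occ & !suit
    occ[died] <- FALSE
    age[died] <- NA_real_
    newCol <- matrix(FALSE, d[1], d[2])
    if (!is.null(offs) && any(occ)) {
      sources <- which(occ & age >= params$maturity)
      si <- (sources - 1L) %% d[1] + 1L
      sj <- (sources - 1L) %/% d[1] + 1L
      for (s in seq_along(sources)) {
        ti <- si[s] + offs$di
        tj <- sj[s] + offs$dj
        ok <- ti >= 1 & ti <= d[1] & tj >= 1 & tj <= d[2]
        if (!any(ok)) next
        tIdx <- cbind(ti[ok], tj[ok])
        open <- !occ[tIdx] & !newCol[tIdx] & suit[tIdx] & !barrier[tIdx]
        if (!any(open)) next
        p <- offs$prob[ok][open]
        hit <- stats::runif(length(p)) < p
        if (any(hit)) newCol[tIdx[open, , drop = FALSE][hit, , drop = FALSE]] <- TRUE
      }
    }
    if (any(newCol)) {
      occ[newCol] <- TRUE
      age[newCol] <- 0
      unseen <- newCol & is.na(colStep)
      colStep[unseen] <- t
    }
    age[occ] <- age[occ] + 1
    history[[t + 1L]] <- occ
  }
  new("SpreadState", lattice = lattice, occupancy = history,
      colonizationStep = colStep, params = params)
}

#' Final occupancy of a spread simulation
#'
#' @param state a [SpreadState].
#' @return logical matrix.
#' @export
finalOccupancy <- function(state) state@occupancy[[length(state@occupancy)]]
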