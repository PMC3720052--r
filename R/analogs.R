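## Reciprocal climate-analog mapping between two regions at configurable
## niche breadths: per focal cell, the counterpart area with analogous
## climate and the distance to the nearest analog cell.

## predictor matrices restricted to land cells; returns list(values n x 3,
## cells logical matrix, coords, areas)
.analogCells <- function(bioclim) {
  land <- bioclim@mask == "land" & is.finite(bioclim@summerT) &
    is.finite(bioclim@coldestT) & is.finite(bioclim@annualP)
  list(values = cbind(summerT = bioclim@summerT[land],
                      coldestT = bioclim@coldestT[land],
                      annualP = bioclim@annualP[land]),
       cells = land,
       coords = .cellCoords(bioclim@lattice, land),
       areas = cellAreasKm2(bioclim@lattice)[land])
}

#' Shared domain ranges of the bioclimatic variables
#'
#' The per-variable ranges `R_j = max - min` computed over the land cells of
#' every region in the analysis domain. Analog windows are expressed as
#' fractions of these shared ranges, which makes the analog relation
#' symmetric between regions and nested across breadths.
#'
#' @param ... one or more [BioclimLayers] covering the analysis domain.
#' @return named numeric vector of ranges for `summerT`, `coldestT`,
#'   `annualP`.
#' @export
analogDomainRanges <- function(...) {
  regions <- list(...)
  vals <- do.call(rbind, lapply(regions, function(b) .analogCells(b)$values))
  if (nrow(vals) == 0) stop("no land cells in the analysis domain")
  rng <- apply(vals, 2, function(v) diff(range(v)))
  if (any(rng == 0))
    stop("degenerate (constant) variable over the analysis domain: ",
         paste(names(rng)[rng == 0], collapse = ", "))
  rng
}

#' Analog mask of one focal climate in a counterpart region
#'
#' A counterpart land cell is an analog of the focal climate iff, for every
#' variable `j`, `|v_cell_j - v_focal_j| <= (b/100) * R_j / 2`, a symmetric
#' window of half-width proportional to the niche breadth `b` (percent of
#' the shared domain range). Masks are nested in `b` and the pairwise
#' relation is symmetric; at `b = 100` every cell is an analog.
#'
#' @param focalValues named numeric vector of the focal cell's predictors.
#' @param counterpart a [BioclimLayers].
#' @param breadth niche breadth in percent (0 < b <= 100).
#' @param ranges shared domain ranges from [analogDomainRanges()].
#' @return logical matrix on the counterpart lattice.
#' @export
analogMask <- function(focalValues, counterpart, breadth, ranges) {
  stopifnot(breadth > 0, breadth <= 100)
  cc <- .analogCells(counterpart)
  half <- (breadth / 100) * ranges / 2
  ok <- rep(TRUE, nrow(cc$values))
  for (v in colnames(cc$values))
    ok <- ok & abs(cc$values[, v] - focalValues[[v]]) <= half[[v]]
  out <- matrix(FALSE, counterpart@lattice@nrow, counterpart@lattice@ncol)
  out[cc$cells] <- ok
  out
}

#' Climate-analog area and distance maps
#'
#' For every focal-region land cell, compares its three predictors with every
#' counterpart land cell (exhaustive pairwise comparison) and reports (i) the
#' summed spherical area of the analog counterpart cells as a percentage of
#' `referenceAreaKm2` (default: the counterpart region's ice-free land area)
#' and (ii) the great-circle distance to the nearest analog cell (`NA` when
#' no analog exists).
#'
#' @param focal,counterpart [BioclimLayers] for the two regions.
#' @param breadth niche breadth in percent.
#' @param ranges shared domain ranges; default
#'   `analogDomainRanges(focal, counterpart)`.
#' @param referenceAreaKm2 reference area for the percentage.
#' @param direction label stored in the result.
#' @return an [AnalogMap] on the focal lattice.
#' @export
analogArea <- function(focal, counterpart, breadth, ranges = NULL,
                       referenceAreaKm2 = NULL,
                       direction = "focal->counterpart") {
  stopifnot(is(focal, "BioclimLayers"), is(counterpart, "BioclimLayers"))
  if (is.null(ranges)) ranges <- analogDomainRanges(focal, counterpart)
  fc <- .analogCells(focal)
  cc <- .analogCells(counterpart)
  if (is.null(referenceAreaKm2)) referenceAreaKm2 <- sum(cc$areas)
  lt <- focal@lattice
  areaPct <- matrix(NA_real_, lt@nrow, lt@ncol)
  distKm <- matrix(NA_real_, lt@nrow, lt@ncol)
  half <- (breadth / 100) * ranges / 2
  fIdx <- which(fc$cells)
  for (k in seq_along(fIdx)) {
    ok <- abs(cc$values[, "summerT"] - fc$values[k, "summerT"]) <= half[["summerT"]] &
      abs(cc$values[, "coldestT"] - fc$values[k, "coldestT"]) <= half[["coldestT"]] &
      abs(cc$values[, "annualP"] - fc$values[k, "annualP"]) <= half[["annualP"]]
    areaPct[fIdx[k]] <- 100 * sum(cc$areas[ok]) / referenceAreaKm2
    if (any(ok)) {
      dk <- haversineKm(fc$coords[k, "lat"], fc$coords[k, "lon"],
                        cc$coords[ok, "lat"], cc$coords[ok, "lon"])
      distKm[fIdx[k]] <- min(dk)
    }
  }
  areaPct <- pmin(areaPct, 100)
  new("AnalogMap", lattice = lt, areaPct = areaPct, distanceKm = distKm,
      breadth = breadth, direction = direction,
      referenceAreaKm2 = referenceAreaKm2)
}

#' Reciprocal analog maps at several breadths
#'
#' Convenience wrapper producing, for each requested niche breadth, the
#' focal-to-counterpart analog map (and optionally the reverse direction).
#'
#' @param focal,counterpart [BioclimLayers] for the two regions.
#' @param breadths niche breadths in percent (defaults 5, 25, 50).
#' @param both also compute the counterpart-to-focal direction.
#' @return nested list of [AnalogMap]s, indexed by direction then breadth.
#' @export
climateAnalogs <- function(focal, counterpart, breadths = c(5, 25, 50),
                           both = FALSE) {
  ranges <- analogDomainRanges(focal, counterpart)
  fwd <- lapply(breadths, function(b)
    analogArea(focal, counterpart, b, ranges, direction = "focal->counterpart"))
  names(fwd) <- paste0("b", breadths)
  out <- list(forward = fwd)
  if (both) {
    rev <- lapply(breadths, function(b)
      analogArea(counterpart, focal, b, ranges,
                 direction = "counterpart->focal"))
    names(rev) <- paste0("b", breadths)
    out$reverse <- rev
  }
  out
}
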