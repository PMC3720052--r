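#' @import methods
NULL

#' Regular geographic lattice
#'
#' Describes the footprint of a regular latitude/longitude grid: the
#' lower-left corner of the grid in degrees, the (square) cell size in
#' degrees, and the number of rows and columns. Rows are stored north to
#' south (row 1 is the northernmost), columns west to east, matching the
#' ESRI ASCII grid layout. All cell coordinates are cell centres.
#'
#' @slot xll longitude of the lower-left grid corner (degrees).
#' @slot yll latitude of the lower-left grid corner (degrees).
#' @slot cellsize cell edge length (degrees); cells are square in degrees.
#' @slot nrow,ncol grid dimensions.
#' @exportClass GridLattice
setClass("GridLattice",
  representation(xll = "numeric", yll = "numeric", cellsize = "numeric",
                 nrow = "integer", ncol = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@cellsize) != 1 || !is.finite(object@cellsize) ||
        object@cellsize <= 0)
      msg <- c(msg, "cellsize must be a single positive number")
    if (object@nrow < 1L || object@ncol < 1L)
      msg <- c(msg, "grid must have at least one row and one column")
    if (!is.finite(object@xll) || !is.finite(object@yll))
      msg <- c(msg, "grid corner must be finite")
    if (length(msg)) msg else TRUE
  })

#' Single gridded layer
#'
#' One value per grid cell on a [GridLattice]. Values may be numeric or
#' logical; missing cells are `NA`.
#'
#' @slot lattice a [GridLattice].
#' @slot values matrix of per-cell values, row 1 = northernmost row.
#' @exportClass GeoLayer
setClass("GeoLayer",
  representation(lattice = "GridLattice", values = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@values),
                   c(object@lattice@nrow, object@lattice@ncol)))
      return("values dimensions do not match the lattice")
    if (!(is.numeric(object@values) || is.logical(object@values)))
      return("values must be numeric or logical")
    TRUE
  })

#' Digital elevation model
#'
#' A [GeoLayer] whose values are elevations in metres. May be a finer
#' resolution than an associated climate lattice, in which case the fine
#' lattice must nest exactly (integer refinement factor, shared extent).
#'
#' @exportClass ElevationGrid
setClass("ElevationGrid", contains = "GeoLayer")

.MASK_LEVELS <- c("land", "ice", "sea")

#' Monthly climate grid
#'
#' Twelve monthly mean-temperature layers (degrees C) and twelve monthly
#' precipitation layers (mm) on a shared lattice, together with a surface
#' mask classifying each cell as land, ice or sea, and the reference
#' elevation (m) at which the climate values are valid. Temperature must be
#' finite on every land cell in every month; precipitation is non-negative
#' wherever present. Non-land cells may carry `NA`.
#'
#' @slot lattice a [GridLattice].
#' @slot temperature numeric array `nrow x ncol x 12`, degrees C.
#' @slot precipitation numeric array `nrow x ncol x 12`, mm per month.
#' @slot mask character matrix with entries `"land"`, `"ice"` or `"sea"`.
#' @slot refElevation numeric matrix, metres.
#' @slot label free-form slice/scenario label (e.g. `"9kyrBP"`).
#' @exportClass ClimateGrid
setClass("ClimateGrid",
  representation(lattice = "GridLattice", temperature = "array",
                 precipitation = "array", mask = "matrix",
                 refElevation = "matrix", label = "character"),
  prototype(label = ""),
  validity = function(object) {
    d <- c(object@lattice@nrow, object@lattice@ncol)
    msg <- character()
    if (!identical(dim(object@temperature), c(d, 12L)))
      msg <- c(msg, "temperature must have exactly 12 monthly layers on the lattice")
    if (!identical(dim(object@precipitation), c(d, 12L)))
      msg <- c(msg, "precipitation must have exactly 12 monthly layers on the lattice")
    if (!identical(dim(object@mask), d) || !identical(dim(object@refElevation), d))
      msg <- c(msg, "mask and reference elevation must share the lattice shape")
    if (length(msg)) return(msg)
    if (!all(object@mask %in% .MASK_LEVELS))
      msg <- c(msg, "mask entries must be 'land', 'ice' or 'sea'")
    land <- object@mask == "land"
    if (any(land)) {
      tl <- matrix(object@temperature, prod(d), 12L)[land, , drop = FALSE]
      if (!all(is.finite(tl)))
        msg <- c(msg, "temperature must be finite on all land cells")
    }
    p <- object@precipitation
    if (any(p[!is.na(p)] < 0))
      msg <- c(msg, "precipitation must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Bioclimatic predictor layers
#'
#' The three predictors used throughout: mean summer temperature (degrees C),
#' temperature of the coldest month (degrees C) and annual precipitation sum
#' (mm), each one layer on the source climate lattice. On every land cell the
#' coldest month cannot exceed the summer mean.
#'
#' @slot lattice a [GridLattice].
#' @slot summerT,coldestT numeric matrices, degrees C.
#' @slot annualP numeric matrix, mm per year.
#' @slot mask surface mask carried over from the source [ClimateGrid].
#' @exportClass BioclimLayers
setClass("BioclimLayers",
  representation(lattice = "GridLattice", summerT = "matrix",
                 coldestT = "matrix", annualP = "matrix", mask = "matrix"),
  validity = function(object) {
    d <- c(object@lattice@nrow, object@lattice@ncol)
    for (s in c("summerT", "coldestT", "annualP", "mask"))
      if (!identical(dim(slot(object, s)), d))
        return(sprintf("%s dimensions do not match the lattice", s))
    land <- object@mask == "land"
    ok <- is.finite(object@coldestT) & is.finite(object@summerT) & land
    if (any(object@coldestT[ok] > object@summerT[ok] + 1e-9))
      return("coldest-month temperature exceeds summer mean on a land cell")
    ap <- object@annualP
    if (any(ap[!is.na(ap)] < 0))
      return("annual precipitation must be non-negative")
    TRUE
  })

#' Potential-treeline surface
#'
#' Per-climate-cell potential treeline elevation (m above the scan datum),
#' `NA` where no elevation in the scan qualifies, plus the parameter set
#' used. Elevations are always multiples of the scan step within the scan
#' range.
#'
#' @slot lattice a [GridLattice].
#' @slot elevation numeric matrix of treeline elevations (m), `NA` = absent.
#' @slot params the `treelineParams()` list used.
#' @slot label climate slice / model label.
#' @exportClass TreelineSurface
setClass("TreelineSurface",
  representation(lattice = "GridLattice", elevation = "matrix",
                 params = "list", label = "character"),
  prototype(label = ""),
  validity = function(object) {
    d <- c(object@lattice@nrow, object@lattice@ncol)
    if (!identical(dim(object@elevation), d))
      return("elevation dimensions do not match the lattice")
    z <- object@elevation[!is.na(object@elevation)]
    p <- object@params
    if (length(z) && !is.null(p$zStep)) {
      if (any(z < p$zMin - 1e-9 | z > p$zMax + 1e-9))
        return("treeline elevations outside the scan range")
      if (any(abs((z - p$zMin) %% p$zStep) > 1e-6 &
              abs((z - p$zMin) %% p$zStep - p$zStep) > 1e-6))
        return("treeline elevations are not multiples of the scan step")
    }
    TRUE
  })

#' Time-ordered binary suitability series
#'
#' One binary suitability grid per time slice for one species, at a stated
#' model-agreement level. Times are stored on a single axis of years before
#' 2000 (positive = past, negative = future) and must be strictly ordered
#' from oldest to most recent.
#'
#' @slot lattice a [GridLattice].
#' @slot labels slice labels (e.g. `"9kyrBP"`, `"2100"`).
#' @slot times numeric, years before 2000; strictly decreasing.
#' @slot grids list of logical matrices, one per slice.
#' @slot species species identifier.
#' @exportClass SuitabilitySeries
setClass("SuitabilitySeries",
  representation(lattice = "GridLattice", labels = "character",
                 times = "numeric", grids = "list", species = "character"),
  prototype(species = ""),
  validity = function(object) {
    n <- length(object@grids)
    if (length(object@labels) != n || length(object@times) != n)
      return("labels, times and grids must have equal length")
    if (n > 1 && any(diff(object@times) >= 0))
      return("times must be strictly decreasing (oldest slice first)")
    d <- c(object@lattice@nrow, object@lattice@ncol)
    for (g in object@grids)
      if (!is.logical(g) || !identical(dim(g), d))
        return("every slice grid must be a logical matrix on the shared lattice")
    TRUE
  })

#' Cellular-automaton spread state
#'
#' Occupancy history of a dispersal simulation: one logical occupancy grid
#' per step (element 1 is the initial state), the step index at which each
#' cell was first colonized (0 for initially occupied cells, `NA` for never
#' colonized), and the dispersal parameters used. Occupancy is only ever
#' placed on suitable, non-barrier cells.
#'
#' @slot lattice a [GridLattice].
#' @slot occupancy list of logical matrices, length `steps + 1`.
#' @slot colonizationStep integer matrix of first-colonization step indices.
#' @slot params the `dispersalParams()` list used (kernel, maturity, seed).
#' @exportClass SpreadState
setClass("SpreadState",
  representation(lattice = "GridLattice", occupancy = "list",
                 colonizationStep = "matrix", params = "list"),
  validity = function(object) {
    d <- c(object@lattice@nrow, object@lattice@ncol)
    for (g in object@occupancy)
      if (!is.logical(g) || !identical(dim(g), d))
        return("occupancy grids must be logical matrices on the lattice")
    if (!identical(dim(object@colonizationStep), d))
      return("colonizationStep dimensions do not match the lattice")
    TRUE
  })

#' Fitted suitability model
#'
#' One fitted climatic-niche model: the algorithm identifier, its fitted
#' parameters (envelope bounds, standardized coefficients, or a wrapped
#' learner), the class-balancing weights summary, the TSS-optimal
#' binarization threshold and hold-out evaluation metrics.
#'
#' @slot algorithm one of `"envelope"`, `"glm"`, `"rf"`.
#' @slot fit algorithm-specific fitted parameters.
#' @slot weightSummary total presence/absence weight used in fitting.
#' @slot threshold TSS-optimal score threshold (`NA` until evaluated).
#' @slot evaluation named numeric: `auc`, `tss`, `sensitivity` on hold-out.
#' @exportClass ModelFit
setClass("ModelFit",
  representation(algorithm = "character", fit = "list",
                 weightSummary = "numeric", threshold = "numeric",
                 evaluation = "numeric"),
  prototype(threshold = NA_real_,
            evaluation = c(auc = NA_real_, tss = NA_real_,
                           sensitivity = NA_real_)),
  validity = function(object) {
    ev <- object@evaluation
    if (!all(c("auc", "tss", "sensitivity") %in% names(ev)))
      return("evaluation must carry auc, tss and sensitivity")
    if (!is.na(ev["auc"]) && (ev["auc"] < 0 || ev["auc"] > 1))
      return("AUC must lie in [0, 1]")
    if (!is.na(ev["tss"]) && (ev["tss"] < -1 || ev["tss"] > 1))
      return("TSS must lie in [-1, 1]")
    TRUE
  })

#' Summed model ensemble on a grid
#'
#' Per-cell count of models projecting presence, the majority rule in force
#' (default: at least 3 models), and the derived binary majority layer.
#'
#' @slot lattice a [GridLattice].
#' @slot count integer matrix of model-agreement counts.
#' @slot majority minimum agreeing models for the majority layer.
#' @slot layer logical matrix, `count >= majority`.
#' @slot provenance free-form list (species, slice, scenario).
#' @exportClass EnsembleProjection
setClass("EnsembleProjection",
  representation(lattice = "GridLattice", count = "matrix",
                 majority = "numeric", layer = "matrix",
                 provenance = "list"),
  prototype(provenance = list()),
  validity = function(object) {
    d <- c(object@lattice@nrow, object@lattice@ncol)
    if (!identical(dim(object@count), d) || !identical(dim(object@layer), d))
      return("count and layer must match the lattice")
    if (!is.logical(object@layer))
      return("majority layer must be logical")
    cnt <- object@count[!is.na(object@count)]
    if (any(cnt < 0)) return("counts must be non-negative")
    ok <- !is.na(object@count)
    if (!identical(object@layer[ok], (object@count >= object@majority)[ok]))
      return("majority layer inconsistent with counts")
    TRUE
  })

#' Synthetic world with known truth
#'
#' A generated [ClimateGrid]/[ElevationGrid] pair plus the generating
#' parameters ("truth record"): lapse rate, latitudinal gradient, seasonal
#' amplitude, noise standard deviation and seed. Regenerating with the same
#' seed reproduces all layers bit-identically.
#'
#' @slot climate a [ClimateGrid].
#' @slot dem an [ElevationGrid] (possibly finer than the climate lattice).
#' @slot truth named list of generating parameters.
#' @exportClass SyntheticWorld
setClass("SyntheticWorld",
  representation(climate = "ClimateGrid", dem = "ElevationGrid",
                 truth = "list"))

#' Virtual species with known niche
#'
#' A species whose truth-suitable area is defined by rectilinear bounds on
#' the bioclimatic predictors of a [SyntheticWorld]. Occurrences are drawn
#' from truth-suitable land cells and then coordinate-degraded by rounding
#' to per-record decimal digit counts, emulating heterogeneous archive
#' precision.
#'
#' @slot bounds numeric matrix `2 x p` (rows `lo`, `hi`) over the predictors.
#' @slot occurrences data frame: species, lat, lon, digits_lat, digits_lon,
#'   source, plus the undegraded coordinates (`lat_true`, `lon_true`).
#' @slot truthMask logical matrix of truth-suitable cells.
#' @slot prevalence fraction of land cells that are truth-suitable.
#' @slot seed generator seed.
#' @exportClass VirtualSpecies
setClass("VirtualSpecies",
  representation(bounds = "matrix", occurrences = "data.frame",
                 truthMask = "matrix", prevalence = "numeric",
                 seed = "numeric"),
  validity = function(object) {
    if (nrow(object@bounds) != 2)
      return("bounds must have two rows (lo, hi)")
    if (any(object@bounds["lo", ] > object@bounds["hi", ]))
      return("lower niche bounds exceed upper bounds")
    TRUE
  })

#' Occurrence data for one species
#'
#' Presence records and pseudo-absence records (both as the data frames
#' produced by [occurrenceRecords()]), plus provenance notes. Pseudo-absences
#' are sampled outside the species range outline within an allowed
#' continental mask.
#'
#' @slot presences,pseudoAbsences occurrence data frames.
#' @slot notes provenance notes.
#' @exportClass OccurrenceSet
setClass("OccurrenceSet",
  representation(presences = "data.frame", pseudoAbsences = "data.frame",
                 notes = "character"),
  prototype(notes = character()),
  validity = function(object) {
    for (df in list(object@presences, object@pseudoAbsences)) {
      if (nrow(df) == 0) next
      if (!all(c("lat", "lon") %in% names(df)))
        return("records need lat and lon columns")
      if (any(abs(df$lat) > 90) || any(abs(df$lon) > 180))
        return("coordinates out of range")
    }
    TRUE
  })

#' Climate-analog map
#'
#' For each focal-region cell: the area of the counterpart region with
#' analogous climate (as a percentage of a stated reference area) and the
#' great-circle distance (km) to the nearest analog cell (`NA` when no
#' analog exists).
#'
#' @slot lattice focal-region [GridLattice].
#' @slot areaPct numeric matrix, percent of the reference area.
#' @slot distanceKm numeric matrix, km to nearest analog.
#' @slot breadth niche breadth used (percent of each variable's domain range).
#' @slot direction label, e.g. `"focal->counterpart"`.
#' @slot referenceAreaKm2 the reference area used for the percentage.
#' @exportClass AnalogMap
setClass("AnalogMap",
  representation(lattice = "GridLattice", areaPct = "matrix",
                 distanceKm = "matrix", breadth = "numeric",
                 direction = "character", referenceAreaKm2 = "numeric"),
  validity = function(object) {
    a <- object@areaPct[!is.na(object@areaPct)]
    if (any(a < -1e-9 | a > 100 + 1e-9))
      return("analog area percentages must lie in [0, 100]")
    dk <- object@distanceKm[!is.na(object@distanceKm)]
    if (any(dk < 0)) return("distances must be non-negative")
    if (object@breadth <= 0 || object@breadth > 100)
      return("breadth must lie in (0, 100]")
    TRUE
  })
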