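---
title: "Modelling treelines, climatic niches and migration lags with greenshift"
author: "greenshift authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling treelines, climatic niches and migration lags with greenshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greenshift)
```

## The scientific problem

Warming lets trees and shrubs grow far beyond their current Arctic ranges,
but whether they actually get there is a different question: dispersal
across fragmented, isolated terrain can lag behind the climate by millennia.
greenshift implements the full computational chain needed to study this
disequilibrium on gridded climate data: where the thermal potential for tree
growth lies (a treeline model), where individual species find suitable
climate (an ensemble of niche models), how long it takes them to reach that
area (distance-based lags and a cellular-automaton spread simulation), and
where climatically analogous source and sink regions lie (reciprocal analog
mapping). A synthetic-world generator supplies inputs with known truth so
that every stage can be validated without external data.

## Data model

A `ClimateGrid` holds 12 monthly mean-temperature layers (°C) and 12 monthly
precipitation layers (mm) on a regular latitude/longitude lattice, plus a
land/ice/sea mask and the reference elevation of the climate surface. Grid
registration is cell-centre, row 1 is the northernmost row, and all
distances are computed on the authalic sphere (R = 6371.0088 km). Missing
data propagate as `NA`; an operation on a missing cell yields a missing
result, never zero.

Supported on-disk formats are ESRI ASCII grids (single layers; the
`NODATA_value` sentinel maps to `NA`) and CF-style NetCDF (single layers and
full climate grids). Round-trips through either format reproduce layers and
lattice metadata at full precision.

Three bioclimatic predictors drive all niche computations: mean summer
temperature, temperature of the coldest month, and the annual precipitation
sum. Summer defaults to June–August, the natural choice for boreal and
Arctic Northern Hemisphere study regions; the month set is configurable for
other applications. Adding a uniform constant to all monthly temperatures
shifts both temperature predictors by exactly that constant and leaves
precipitation untouched — a property the tests assert.

### Resolution changes and delta-change downscaling

`changeResolution()` disaggregates by block replication (each parent value
copied into factor² children) and aggregates by the mean of non-missing
children. Replication rather than interpolation is the conservative default
because it introduces no values that were not in the parent grid; the pair
of operations is an exact identity, which would not hold for any smoothing
scheme.

`deltaDownscale()` applies the classic anomaly method: the coarse
scenario-minus-reference difference is interpolated bilinearly (on cell
centres, clamped to the coarse hull at the margins) and added to a fine
baseline. Precipitation uses the scenario/reference ratio instead, because
precipitation anomalies scale multiplicatively; where the coarse reference
is at or below 0.1 mm the anomaly is applied additively to avoid dividing by
near-zero values, and results are floored at 0 mm. When scenario equals
reference the fine baseline is returned unchanged — exactly for temperature,
and exactly for precipitation too, since identical inputs produce an
interpolated ratio of exactly one.

## The treeline model

The potential climatic treeline combines two thermal criteria for the
persistence of tree populations:

1. a growing season of at least **94 days** with a daily mean air
   temperature of at least **0.9 °C**, and
2. a mean air temperature over those days of at least **6.4 °C**.

Daily means are derived from the 12 monthly means by piecewise-linear
interpolation between month mid-points on a fixed 365-day year, December
wrapping to January. The interpolation method is a documented numerical
choice (the criteria's source models do the same in spirit); it passes
exactly through each monthly mean and never leaves the range of the monthly
values. The default growing season is *all* days meeting the daily
threshold, matching the day-counting wording of the criteria; a
`longest_run` option restricts the season to the longest contiguous run
(with wraparound) for users who prefer the contiguous convention.

The elevation scan shifts the daily series by a constant adiabatic lapse
rate of **0.55 K per 100 m** across elevations 0–2000 m in 25 m steps and
keeps the highest qualifying elevation. Equality counts as qualifying at
every threshold ("minimum of", "at least"). Two reference conventions are
provided: by default the climate surface is valid at the grid's reference
elevation (the DEM aggregated to the climate lattice), so the scan is
anchored there; a `sea_level` mode reproduces the literal 0–2000 m absolute
scan. The scan is monotone by construction — if elevation *z* qualifies,
every lower scanned elevation does — and warming can only raise treelines,
two properties the test suite asserts on random profiles and random worlds.

`belowTreelineMask()` transfers the treeline to a DEM that nests exactly in
the climate lattice: a DEM cell is below the treeline when its enclosing
climate cell has one, its elevation does not exceed it, and the surface mask
is land. A finer DEM resolves sub-cell valleys and therefore never finds
less below-treeline terrain than the coarse DEM built by averaging it.

## Occurrence hygiene

Archive occurrence records carry heterogeneous coordinate precision. The
package estimates a record's precision as the great-circle distance between
the reported position and the position displaced by half of the last
reported decimal digit on both axes jointly — the half-step ambiguity of the
printed coordinates at that latitude. A per-axis maximum would be a
defensible alternative; the joint displacement is the stricter, documented
choice. Records are kept when this precision is at most 8 km, the grain of
5-arc-minute climate data.

Spatial thinning reduces sampling bias by retaining at most three records
(configurable) per 100 × 100 km block of a Lambert azimuthal equal-area
plane anchored at the record centroid, by a seeded uniform draw. Points on a
block boundary are assigned to the lower-index block. Range outlines are
sampled at one presence per occupied block (rejection sampling inside the
polygon), and pseudo-absences at one per block among allowed-land cell
centres outside the outline. All sampling is seeded and replays exactly.

## The niche ensemble

Suitability models plug into a single interface; two are implemented in the
package and one wraps an external learner:

* **envelope** — the rectilinear climate envelope: per predictor the
  `[q, 1-q]` quantile interval of presence values (default q = 0.05, the
  envelope convention; q = 0 gives the literal min–max box). The continuous
  score is the fraction of predictors inside their interval.
* **glm** — binomial logistic regression on internally standardized
  predictors, maximised by iterative reweighting, with presences and
  pseudo-absences weighted so both classes contribute equal total weight.
  Complete separation raises a warning and falls back to a lightly ridged
  penalized fit; collinear (aliased) predictors drop out with a zero
  coefficient.
* **rf** — a probability random forest with the same case weights, standing
  in for the machine-learning members of a larger ensemble.

Evaluation follows an 80/20 calibration/validation split (resplit when a
partition lacks a class), reporting the weighted rank AUC, the TSS
(sensitivity + specificity − 1) at the TSS-optimal threshold, and
sensitivity. The TSS-optimal threshold is chosen from the mid-points between
adjacent distinct calibration scores plus the extremes, with ties resolved
to the lowest threshold and the prediction rule `score >= threshold`; a
degenerate all-equal score set yields TSS 0 with a warning. Projections are
binarized at that threshold, restricted to land (and optionally a region
mask), and combined into summed ensembles: a cell counts as suitable when at
least three models agree (the default majority for a five-model ensemble;
for the three-model ensemble used in the examples the majority is two).
Richness stacks count suitable species per cell, and difference maps
subtract current from future stacks.

## Range dynamics

Binary suitability grids across time slices form a `SuitabilitySeries` on a
single time axis of years before 2000 (positive past, negative future).
`firstSuitableTime()` returns the earliest slice reaching a minimum
suitable-cell count, and `immigrationLag()` converts the gap between first
suitability and a pollen-dated arrival into years, flagging (with `NA` and a
warning) arrivals that predate suitability.

The distance-based machinery measures, for every cell, the distance to the
nearest occupied cell — either as the great-circle distance (the default,
"simple" convention) or as the shortest 8-neighbour path over traversable
land cells with great-circle step lengths, which respects barriers such as
ice and sea. From the distance map follow three products, linked by exact
identities: likely colonized area (suitable cells within rate × horizon),
migration-lag maps (distance / rate) and required-rate maps
(distance / horizon). Species-level summaries report the lag to reach *all*
suitable area (the maximum cellwise lag; the median is also reported since
pooling conventions differ) and the required rate to reach it by the
horizon.

The cellular-automaton simulator advances occupancy in decadal steps. Each
step, occupied cells that lost suitability die; every occupied cell at least
`maturity` steps old then attempts to colonize each empty, suitable,
non-barrier cell within the kernel radius, succeeding independently with
the kernel's distance-class probability. Distance classes are Euclidean
cell distances rounded to integers, so a radius-1 class covers all eight
neighbours and a probability-1 radius-1 kernel advances exactly one
8-neighbour ring per step — which is why the simulator is testable against
an independent breadth-first-search oracle. Suitability is held constant
within each decadal step (no interpolation between slices). All draws come
from a single seeded stream in a fixed cell order, so identical seeds replay
bit-identically.

## Climate analogs

Two regions are compared through the same three predictors. Variables are
put on a common footing by the shared domain ranges `R_j` (max − min over
the land cells of the analysis domain); a counterpart cell is an analog of a
focal cell when every variable differs by at most `(b/100) · R_j / 2`, where
`b` is the niche breadth in percent (defaults 5, 25 and 50, spanning narrow
to wide climatic tolerances). This symmetric window makes the analog
relation symmetric between regions and nested across breadths, so analog
areas grow and analog distances shrink monotonically with `b`. Note the
window's half-width at `b = 100` is half the domain range: a focal cell at
one extreme of the domain is then analogous to everything within the range
centred on it, not to the opposite extreme. Per focal cell the package
reports the summed spherical area of analog counterpart cells as a
percentage of a reference area (by default the counterpart's ice-free land
area) and the great-circle distance to the nearest analog (`NA` when none
exists). The comparison is the exhaustive O(n·m) pairwise sweep; at package
problem sizes no indexing shortcut is warranted, and any such shortcut would
be contractually required to return identical results.

## The synthetic world

`makeWorld()` generates the study conditions. Monthly temperature is a sum
of interpretable terms — a base level (default 4 °C mean annual temperature
at the southern edge, a subarctic coast grading into Arctic tundra
northward), a latitudinal gradient (0.8 °C per degree), an elevational lapse
(0.55 K per 100 m on smoothed random relief scaled to 600 m), a seasonal
cosine with July warmest (half-amplitude 12 °C) and optional cell-level
noise (sd 0.3 °C). Precipitation is a monotone latitudinal trend (60 mm per
month at the south, −1.5 mm per degree), floored at zero. Every parameter is
recorded in the returned truth record, and the configured lapse is
recoverable from the generated layers by regression to within 2 %.
`makeTrajectory()` applies uniform temperature offsets per labelled time
slice, emulating glacial-to-future sequences; `makeVirtualSpecies()` draws
presences from a known rectilinear climatic niche and degrades their
coordinates to per-record decimal digit counts, emulating archive precision
heterogeneity, with an optional multiplicative sampling-bias surface.

What the generator deliberately does **not** emulate: circulation physics,
spatially structured precipitation, ice-sheet dynamics (masks are static),
foehn winds, soils, disturbance and biotic interactions. Green tests
therefore demonstrate that the algorithms implement their contracts on data
with known structure — not that the models capture every process shaping
real Arctic vegetation.

## Numerical choices and problem sizes

Thresholds are inclusive everywhere. Treeline elevations are scanned on the
exact 25 m lattice, so outputs are always multiples of the step. TSS
threshold ties resolve to the lowest candidate. The envelope's binary rule
requires all predictors in bounds; its continuous score is deliberately
coarse (k/p for p predictors). Block-boundary points belong to the
lower-index block. The test suite exercises the pipeline at deliberately
small sizes — worlds of 4×4 to 25×25 cells, a 50×50 automaton grid, 200
random treeline cells against a brute-force day-by-day oracle, 1000 random
TSS instances against exhaustive search — chosen so the whole suite runs in
well under a minute per file while still probing every contract at the
scale its statement names.

## Known limitations

* GeoTIFF I/O is not provided; use ESRI ASCII or NetCDF.
* The weighted logistic model is linear in the predictors; a box-shaped
  niche is not linearly separable, which is precisely why the ensemble
  majority, not any single model, is the unit of inference.
* The automaton implements a reduced dispersal model: independent
  per-pair Bernoulli colonization with distance classes, no long-distance
  dispersal events, no propagule-pressure accumulation, no demography or
  competition.
* Analog windows are per-variable rectilinear; a multivariate-distance
  window is a noted alternative that was not implemented.
* Past and future projections inherit whatever biases the baseline and the
  offsets carry; within-step constancy of suitability slightly quantizes
  spread timing.
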