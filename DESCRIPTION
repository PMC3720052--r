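Package: greenshift
Title: Treeline, Climatic Niche and Migration-Lag Modelling for Arctic Trees and Shrubs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects potential thermal treelines, climatically suitable areas,
    postglacial and future migration lags, and climate-analog source/sink
    regions for Arctic and boreal woody species. Provides a gridded monthly
    climate data model with ESRI ASCII and NetCDF input/output, delta-change
    downscaling and bioclimatic predictor derivation; occurrence-record
    hygiene (coordinate-precision filtering, equal-area spatial thinning,
    range-outline presence and pseudo-absence sampling); a growing-season
    treeline algorithm with an elevational lapse-rate scan; an ensemble
    climatic-niche framework (rectilinear envelope, weighted logistic
    regression and pluggable learners) with TSS-optimal binarization and
    majority ensembles; a cellular-automaton dispersal simulator with
    distance-based migration-lag and required-rate maps; and reciprocal
    climate-analog mapping at configurable niche breadths. Includes a
    synthetic-world generator so the full pipeline is testable end to end
    against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    geosphere,
    ncdf4,
    sp,
    pracma,
    igraph,
    ranger,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
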