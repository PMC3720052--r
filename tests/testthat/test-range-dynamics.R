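test_that("first suitable time and cell counts read the series correctly", {
  lt <- gridLattice(-50, 60, 0.5, 4, 4)
  g <- function(n) {
    m <- matrix(FALSE, 4, 4)
    if (n > 0) m[seq_len(n)] <- TRUE
    m
  }
  ser <- suitabilitySeries(lt, c("21kyrBP", "15kyrBP", "9kyrBP", "4kyrBP"),
                           c(21000, 15000, 9000, 4000),
                           list(g(0), g(0), g(4), g(12)), species = "betula")
  counts <- suitableCellCounts(ser)
  expect_equal(counts$count, c(0, 0, 4, 12))
  expect_equal(firstSuitableTime(ser)$label, "9kyrBP")
  expect_equal(firstSuitableTime(ser)$time, 9000)
  expect_equal(firstSuitableTime(ser, minCells = 10)$label, "4kyrBP")

  empty <- suitabilitySeries(lt, c("a", "b"), c(2000, 1000),
                             list(g(0), g(0)))
  expect_equal(nrow(firstSuitableTime(empty)), 0)

  # counts are invariant under relabelling
  ser2 <- suitabilitySeries(lt, c("s1", "s2", "s3", "s4"),
                            c(21000, 15000, 9000, 4000),
                            list(g(0), g(0), g(4), g(12)))
  expect_equal(suitableCellCounts(ser2)$count, counts$count)

  # times must be strictly ordered oldest-first
  expect_error(suitabilitySeries(lt, c("a", "b"), c(1000, 2000),
                                 list(g(1), g(1))), "strictly decreasing")
})

test_that("immigration lags are the suitability-to-arrival gap in years", {
  expect_equal(immigrationLag(9, 4), 5000)
  expect_equal(immigrationLag(4, 4), 0)
  expect_equal(immigrationLag(15, 2), 13000)
  expect_warning(bad <- immigrationLag(4, 9), "arrival before first suitability")
  expect_true(is.na(bad))
  expect_equal(suppressWarnings(immigrationLag(c(9, 4), c(4, 9))),
               c(5000, NA))
})

test_that("front distances match the haversine oracle and metric ordering", {
  lt <- gridLattice(0, -0.25, 0.5, 1, 3)   # one equatorial row
  occ <- matrix(c(TRUE, FALSE, FALSE), 1)
  d <- distanceToFront(occ, lt)
  expect_equal(d[1, 1], 0)
  expect_equal(d[1, 2], oracleHaversineKm(0, 0.25, 0, 0.75), tolerance = 1e-9)
  expect_equal(round(d[1, 2], 1), 55.6)
  expect_error(distanceToFront(matrix(FALSE, 1, 3), lt), "empty")

  # land paths are never shorter than great-circle distances, and detours
  # around a barrier are strictly longer
  lt2 <- gridLattice(0, 50, 0.5, 7, 7)
  occ2 <- matrix(FALSE, 7, 7); occ2[4, 1] <- TRUE
  gc <- distanceToFront(occ2, lt2)
  trav <- matrix(TRUE, 7, 7)
  lp <- distanceToFront(occ2, lt2, mode = "land_path", traversable = trav)
  expect_true(all(lp - gc > -1e-9, na.rm = TRUE))
  trav[2:6, 4] <- FALSE               # wall with gaps at the edges
  lpBar <- distanceToFront(occ2, lt2, mode = "land_path", traversable = trav)
  expect_gt(lpBar[4, 7], lp[4, 7])
  expect_true(all(is.na(lpBar[2:6, 4])))
})

test_that("lag and required-rate maps reproduce the distance map exactly", {
  lt <- gridLattice(0, 55, 0.5, 10, 10)
  occ <- matrix(FALSE, 10, 10); occ[5, 5] <- TRUE
  suit <- matrix(TRUE, 10, 10); suit[1, ] <- FALSE
  dist <- distanceToFront(occ, lt)
  rate <- 0.25; horizon <- 90
  lag <- migrationLagMap(dist, suit, rate)
  rr <- requiredRateMap(dist, suit, horizon)
  expect_equal((lag * rate)[suit], dist[suit])
  expect_equal((rr * horizon)[suit], dist[suit])
  expect_true(all(is.na(lag[!suit])))

  # headline arithmetic: 500 km at 0.25 km/yr is a 2000-year lag;
  # 900 km over 90 years needs 10 km/yr
  expect_equal(migrationLagMap(matrix(500), matrix(TRUE), 0.25)[1, 1], 2000)
  expect_equal(requiredRateMap(matrix(900), matrix(TRUE), 90)[1, 1], 10)
})

test_that("likely-colonized area saturates and is monotone in rate and horizon", {
  lt <- gridLattice(0, 55, 0.5, 10, 10)
  occ <- matrix(FALSE, 10, 10); occ[5, 5] <- TRUE
  suit <- matrix(TRUE, 10, 10)
  dist <- distanceToFront(occ, lt)

  big <- likelyColonized(dist, suit, rate = 100, horizon = 100)
  expect_identical(big, suit)        # rate x horizon >= max distance

  prev <- matrix(FALSE, 10, 10)
  for (rate in c(0.1, 0.5, 2, 10)) {
    cur <- likelyColonized(dist, suit, rate, horizon = 50)
    expect_true(all(cur[prev]))
    prev <- cur
  }
  prev <- matrix(FALSE, 10, 10)
  for (h in c(10, 50, 200, 1000)) {
    cur <- likelyColonized(dist, suit, rate = 0.5, horizon = h)
    expect_true(all(cur[prev]))
    prev <- cur
  }

  sumy <- rangeExpansionSummary(occ, suit, lt, rate = 0.5, horizon = 90)
  expect_equal(sumy$lagToAllYears, max(dist) / 0.5)
  expect_equal(sumy$requiredRateToAll, max(dist) / 90)
  expect_true(sumy$colonizedFraction > 0 && sumy$colonizedFraction < 1)
})

test_that("the deterministic spread front equals the BFS ball every step", {
  lt <- gridLattice(0, 50, 0.2, 50, 50)
  set.seed(9)
  suit <- matrix(runif(2500) < 0.7, 50, 50)
  init <- matrix(FALSE, 50, 50)
  init[25, 25] <- TRUE; init[10, 40] <- TRUE
  suit[init] <- TRUE
  dp <- dispersalParams(data.frame(distance = 1, prob = 1), seed = 2)
  st <- simulateSpread(init, suit, dp, lt, nSteps = 12)
  for (t in 0:12) {
    expect_identical(st@occupancy[[t + 1]],
                     oracleBfsBall(init, suit, t))
  }
})

test_that("spread honours suitability, barriers and no-dispersal limits", {
  lt <- gridLattice(0, 50, 0.5, 8, 8)
  init <- matrix(FALSE, 8, 8); init[4, 4] <- TRUE
  # max distance 0: final occupancy = initial cells suitable at every step
  dp0 <- dispersalParams(data.frame(distance = 0, prob = 1), seed = 1)
  suits <- list(matrix(TRUE, 8, 8), matrix(TRUE, 8, 8))
  st0 <- simulateSpread(init, suits, dp0, lt)
  expect_identical(finalOccupancy(st0), init)

  # all suitability lost at step 1: immediate extinction
  dp <- dispersalParams(data.frame(distance = 1, prob = 1), seed = 1)
  stx <- simulateSpread(init, matrix(FALSE, 8, 8), dp, lt, nSteps = 1)
  expect_false(any(finalOccupancy(stx)))

  # barrier cells are never occupied; never-suitable cells neither
  barrier <- matrix(FALSE, 8, 8); barrier[, 6] <- TRUE
  suit <- matrix(TRUE, 8, 8); suit[1, ] <- FALSE
  stb <- simulateSpread(init, suit, dp, lt, barrier = barrier, nSteps = 10)
  for (g in stb@occupancy) {
    expect_false(any(g & barrier))
    expect_false(any(g & !suit))
  }
  # the full-height wall cannot be crossed by a radius-1 kernel
  expect_false(any(finalOccupancy(stb)[, 7:8]))

  # colonization steps are recorded once and increase outward
  cs <- stb@colonizationStep
  expect_equal(cs[4, 4], 0L)
  expect_true(all(is.na(cs[, 7:8])))
  expect_equal(cs[4, 5], 1L)
})

test_that("stochastic spread replays bit-identically under a fixed seed", {
  lt <- gridLattice(0, 50, 0.5, 12, 12)
  init <- matrix(FALSE, 12, 12); init[6, 6] <- TRUE
  kern <- data.frame(distance = c(1, 2), prob = c(0.6, 0.15))
  dp <- dispersalParams(kern, maturity = 1, seed = 77)
  a <- simulateSpread(init, matrix(TRUE, 12, 12), dp, lt, nSteps = 8)
  b <- simulateSpread(init, matrix(TRUE, 12, 12), dp, lt, nSteps = 8)
  expect_identical(a@occupancy, b@occupancy)
  expect_identical(a@colonizationStep, b@colonizationStep)
  dp2 <- dispersalParams(kern, maturity = 1, seed = 78)
  c <- simulateSpread(init, matrix(TRUE, 12, 12), dp2, lt, nSteps = 8)
  expect_false(identical(a@occupancy, c@occupancy))

  # occupancy only grows under static full suitability
  for (t in seq_len(8))
    expect_true(all(a@occupancy[[t + 1]][a@occupancy[[t]]]))

  expect_error(dispersalParams(data.frame(distance = 1, prob = 1.2),
                               seed = 1))
  expect_error(dispersalParams(NULL, seed = 1), "empty")
})
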