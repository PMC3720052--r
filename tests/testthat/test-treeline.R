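test_that("monthly-to-daily interpolation anchors at month mid-points", {
  expect_equal(monthlyToDaily(rep(5, 12)), rep(5, 365))

  m <- c(-10, -8, -4, 0, 4, 8, 10, 9, 5, 0, -5, -9)
  daily <- monthlyToDaily(m)
  expect_length(daily, 365)
  expect_gte(min(daily), min(m))
  expect_lte(max(daily), max(m))
  expect_equal(monthlyToDaily(m, at = monthMidpoints()), m)
  expect_error(monthlyToDaily(m[1:11]), "12 finite")
})

test_that("season statistics honour threshold equality exactly", {
  # 94 days at exactly 6.4 degC: both criteria pass at equality
  daily <- c(rep(6.4, 94), rep(-10, 271))
  s <- seasonStats(daily)
  expect_equal(unname(s["length"]), 94)
  expect_equal(unname(s["mean"]), 6.4)
  p <- treelineParams()
  expect_true(s["length"] >= p$minSeasonDays && s["mean"] >= p$seasonMeanThreshold)

  # 93 days fails the length criterion
  s93 <- seasonStats(c(rep(6.4, 93), rep(-10, 272)))
  expect_lt(s93["length"], p$minSeasonDays)

  # a season mean of 6.39 fails the mean criterion
  s639 <- seasonStats(c(rep(6.39, 94), rep(-10, 271)))
  expect_equal(unname(s639["length"]), 94)
  expect_lt(s639["mean"], p$seasonMeanThreshold)

  # all days below the 0.9 degC day threshold: empty season
  s0 <- seasonStats(rep(0, 365))
  expect_equal(unname(s0["length"]), 0)
  expect_true(is.na(s0["mean"]))

  # long but cool season: length passes, mean fails
  s5 <- seasonStats(c(rep(5, 100), rep(-10, 265)))
  expect_equal(unname(s5["length"]), 100)
  expect_equal(unname(s5["mean"]), 5)
})

test_that("potential treeline matches the brute-force elevation scan", {
  set.seed(14)
  mism <- 0
  for (k in 1:200) {
    base <- runif(1, -2, 14)
    amp <- runif(1, 4, 16)
    noise <- rnorm(12, 0, 0.5)
    monthly <- base + amp * cos(2 * pi * ((1:12) - 7) / 12) + noise
    refE <- sample(c(0, 100, 400), 1)
    got <- potentialTreeline(monthly, refE)
    want <- oracleTreeline(monthly, refE)
    if (!identical(is.na(got), is.na(want)) ||
        (!is.na(got) && got != want)) mism <- mism + 1
  }
  expect_equal(mism, 0)
})

test_that("treeline scan edge behaviour matches its contract", {
  # climate failing at the scan floor: absent
  expect_true(is.na(potentialTreeline(rep(-5, 12))))

  # warming by one lapse step raises a qualifying treeline by exactly one step
  p <- treelineParams()
  m <- 6 + 10 * cos(2 * pi * ((1:12) - 7) / 12)
  z0 <- potentialTreeline(m, 0, p)
  z1 <- potentialTreeline(m + p$lapseRate * p$zStep, 0, p)
  expect_false(is.na(z0))
  expect_lt(z0, p$zMax)            # not capped, so the shift is exact
  expect_equal(z1, z0 + p$zStep)

  # elevation monotonicity: every elevation below a qualifying one qualifies
  zs <- seq(p$zMin, p$zMax, by = p$zStep)
  set.seed(3)
  for (k in 1:20) {
    m <- runif(1, 0, 12) + runif(1, 5, 14) * cos(2 * pi * ((1:12) - 7) / 12)
    qual <- vapply(zs, function(z) {
      s <- seasonStats(monthlyToDaily(m) - p$lapseRate * z, p)
      s["length"] >= p$minSeasonDays && !is.na(s["mean"]) &&
        s["mean"] >= p$seasonMeanThreshold
    }, logical(1))
    if (any(qual)) expect_true(all(qual[seq_len(max(which(qual)))]))
  }
})

test_that("below-treeline masks respect treeline, DEM, mask and nesting", {
  w <- tinyWorld(seed = 17, n = 6)
  surf <- treelineSurface(w@climate)

  # no treeline anywhere: all-false mask
  none <- surf
  none@elevation[] <- NA_real_
  expect_false(any(gridValues(belowTreelineMask(none, w@dem))))

  # flat DEM at 0 m with a 500 m treeline everywhere: mask = land mask
  flat <- new("ElevationGrid", lattice = w@dem@lattice,
              values = matrix(0, 6, 6))
  all500 <- surf
  all500@elevation[] <- 500
  mask <- w@climate@mask
  mask[1, ] <- "ice"
  got <- gridValues(belowTreelineMask(all500, flat, mask))
  expect_identical(got, mask == "land")
})

test_that("a finer DEM finds at least the below-treeline area of its aggregate", {
  # climate cell with a treeline at moderate elevation, DEM with a deep
  # sub-cell valley: the coarse mean sits above the treeline, the fine DEM
  # resolves the valley floor
  lt <- gridLattice(0, 60, 1, 2, 2)
  m <- 8 + 11 * cos(2 * pi * ((1:12) - 7) / 12)
  grid <- new("ClimateGrid", lattice = lt,
              temperature = array(rep(m, each = 4), c(2, 2, 12)),
              precipitation = array(50, c(2, 2, 12)),
              mask = matrix("land", 2, 2), refElevation = matrix(0, 2, 2))
  surf <- treelineSurface(grid)
  expect_false(any(is.na(surf@elevation)))
  zt <- surf@elevation[1, 1]

  fineLt <- gridLattice(0, 60, 0.5, 4, 4)
  fineVals <- matrix(zt + 200, 4, 4)
  fineVals[cbind(1:4, 1:4)] <- zt - 100        # valley floor below treeline
  fineDem <- new("ElevationGrid", lattice = fineLt, values = fineVals)
  coarseDem <- new("ElevationGrid", lattice = lt,
                   values = changeResolution(fineVals, 2, "aggregate_mean"))

  fineArea <- sum(gridValues(belowTreelineMask(surf, fineDem))) / 4
  coarseArea <- sum(gridValues(belowTreelineMask(surf, coarseDem)))
  expect_gt(fineArea, coarseArea)
})

test_that("layer agreement counts true layers per cell", {
  a <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2)
  expect_equal(layerAgreement(rep(list(a), 6))[a], rep(6L, 2))
  expect_equal(layerAgreement(rep(list(a), 6))[!a], rep(0L, 2))
  expect_equal(layerAgreement(list(a)), a * 1L)
  expect_true(all(layerAgreement(list(a, !a)) == 1L))
  expect_error(layerAgreement(list(a, matrix(TRUE, 3, 3))), "differ")
})

test_that("uniform warming never lowers treelines or shrinks the mask", {
  for (seed in c(1, 2, 3)) {
    w <- makeWorld(nRows = 5, nCols = 5, noiseSd = 0.4, relief = 700,
                   seed = seed)
    warm <- w@climate
    warm@temperature <- warm@temperature + 1
    s0 <- treelineSurface(w@climate)
    s1 <- treelineSurface(warm)
    z0 <- s0@elevation; z1 <- s1@elevation
    expect_true(all(is.na(z0) | (!is.na(z1) & z1 >= z0)))
    m0 <- gridValues(belowTreelineMask(s0, w@dem, w@climate@mask))
    m1 <- gridValues(belowTreelineMask(s1, w@dem, w@climate@mask))
    expect_true(all(m1[m0]))
  }
})

test_that("the longest-run season definition is at most the all-days season", {
  p <- treelineParams()
  pr <- treelineParams(seasonDefinition = "longest_run")
  set.seed(6)
  for (k in 1:10) {
    daily <- monthlyToDaily(runif(1, -2, 8) +
                            runif(1, 6, 14) * cos(2 * pi * ((1:12) - 7) / 12) +
                            rnorm(12))
    sAll <- seasonStats(daily, p)
    sRun <- seasonStats(daily, pr)
    expect_lte(sRun["length"], sAll["length"])
  }
  # wraparound: a season spanning the year boundary is one run
  daily <- rep(-5, 365)
  daily[c(350:365, 1:20)] <- 3
  expect_equal(unname(seasonStats(daily, pr)["length"]), 36)
})
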