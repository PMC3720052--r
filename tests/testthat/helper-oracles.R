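## Independent oracles used by the tests. Each reimplements the checked
## quantity from first principles, sharing no code with the package path it
## verifies.

## plain haversine from the textbook formula, R = 6371.0088 km
oracleHaversineKm <- function(lat1, lon1, lat2, lon2) {
  R <- 6371.0088
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dp <- (lat2 - lat1) * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * R * atan2(sqrt(a), sqrt(1 - a))
}

## daily series by explicit bracketing of month mid-points (no approx())
oracleDaily <- function(monthly) {
  len <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  mids <- cumsum(len) - len / 2
  vapply(1:365, function(d) {
    if (d < mids[1]) {
      x1 <- mids[12] - 365; y1 <- monthly[12]; x2 <- mids[1]; y2 <- monthly[1]
    } else if (d >= mids[12]) {
      x1 <- mids[12]; y1 <- monthly[12]; x2 <- mids[1] + 365; y2 <- monthly[1]
    } else {
      k <- max(which(mids <= d))
      x1 <- mids[k]; y1 <- monthly[k]; x2 <- mids[k + 1]; y2 <- monthly[k + 1]
    }
    y1 + (y2 - y1) * (d - x1) / (x2 - x1)
  }, numeric(1))
}

## brute-force treeline: scan every elevation step from the top, count
## qualifying days and their mean directly
oracleTreeline <- function(monthly, refElev = 0, minDays = 94, dayThr = 0.9,
                           meanThr = 6.4, lapse = 0.0055, zMin = 0,
                           zMax = 2000, zStep = 25) {
  daily <- oracleDaily(monthly)
  for (z in rev(seq(zMin, zMax, by = zStep))) {
    d <- daily - lapse * (z - refElev)
    qual <- d[d >= dayThr]
    if (length(qual) >= minDays && mean(qual) >= meanThr) return(z)
  }
  NA_real_
}

## exhaustive TSS threshold search over mid-point candidates plus extremes
oracleTssThreshold <- function(scores, labels, weights = rep(1, length(scores))) {
  s <- sort(unique(scores))
  cands <- if (length(s) == 1) s else
    c(s[1], (s[-1] + s[-length(s)]) / 2, s[length(s)])
  best <- -Inf; bestT <- NA
  for (t in cands) {
    tp <- sum(weights[labels == 1 & scores >= t])
    fn <- sum(weights[labels == 1 & scores < t])
    tn <- sum(weights[labels == 0 & scores < t])
    fp <- sum(weights[labels == 0 & scores >= t])
    tss <- tp / (tp + fn) + tn / (tn + fp) - 1
    if (tss > best + 1e-12) { best <- tss; bestT <- t }
  }
  list(threshold = bestT, tss = best)
}

## breadth-first search ball over 8-connected suitable cells
oracleBfsBall <- function(initial, suitable, steps) {
  d <- dim(initial)
  frontier <- initial & suitable
  visited <- frontier
  for (s in seq_len(steps)) {
    idx <- which(frontier)
    if (length(idx) == 0) break
    i <- (idx - 1L) %% d[1] + 1L
    j <- (idx - 1L) %/% d[1] + 1L
    nxt <- matrix(FALSE, d[1], d[2])
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2]
      nxt[cbind(ii[ok], jj[ok])] <- TRUE
    }
    frontier <- nxt & suitable & !visited
    visited <- visited | frontier
  }
  visited
}

## shared small-world fixture
tinyWorld <- function(seed = 11, n = 15, noise = 0, relief = 400, ...) {
  makeWorld(nRows = n, nCols = n, noiseSd = noise, relief = relief,
            seed = seed, ...)
}

## predictor table + labels for a virtual species: truth presences (undegraded
## coordinates) against pseudo-absences drawn from unsuitable land cells
speciesTrainingData <- function(world, vs) {
  bio <- deriveBioclim(world@climate)
  occ <- vs@occurrences
  land <- gridMask(world@climate) == "land"
  absMask <- land & !vs@truthMask
  pred <- rbind(
    extractPredictors(bio, occ$lat_true, occ$lon_true),
    data.frame(summerT = bio@summerT[absMask],
               coldestT = bio@coldestT[absMask],
               annualP = bio@annualP[absMask]))
  list(data = pred,
       labels = c(rep(1, nrow(occ)), rep(0, sum(absMask))),
       bio = bio, absMask = absMask)
}
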