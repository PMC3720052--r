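test_that("the envelope recovers a known box at zero trim", {
  set.seed(1)
  pres <- data.frame(a = runif(200, 2, 5), b = runif(200, -3, 1))
  pres[1, ] <- c(2, -3)   # pin the corners so the box is exactly realized
  pres[2, ] <- c(5, 1)
  fit <- fitEnvelope(pres, q = 0)
  expect_equal(unname(fit@fit$lower), c(2, -3))
  expect_equal(unname(fit@fit$upper), c(5, 1))

  # a point outside any one bound is not inside the binary envelope
  s <- predictSuitability(fit, data.frame(a = c(3, 6, 3), b = c(0, 0, 2)))
  expect_equal(s, c(1, 0.5, 0.5))
  expect_true(s[1] == 1 && all(s[-1] < 1))
  expect_error(fitEnvelope(pres[1, , drop = FALSE]), "at least 2")

  # trimmed envelope clips the outer quantiles
  fitq <- fitEnvelope(pres, q = 0.05)
  expect_gt(fitq@fit$lower[["a"]], 2)
  expect_lt(fitq@fit$upper[["a"]], 5)
})

test_that("weighted logistic fit balances classes and respects weight invariance", {
  set.seed(2)
  n <- 120
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, plogis(1.2 * x$a - 0.8 * x$b))
  # balanced classes: equal weights are all 1
  yb <- c(rep(1, 50), rep(0, 50))
  expect_equal(equalClassWeights(yb), rep(1, 100))

  w <- equalClassWeights(y)
  expect_equal(sum(w[y == 1]), sum(w[y == 0]))

  fit <- fitModel("glm", x, y)
  # duplicating every absence at half weight leaves coefficients unchanged
  absIdx <- which(y == 0)
  x2 <- rbind(x, x[absIdx, ]); y2 <- c(y, y[absIdx])
  w2 <- c(w, w[absIdx])
  w2[c(absIdx, n + seq_along(absIdx))] <- w[absIdx] / 2
  fit2 <- fitModel("glm", x2, y2, weights = w2)
  # compare on the probability scale (the fits standardize internally
  # against different record sets, so raw coefficients are rescaled)
  grid <- expand.grid(a = seq(-2, 2, 0.5), b = seq(-2, 2, 0.5))
  expect_equal(predictSuitability(fit, grid), predictSuitability(fit2, grid),
               tolerance = 1e-6)
})

test_that("complete separation falls back to a penalized fit with a warning", {
  x <- data.frame(a = c(rnorm(30, -3), rnorm(30, 3)))
  y <- rep(c(0, 1), each = 30)
  expect_warning(fit <- fitModel("glm", x, y), "separation")
  s <- predictSuitability(fit, x)
  expect_true(all(s[y == 1] > 0.5) && all(s[y == 0] < 0.5))
})

test_that("TSS threshold equals exhaustive search on random score sets", {
  set.seed(3)
  for (k in 1:1000) {
    n <- sample(8:40, 1)
    scores <- round(runif(n), sample(1:3, 1))  # force ties sometimes
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    w <- runif(n, 0.5, 2)
    got <- suppressWarnings(tssThreshold(scores, labels, w))
    want <- oracleTssThreshold(scores, labels, w)
    expect_equal(as.numeric(got), want$threshold)
    expect_equal(attr(got, "tss"), want$tss, tolerance = 1e-12)
  }
})

test_that("TSS threshold contract: separable, identity and degenerate cases", {
  # separable scores: TSS 1 at the lowest optimal threshold
  sc <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  lb <- c(0, 0, 0, 1, 1, 1)
  t <- tssThreshold(sc, lb)
  expect_equal(attr(t, "tss"), 1)
  expect_equal(as.numeric(t), 0.5)   # lowest mid-gap giving TSS = 1

  # sens 0.9 / spec 0.8 at a threshold gives TSS 0.7
  scores <- c(rep(1, 9), 0, rep(0, 8), 1, 1)
  labels <- c(rep(1, 10), rep(0, 10))
  ss <- greenshift:::.sensSpec(scores, labels, 0.5, rep(1, 20))
  expect_equal(unname(ss["sensitivity"]), 0.9)
  expect_equal(unname(ss["specificity"]), 0.8)
  expect_equal(unname(ss["sensitivity"] + ss["specificity"] - 1), 0.7)

  # all scores equal: degenerate, TSS 0
  expect_warning(td <- tssThreshold(rep(0.4, 6), lb), "degenerate")
  expect_equal(attr(td, "tss"), 0)
})

test_that("AUC is 1 for perfect ranking, 0.5 for random labels, and rank-invariant", {
  sc <- c(0.8, 0.9, 0.7, 0.1, 0.2, 0.3)
  lb <- c(1, 1, 1, 0, 0, 0)
  expect_equal(aucWeighted(sc, lb), 1)

  # monotone transform invariance
  set.seed(4)
  s <- runif(60); l <- rbinom(60, 1, 0.5)
  expect_equal(aucWeighted(s, l), aucWeighted(qlogis(s * 0.98 + 0.01), l))

  # Monte-Carlo: independent labels give AUC ~ 0.5
  set.seed(5)
  aucs <- replicate(1000, {
    s <- runif(40); l <- c(rep(1, 20), rep(0, 20))
    aucWeighted(s, l)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.01)
})

test_that("an 80/20 split evaluation returns perfect metrics on separable data", {
  set.seed(6)
  x <- data.frame(a = c(runif(100, 0, 1), runif(100, 2, 3)),
                  b = runif(200))
  y <- rep(c(0, 1), each = 100)
  fit <- suppressWarnings(evaluateSplit("glm", x, y, seed = 8))
  expect_equal(unname(fit@evaluation["auc"]), 1)
  expect_equal(unname(fit@evaluation["tss"]), 1)
  expect_equal(unname(fit@evaluation["sensitivity"]), 1)
  expect_true(fit@threshold >= 0 && fit@threshold <= 1)

  # single-class input cannot be split
  expect_error(evaluateSplit("glm", x, rep(1, 200), seed = 1))
})

test_that("ensembles follow the at-least-three majority rule", {
  lt <- gridLattice(0, 60, 1, 2, 2)
  l1 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  l2 <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2)
  l3 <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2)
  l4 <- matrix(c(FALSE, TRUE, FALSE, FALSE), 2)
  l5 <- matrix(c(FALSE, FALSE, FALSE, FALSE), 2)
  ens <- ensembleProject(list(l1, l2, l3, l4, l5), lt)
  expect_equal(ens@count[1, 1], 3L)
  expect_true(ens@layer[1, 1])       # 3 of 5: majority
  expect_equal(ens@count[2, 1], 3L)
  expect_true(ens@layer[2, 1])
  expect_equal(ens@count[1, 2], 2L)
  expect_false(ens@layer[1, 2])      # 2 of 5: no majority
  expect_false(any(ens@layer[2, 2]))

  # identical layers: majority layer equals the layer itself
  same <- ensembleProject(rep(list(l3), 5), lt)
  expect_identical(same@layer, l3)

  # conservation: summed counts equal summed per-model true cells
  expect_equal(sum(ens@count), sum(sapply(list(l1, l2, l3, l4, l5), sum)))
})

test_that("richness stacks count species and difference maps subtract", {
  a <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2)
  b <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  zero <- matrix(FALSE, 2, 2)
  expect_true(all(richnessStack(list(zero, zero)) == 0L))
  one <- matrix(TRUE, 2, 2)
  expect_true(all(richnessStack(list(one)) == 1L))
  cur <- richnessStack(list(a, b))
  expect_equal(cur, a + b)
  expect_true(all(richnessDiff(cur, cur) == 0L))
  fut <- richnessStack(list(a, one))
  expect_equal(richnessDiff(fut, cur), (a + one) - (a + b))
})

test_that("model projection restricts scores to land and region masks", {
  w <- tinyWorld(seed = 23, n = 8)
  bio <- deriveBioclim(w@climate)
  vs <- makeVirtualSpecies(w, rbind(lo = c(-100, -100, 0),
                                    hi = c(100, 100, 1e5)),
                           nPresence = 50, seed = 1)
  td <- speciesTrainingData(w, vs)
  fit <- fitEnvelope(td$data[td$labels == 1, ], q = 0)
  fit@threshold <- 0.99
  region <- matrix(FALSE, 8, 8)
  region[1:4, ] <- TRUE
  proj <- projectModel(fit, bio, regionMask = region)
  expect_true(all(is.na(proj$score[!region])))
  expect_false(any(proj$binary[5:8, ]))
})
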