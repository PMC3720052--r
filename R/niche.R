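## Climatic-niche ensemble: pluggable suitability models (rectilinear
## envelope, class-weighted logistic regression, a probability-forest
## adapter), 80/20 hold-out evaluation with AUC/TSS/sensitivity, TSS-optimal
## binarization, majority ensembles and richness stacks.

#' Class-balancing weights
#'
#' Per-record weights such that the total presence weight equals the total
#' absence weight (presences weight 1, absences `nPres / nAbs`), so both
#' classes contribute equally to the fit regardless of how many
#' pseudo-absences were sampled.
#'
#' @param labels 0/1 (or logical) class labels.
#' @return numeric weight vector.
#' @export
equalClassWeights <- function(labels) {
  labels <- as.numeric(labels)
  nP <- sum(labels == 1)
  nA <- sum(labels == 0)
  if (nP == 0 || nA == 0) stop("both classes must be non-empty")
  ifelse(labels == 1, 1, nP / nA)
}

#' Fit a suitability model
#'
#' Pluggable model interface. `"envelope"` fits a rectilinear climate
#' envelope from the presences only: per predictor the `[q, 1-q]` quantile
#' interval of presence values (`q = 0` gives the literal min/max box); its
#' continuous score is the fraction of predictors inside their interval, and
#' a point is inside the binary envelope only when all predictors are in
#' bounds. `"glm"` is a class-weighted binomial logistic regression on
#' internally standardized predictors, maximised by iterative reweighting;
#' under complete separation a warning is raised and a small-ridge penalized
#' fit (glmnet) is used instead. `"rf"` wraps a probability random forest
#' (ranger) with the same case weights.
#'
#' @param algorithm `"envelope"`, `"glm"` or `"rf"`.
#' @param data data frame of predictor values.
#' @param labels 0/1 class labels (1 = presence).
#' @param weights per-record weights; default [equalClassWeights()].
#' @param q envelope quantile trim (default 0.05).
#' @param seed seed for learners with internal randomness.
#' @return a [ModelFit].
#' @export
fitModel <- function(algorithm = c("envelope", "glm", "rf"), data, labels,
                     weights = NULL, q = 0.05, seed = 1) {
  algorithm <- match.arg(algorithm)
  labels <- as.numeric(labels)
  if (is.null(weights)) weights <- equalClassWeights(labels)
  fit <- switch(algorithm,
    envelope = .fitEnvelope(data[labels == 1, , drop = FALSE], q),
    glm = .fitWeightedLogistic(data, labels, weights),
    rf = .fitRanger(data, labels, weights, seed))
  new("ModelFit", algorithm = algorithm, fit = fit,
      weightSummary = c(presence = sum(weights[labels == 1]),
                        absence = sum(weights[labels == 0])))
}

#' @rdname fitModel
#' @export
fitEnvelope <- function(data, q = 0.05) {
  # convenience wrapper taking presence predictor values directly
  fit <- .fitEnvelope(data, q)
  new("ModelFit", algorithm = "envelope", fit = fit,
      weightSummary = c(presence = nrow(data), absence = 0))
}

.fitEnvelope <- function(pres, q) {
  if (nrow(pres) < 2) stop("envelope needs at least 2 presences")
  stopifnot(q >= 0, q < 0.5)
  lo <- vapply(pres, function(v) stats::quantile(v, q, names = FALSE,
                                                 na.rm = TRUE), numeric(1))
  hi <- vapply(pres, function(v) stats::quantile(v, 1 - q, names = FALSE,
                                                 na.rm = TRUE), numeric(1))
  list(lower = lo, upper = hi, q = q, vars = names(pres))
}

.standardize <- function(data) {
  ctr <- vapply(data, mean, numeric(1))
  scl <- vapply(data, stats::sd, numeric(1))
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl,
       x = sweep(sweep(as.matrix(data), 2, ctr), 2, scl, "/"))
}

.fitWeightedLogistic <- function(data, labels, weights) {
  std <- .standardize(data)
  df <- as.data.frame(std$x)
  df$.y <- labels
  df$.w <- weights
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df[, c(names(data), ".y")],
               family = stats::binomial(), weights = df$.w),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || !fit$converged) {
    warning("complete separation detected; using a small-ridge penalized fit")
    x <- std$x
    pad <- ncol(x) < 2            # glmnet needs >= 2 columns
    if (pad) x <- cbind(x, .pad = 0)
    rf <- glmnet::glmnet(x, labels, family = "binomial",
                         weights = weights, alpha = 0, lambda = 1e-4,
                         standardize = FALSE)
    beta <- c(as.numeric(rf$a0), as.numeric(rf$beta))
    if (pad) beta <- beta[-length(beta)]
  } else {
    beta <- stats::coef(fit)
    beta[is.na(beta)] <- 0       # aliased (collinear) predictors drop out
  }
  names(beta) <- c("(Intercept)", names(data))
  list(coef = beta, center = std$center, scale = std$scale,
       vars = names(data), separation = sep)
}

.fitRanger <- function(data, labels, weights, seed) {
  df <- data
  df$.y <- factor(labels, levels = c(0, 1))
  rf <- ranger::ranger(.y ~ ., data = df, probability = TRUE,
                       case.weights = weights, num.trees = 500,
                       seed = seed, num.threads = 1)
  list(model = rf, vars = names(data))
}

#' Predict suitability scores
#'
#' @param fit a [ModelFit].
#' @param newdata data frame of predictor values.
#' @return numeric scores in `[0, 1]` (envelope: fraction of predictors in
#'   bounds; glm/rf: predicted presence probability).
#' @export
predictSuitability <- function(fit, newdata) {
  stopifnot(is(fit, "ModelFit"))
  f <- fit@fit
  x <- newdata[, f$vars, drop = FALSE]
  switch(fit@algorithm,
    envelope = {
      inb <- mapply(function(v, lo, hi) v >= lo & v <= hi,
                    x, f$lower, f$upper)
      if (is.null(dim(inb))) inb <- matrix(inb, nrow = nrow(x))
      rowMeans(inb)
    },
    glm = {
      xs <- sweep(sweep(as.matrix(x), 2, f$center[f$vars]), 2,
                  f$scale[f$vars], "/")
      eta <- as.numeric(f$coef[1] + xs %*% f$coef[-1])
      1 / (1 + exp(-eta))
    },
    rf = {
      p <- stats::predict(f$model, data = x, num.threads = 1)$predictions
      p[, "1"]
    })
}

#' TSS-optimal binarization threshold
#'
#' Evaluates the weighted true skill statistic (sensitivity + specificity
#' - 1, prediction rule `score >= threshold`) at every candidate cut point
#' (the mid-points between adjacent distinct scores plus the extremes) and
#' returns the threshold maximising it; ties resolve to the lowest
#' threshold. A degenerate score set (all scores equal) yields that single
#' value with TSS 0 and a warning.
#'
#' @param scores numeric model scores.
#' @param labels 0/1 class labels.
#' @param weights optional per-record weights (default 1).
#' @return the threshold, with attributes `tss` (the maximised TSS) and
#'   `degenerate`.
#' @export
tssThreshold <- function(scores, labels, weights = NULL) {
  labels <- as.numeric(labels)
  if (is.null(weights)) weights <- rep(1, length(scores))
  s <- sort(unique(scores))
  if (length(s) == 1) {
    warning("all scores are equal; TSS threshold is degenerate")
    out <- s
    attr(out, "tss") <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  cands <- c(s[1], (s[-1] + s[-length(s)]) / 2, s[length(s)])
  wP <- sum(weights[labels == 1])
  wA <- sum(weights[labels == 0])
  tss <- vapply(cands, function(t) {
    pred <- scores >= t
    sens <- sum(weights[labels == 1 & pred]) / wP
    spec <- sum(weights[labels == 0 & !pred]) / wA
    sens + spec - 1
  }, numeric(1))
  best <- which(tss >= max(tss) - 1e-12)[1]   # lowest threshold on ties
  out <- cands[best]
  attr(out, "tss") <- tss[best]
  attr(out, "degenerate") <- FALSE
  out
}

#' Weighted rank AUC
#'
#' Area under the ROC curve as the weighted probability that a presence
#' scores above an absence (ties count one half). Invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores numeric model scores.
#' @param labels 0/1 class labels.
#' @param weights optional per-record weights.
#' @return AUC in `[0, 1]`.
#' @export
aucWeighted <- function(scores, labels, weights = NULL) {
  labels <- as.numeric(labels)
  if (is.null(weights)) weights <- rep(1, length(scores))
  sP <- scores[labels == 1]; wp <- weights[labels == 1]
  sA <- scores[labels == 0]; wa <- weights[labels == 0]
  if (length(sP) == 0 || length(sA) == 0)
    stop("both classes must be present")
  cmp <- outer(sP, sA, function(a, b) (a > b) + 0.5 * (a == b))
  sum((wp %o% wa) * cmp) / (sum(wp) * sum(wa))
}

## sensitivity/specificity at a threshold (rule: score >= threshold)
.sensSpec <- function(scores, labels, threshold, weights) {
  pred <- scores >= threshold
  wP <- sum(weights[labels == 1])
  wA <- sum(weights[labels == 0])
  c(sensitivity = sum(weights[labels == 1 & pred]) / wP,
    specificity = sum(weights[labels == 0 & !pred]) / wA)
}

#' Fit and evaluate a model on a random calibration/validation split
#'
#' Splits the records into a calibration fraction (default 80%) and a
#' validation remainder, refusing splits that leave either partition without
#' both classes (resplitting up to `retries` times). The model is fitted on
#' the calibration partition with class-balancing weights, the TSS-optimal
#' threshold is derived from the calibration scores, and AUC, TSS
#' (sensitivity + specificity - 1 at that threshold) and sensitivity are
#' measured on the validation partition, weights respected throughout.
#'
#' @param algorithm passed to [fitModel()].
#' @param data data frame of predictor values.
#' @param labels 0/1 class labels.
#' @param calibrationFraction fraction used for calibration (default 0.8).
#' @param seed integer random seed for the split.
#' @param retries resplit attempts when a partition lacks a class.
#' @param q envelope quantile trim.
#' @return a [ModelFit] fitted on the calibration partition, with `threshold`
#'   and hold-out `evaluation` filled in.
#' @export
evaluateSplit <- function(algorithm, data, labels, calibrationFraction = 0.8,
                          seed, retries = 20, q = 0.05) {
  if (missing(seed)) stop("a seed is required")
  labels <- as.numeric(labels)
  n <- length(labels)
  set.seed(seed)
  for (k in seq_len(retries)) {
    cal <- sample(n, round(calibrationFraction * n))
    val <- setdiff(seq_len(n), cal)
    if (length(unique(labels[cal])) == 2 && length(unique(labels[val])) == 2)
      break
    if (k == retries) stop("could not obtain a split with both classes in both partitions")
  }
  wCal <- equalClassWeights(labels[cal])
  wVal <- equalClassWeights(labels[val])
  fit <- fitModel(algorithm, data[cal, , drop = FALSE], labels[cal],
                  weights = wCal, q = q, seed = seed)
  sCal <- predictSuitability(fit, data[cal, , drop = FALSE])
  thr <- suppressWarnings(tssThreshold(sCal, labels[cal], wCal))
  sVal <- predictSuitability(fit, data[val, , drop = FALSE])
  ss <- .sensSpec(sVal, labels[val], as.numeric(thr), wVal)
  fit@threshold <- as.numeric(thr)
  fit@evaluation <- c(auc = aucWeighted(sVal, labels[val], wVal),
                      tss = unname(ss["sensitivity"] + ss["specificity"] - 1),
                      sensitivity = unname(ss["sensitivity"]))
  validObject(fit)
  fit
}

#' Project a fitted model onto a bioclim grid
#'
#' Scores every land cell of the grid (optionally restricted to a region
#' mask) and, when the fit carries a threshold, binarizes the scores.
#'
#' @param fit a [ModelFit] (with `threshold` set for binary output).
#' @param bioclim a [BioclimLayers].
#' @param regionMask optional logical matrix restricting the projection.
#' @return list with `score` (numeric matrix) and `binary` (logical matrix,
#'   `NA`-free: cells outside land/region are `FALSE`).
#' @export
projectModel <- function(fit, bioclim, regionMask = NULL) {
  stopifnot(is(bioclim, "BioclimLayers"))
  lt <- bioclim@lattice
  land <- bioclim@mask == "land"
  if (!is.null(regionMask)) land <- land & regionMask
  newdata <- data.frame(summerT = bioclim@summerT[land],
                        coldestT = bioclim@coldestT[land],
                        annualP = bioclim@annualP[land])
  score <- matrix(NA_real_, lt@nrow, lt@ncol)
  score[land] <- predictSuitability(fit, newdata)
  binary <- matrix(FALSE, lt@nrow, lt@ncol)
  if (!is.na(fit@threshold))
    binary[land] <- score[land] >= fit@threshold
  list(score = score, binary = binary)
}

#' Summed model ensemble
#'
#' Counts per-cell model agreement across binary projection layers and
#' applies the majority rule (default: at least 3 agreeing models count a
#' cell as suitable).
#'
#' @param layers list of logical matrices (one per model).
#' @param lattice the shared [GridLattice].
#' @param majority minimum agreeing models (default 3).
#' @param provenance optional provenance list.
#' @return an [EnsembleProjection].
#' @export
ensembleProject <- function(layers, lattice, majority = 3,
                            provenance = list()) {
  count <- layerAgreement(layers)
  if (majority > length(layers))
    warning("majority threshold exceeds the number of models; ",
            "the majority layer will be empty")
  new("EnsembleProjection", lattice = lattice, count = count,
      majority = majority, layer = count >= majority,
      provenance = provenance)
}

#' Species richness stack and difference
#'
#' `richnessStack()` counts, per cell, the number of species whose majority
#' layer is `TRUE`; `richnessDiff()` is the future-minus-current difference
#' of two such stacks.
#'
#' @param layers list of per-species logical majority layers (or
#'   [EnsembleProjection]s).
#' @return integer matrix of species counts.
#' @export
richnessStack <- function(layers) {
  mats <- lapply(layers, function(l)
    if (is(l, "EnsembleProjection")) l@layer else l)
  layerAgreement(mats)
}

#' @rdname richnessStack
#' @param future,current richness matrices from [richnessStack()].
#' @return `richnessDiff`: signed integer matrix, future minus current.
#' @export
richnessDiff <- function(future, current) {
  stopifnot(identical(dim(future), dim(current)))
  future - current
}
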