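## Learners, resampling, evaluation metrics, Y-randomization and
## hyperparameter search. Five algorithm families behind one interface:
## random_forest (ranger), knn (in-package, full class-probability output),
## svm (e1071, RBF; epsilon-SVR for regression), gbt_light (xgboost,
## histogram + leaf-wise growth) and gbt_extreme (xgboost, depth-wise).

.TASKS <- c("binary", "multiclass", "regression")
.ALGORITHMS <- c("random_forest", "knn", "svm", "gbt_light", "gbt_extreme")

.asBitMatrix <- function(X) {
  if (is(X, "FingerprintMatrix")) fpBits(X) else as.matrix(X)
}

.asFactorY <- function(y, task) {
  if (is.factor(y)) y <- as.character(droplevels(y))
  lv <- if (task == "binary") BINARY_LEVELS else MULTICLASS_LEVELS
  # canonical ordering puts nonblocker first so the positive class is last
  if (all(unique(y) %in% lv)) factor(y, levels = intersect(lv, unique(y)))
  else factor(y)
}

## ---- evaluation -----------------------------------------------------------

.confusion <- function(truth, predicted, levels) {
  table(factor(truth, levels = levels), factor(predicted, levels = levels))
}

# generalized (multi-category) Matthews correlation; equals the classic
# binary formula for two classes; defined as 0 when a marginal is degenerate
.mccFromConfusion <- function(cm) {
  s <- sum(cm)
  c0 <- sum(diag(cm))
  t <- rowSums(cm)  # truth counts
  p <- colSums(cm)  # prediction counts
  num <- c0 * s - sum(p * t)
  den <- sqrt(s^2 - sum(p^2)) * sqrt(s^2 - sum(t^2))
  if (den == 0) return(0)
  num / den
}

#' Classification metrics
#'
#' Computes balanced accuracy, sensitivity, specificity, precision, F1,
#' Matthews correlation and (when scores are supplied) ROC AUC from a truth
#' and prediction vector. Binary problems use the conventional positive-class
#' definitions with `positive` as the positive class; multiclass problems are
#' macro-averaged one-vs-rest (balanced accuracy is the mean per-class
#' recall, and MCC is the multi-category generalization).
#'
#' @param truth factor/character of reference labels.
#' @param predicted factor/character of predicted labels (same vocabulary).
#' @param scores optional: numeric positive-class probability (binary), or a
#'   probability matrix with one column per class (multiclass). When absent,
#'   AUC is omitted (NA).
#' @param positive positive class for binary problems (default `"blocker"`).
#' @return named list: bacc, se, sp, precision, f1, mcc, auc.
#' @export
evaluateClassification <- function(truth, predicted, scores = NULL,
                                   positive = "blocker") {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  levels <- unique(c(truth, predicted))
  canonical <- c(BINARY_LEVELS, MULTICLASS_LEVELS, REGRESSION_LEVELS)
  levels <- c(intersect(canonical, levels), setdiff(levels, canonical))
  cm <- .confusion(truth, predicted, levels)
  k <- length(levels)
  mcc <- .mccFromConfusion(cm)
  if (k == 2L && positive %in% levels) {
    neg <- setdiff(levels, positive)
    tp <- cm[positive, positive]; fn <- cm[positive, neg]
    tn <- cm[neg, neg]; fp <- cm[neg, positive]
    se <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(se) && prec + se > 0)
      2 * prec * se / (prec + se) else NA_real_
    auc <- NA_real_
    if (!is.null(scores)) {
      sc <- if (is.matrix(scores)) scores[, positive] else scores
      auc <- as.numeric(pROC::auc(pROC::roc(
        response = factor(truth, levels = c(neg, positive)),
        predictor = as.numeric(sc), levels = c(neg, positive),
        direction = "<", quiet = TRUE)))
    }
    bacc <- mean(c(se, sp))
  } else {
    perClass <- lapply(levels, function(cl) {
      tp <- cm[cl, cl]; fn <- sum(cm[cl, ]) - tp
      fp <- sum(cm[, cl]) - tp; tn <- sum(cm) - tp - fn - fp
      c(se = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
        sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
        prec = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
    })
    pc <- do.call(rbind, perClass)
    se <- mean(pc[, "se"], na.rm = TRUE)
    sp <- mean(pc[, "sp"], na.rm = TRUE)
    prec <- mean(pc[, "prec"], na.rm = TRUE)
    f1 <- if (prec + se > 0) 2 * prec * se / (prec + se) else NA_real_
    bacc <- se  # mean per-class recall
    auc <- NA_real_
    if (!is.null(scores) && is.matrix(scores)) {
      aucs <- vapply(levels, function(cl) {
        if (!cl %in% colnames(scores) || !cl %in% truth ||
            all(truth == cl)) return(NA_real_)
        as.numeric(pROC::auc(pROC::roc(
          response = factor(truth == cl, levels = c(FALSE, TRUE)),
          predictor = scores[, cl], levels = c(FALSE, TRUE),
          direction = "<", quiet = TRUE)))
      }, numeric(1))
      auc <- mean(aucs, na.rm = TRUE)
    }
  }
  list(bacc = bacc, se = se, sp = sp, precision = prec, f1 = f1,
       mcc = mcc, auc = auc)
}

#' Regression metrics
#'
#' @param truth,predicted numeric vectors of equal length (>= 2).
#' @return named list: r2 (1 - SSres/SStot), mse, mae, rmse.
#' @export
evaluateRegression <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted), length(truth) >= 2L)
  if (stats::var(truth) == 0)
    stop("truth has zero variance; R2 is undefined")
  res <- truth - predicted
  mse <- mean(res^2)
  list(r2 = 1 - sum(res^2) / sum((truth - mean(truth))^2),
       mse = mse, mae = mean(abs(res)), rmse = sqrt(mse))
}

## ---- resampling -----------------------------------------------------------

#' Stratified train/test split
#'
#' Splits compounds 80/20 (by default) preserving class proportions
#' (classification) or the distribution of binned responses (regression),
#' deterministically for a given seed.
#'
#' @param y labels (factor/character) or numeric responses.
#' @param testFraction fraction held out (default 0.2).
#' @param seed RNG seed (default 42).
#' @param task task type; inferred from `y` when omitted.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratifiedSplit <- function(y, testFraction = 0.2, seed = 42L, task = NULL) {
  if (is.null(task))
    task <- if (is.numeric(y)) "regression" else "binary"
  if (task == "regression") {
    if (length(y) < 10L) stop("need at least 10 compounds to stratify")
    y <- as.numeric(y)
  } else {
    y <- .asFactorY(y, task)
    if (nlevels(y) < 2L) stop("need at least two classes to stratify")
    if (min(table(y)) < 2L)
      stop("every class needs at least two members to stratify")
  }
  set.seed(seed)
  trainIdx <- as.integer(caret::createDataPartition(
    y, p = 1 - testFraction, list = FALSE))
  list(train = trainIdx, test = setdiff(seq_along(y), trainIdx))
}

## ---- learners -------------------------------------------------------------

.hp <- function(hp, name, default) {
  if (!is.null(hp[[name]])) hp[[name]] else default
}

.fitLearner <- function(task, algorithm, X, y, hp, seed) {
  set.seed(seed)
  if (algorithm %in% c("gbt_light", "gbt_extreme")) {
    params <- list(
      eta = .hp(hp, "eta", 0.1),
      min_child_weight = .hp(hp, "min_child_weight", 1),
      subsample = .hp(hp, "subsample", 1),
      colsample_bytree = .hp(hp, "colsample_bytree", 1),
      tree_method = "hist", nthread = 1, seed = seed)
    if (algorithm == "gbt_light") {
      params$grow_policy <- "lossguide"
      params$max_leaves <- .hp(hp, "max_leaves", 31)
      params$max_depth <- 0
    } else {
      params$grow_policy <- "depthwise"
      params$max_depth <- .hp(hp, "max_depth", 6)
    }
    if (task == "regression") {
      params$objective <- "reg:squarederror"
      label <- y
    } else if (nlevels(y) == 2L) {
      params$objective <- "binary:logistic"
      label <- as.integer(y) - 1L
    } else {
      params$objective <- "multi:softprob"
      params$num_class <- nlevels(y)
      label <- as.integer(y) - 1L
    }
    booster <- xgboost::xgb.train(
      params = params, data = xgboost::xgb.DMatrix(X, label = label),
      nrounds = .hp(hp, "nrounds", 100), verbose = 0)
    return(list(kind = "xgb", raw = xgboost::xgb.save.raw(booster),
                nfeat = ncol(X)))
  }
  if (algorithm == "random_forest") {
    mtry <- max(1L, floor(.hp(hp, "mtryFrac", sqrt(ncol(X)) / ncol(X)) *
                            ncol(X)))
    fit <- ranger::ranger(
      x = X, y = y, num.trees = .hp(hp, "num.trees", 500),
      mtry = mtry, min.node.size = .hp(hp, "min.node.size",
                                       if (task == "regression") 5 else 1),
      probability = task != "regression", seed = seed, num.threads = 1,
      importance = "impurity")
    return(list(kind = "ranger", fit = fit))
  }
  if (algorithm == "svm") {
    fit <- e1071::svm(
      x = X, y = y, kernel = "radial",
      type = if (task == "regression") "eps-regression" else "C-classification",
      cost = .hp(hp, "cost", 10), gamma = .hp(hp, "gamma", 10 / ncol(X)),
      epsilon = .hp(hp, "epsilon", 0.1),
      probability = task != "regression", scale = FALSE)
    return(list(kind = "svm", fit = fit))
  }
  if (algorithm == "knn") {
    return(list(kind = "knn", X = X, y = y, k = .hp(hp, "k", 5L)))
  }
  stop("unknown algorithm: ", algorithm)
}

.xgbBooster <- function(fit) xgboost::xgb.load.raw(fit$raw)

.predictLearner <- function(fit, task, classLevels, X) {
  if (fit$kind == "xgb") {
    booster <- .xgbBooster(fit)
    p <- predict(booster, xgboost::xgb.DMatrix(X))
    if (task == "regression") return(list(response = as.numeric(p)))
    if (length(classLevels) == 2L) {
      prob <- cbind(1 - p, p)
      colnames(prob) <- classLevels
    } else {
      prob <- if (is.matrix(p)) p
              else matrix(p, nrow = nrow(X), byrow = TRUE)
      colnames(prob) <- classLevels
    }
    lab <- classLevels[max.col(prob, ties.method = "first")]
    return(list(label = factor(lab, levels = classLevels), prob = prob))
  }
  if (fit$kind == "ranger") {
    pr <- predict(fit$fit, data = X, num.threads = 1)
    if (task == "regression") return(list(response = pr$predictions))
    prob <- pr$predictions[, classLevels, drop = FALSE]
    lab <- classLevels[max.col(prob, ties.method = "first")]
    return(list(label = factor(lab, levels = classLevels), prob = prob))
  }
  if (fit$kind == "svm") {
    if (task == "regression")
      return(list(response = as.numeric(predict(fit$fit, X))))
    pr <- predict(fit$fit, X, probability = TRUE)
    prob <- attr(pr, "probabilities")[, classLevels, drop = FALSE]
    lab <- classLevels[max.col(prob, ties.method = "first")]
    return(list(label = factor(lab, levels = classLevels), prob = prob))
  }
  if (fit$kind == "knn") {
    n <- nrow(X)
    resp <- numeric(n)
    prob <- if (task != "regression")
      matrix(0, n, length(classLevels), dimnames = list(NULL, classLevels))
    k <- min(fit$k, nrow(fit$X))
    refSq <- rowSums(fit$X^2)
    for (i in seq_len(n)) {
      d2 <- refSq - 2 * as.numeric(fit$X %*% X[i, ]) + sum(X[i, ]^2)
      nb <- order(d2)[seq_len(k)]   # ties broken by reference order
      if (task == "regression") {
        resp[i] <- mean(fit$y[nb])
      } else {
        tab <- table(factor(fit$y[nb], levels = classLevels)) / k
        prob[i, ] <- as.numeric(tab)
      }
    }
    if (task == "regression") return(list(response = resp))
    lab <- classLevels[max.col(prob, ties.method = "first")]
    return(list(label = factor(lab, levels = classLevels), prob = prob))
  }
  stop("unknown learner kind")
}

#' Train a QSAR model
#'
#' Fits one learner on a fingerprint matrix, records the seed, fingerprint
#' spec and hyperparameters for bit-for-bit reproducibility, and fits the
#' applicability-domain model on the training fingerprints.
#'
#' @param task `"binary"`, `"multiclass"` or `"regression"`.
#' @param algorithm one of random_forest, knn, svm, gbt_light, gbt_extreme.
#' @param X a [FingerprintMatrix-class] (or plain 0/1 matrix).
#' @param y class labels (classification) or pIC50 values (regression).
#' @param hyperparameters named list of learner settings (defaults used for
#'   anything omitted).
#' @param seed integer RNG seed.
#' @param fitADModel fit the applicability domain alongside (default TRUE).
#' @param adK,adZ applicability-domain neighbor count and width multiplier.
#' @return A [HergModel-class].
#' @export
trainModel <- function(task, algorithm, X, y, hyperparameters = list(),
                       seed = 1L, fitADModel = TRUE, adK = 1L, adZ = 0.5) {
  task <- match.arg(task, .TASKS)
  algorithm <- match.arg(algorithm, .ALGORITHMS)
  spec <- if (is(X, "FingerprintMatrix")) fpSpec(X) else fingerprintSpec()
  ids <- if (is(X, "FingerprintMatrix")) compoundIds(X)
         else sprintf("cpd%d", seq_len(nrow(X)))
  Xm <- .asBitMatrix(X)
  stopifnot(nrow(Xm) == length(y))
  if (task == "regression") {
    y <- as.numeric(y)
    if (stats::var(y) == 0) stop("response has zero variance")
    classLevels <- character()
  } else {
    y <- .asFactorY(y, task)
    if (nlevels(y) < 2L) stop("training labels contain a single class")
    classLevels <- levels(y)
  }
  fit <- .fitLearner(task, algorithm, Xm, y, hyperparameters, seed)
  ad <- if (fitADModel) fitAD(Xm, k = adK, z = adZ) else NULL
  new("HergModel", task = task, algorithm = algorithm,
      hyperparameters = hyperparameters, fingerprint = spec,
      seed = as.integer(seed), fit = fit, classLevels = classLevels,
      trainIds = ids, ad = ad, metrics = list())
}

#' Predict with a trained model
#'
#' @param object a [HergModel-class].
#' @param newdata a [FingerprintMatrix-class], a plain 0/1 matrix, or a
#'   character vector of SMILES (featurized with the model's spec).
#' @param type `"label"` (classification factor / numeric response),
#'   `"prob"` (class-probability matrix) or `"response"` (numeric; the
#'   positive-class probability for binary models).
#' @return predictions as described under `type`.
#' @export
setMethod("predict", "HergModel",
          function(object, newdata, type = c("label", "prob", "response")) {
  type <- match.arg(type)
  if (is.character(newdata))
    newdata <- featurizeDataset(newdata, fpSpec(object))
  Xm <- .asBitMatrix(newdata)
  out <- .predictLearner(object@fit, object@task, object@classLevels, Xm)
  if (object@task == "regression") return(out$response)
  switch(type,
         label = out$label,
         prob = out$prob,
         response = if (length(object@classLevels) == 2L)
           out$prob[, object@classLevels[2L]] else out$prob)
})

#' Cross-validate a model specification
#'
#' Stratified k-fold cross-validation: every compound appears in exactly one
#' validation fold; fold metrics are averaged and their SD reported.
#'
#' @inheritParams trainModel
#' @param folds number of folds (default 5).
#' @return list with `perFold` (metric list per fold), `mean` and `sd`
#'   (named numeric vectors) and `foldAssignment`.
#' @export
crossValidate <- function(task, algorithm, X, y, folds = 5L, seed = 1L,
                          hyperparameters = list()) {
  task <- match.arg(task, .TASKS)
  Xm <- .asBitMatrix(X)
  yy <- if (task == "regression") as.numeric(y) else .asFactorY(y, task)
  if (folds < 2L) stop("folds must be >= 2")
  if (task != "regression" && folds > min(table(yy)))
    stop("folds exceed the size of the smallest class")
  set.seed(seed)
  foldIdx <- caret::createFolds(yy, k = folds)
  assignment <- integer(length(yy))
  for (f in seq_along(foldIdx)) assignment[foldIdx[[f]]] <- f
  perFold <- lapply(seq_along(foldIdx), function(f) {
    test <- foldIdx[[f]]
    m <- trainModel(task, algorithm, Xm[-test, , drop = FALSE], yy[-test],
                    hyperparameters, seed = seed, fitADModel = FALSE)
    if (task == "regression") {
      evaluateRegression(yy[test],
                         predict(m, Xm[test, , drop = FALSE]))
    } else {
      evaluateClassification(
        yy[test], predict(m, Xm[test, , drop = FALSE], type = "label"),
        scores = predict(m, Xm[test, , drop = FALSE], type = "prob"),
        positive = if (length(m@classLevels) == 2L) m@classLevels[2L]
                   else "blocker")
    }
  })
  metricNames <- names(perFold[[1]])
  mat <- vapply(perFold, function(p) unlist(p[metricNames]),
                numeric(length(metricNames)))
  list(perFold = perFold,
       mean = rowMeans(mat, na.rm = TRUE),
       sd = apply(mat, 1, stats::sd, na.rm = TRUE),
       foldAssignment = assignment)
}

#' Y-randomization (response scrambling)
#'
#' Retrains the model `rounds` times on permuted training responses (round r
#' permutes with seed `seed + r`) and evaluates each scrambled model against
#' the true labels of the untouched test split. Real structure-activity
#' signal shows as a wide gap between the unscrambled model and the
#' chance-level scrambled distribution.
#'
#' @inheritParams trainModel
#' @param trainIdx,testIdx integer index vectors from [stratifiedSplit()].
#' @param rounds number of scrambling rounds (default 20).
#' @return list with `perRound` metric lists and `summary` (mean and sd of
#'   balanced accuracy or R2 across rounds).
#' @export
yRandomization <- function(task, algorithm, X, y, trainIdx, testIdx,
                           rounds = 20L, seed = 1L,
                           hyperparameters = list()) {
  stopifnot(rounds >= 1L)
  Xm <- .asBitMatrix(X)
  yy <- if (task == "regression") as.numeric(y) else .asFactorY(y, task)
  perRound <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    set.seed(seed + r)
    yScr <- yy[trainIdx][sample(length(trainIdx))]
    m <- trainModel(task, algorithm, Xm[trainIdx, , drop = FALSE], yScr,
                    hyperparameters, seed = seed + r, fitADModel = FALSE)
    perRound[[r]] <- if (task == "regression") {
      evaluateRegression(yy[testIdx],
                         predict(m, Xm[testIdx, , drop = FALSE]))
    } else {
      evaluateClassification(
        yy[testIdx],
        predict(m, Xm[testIdx, , drop = FALSE], type = "label"),
        positive = if (nlevels(yy) == 2L) levels(yy)[2L] else "blocker")
    }
  }
  key <- if (task == "regression") "r2" else "bacc"
  vals <- vapply(perRound, function(p) p[[key]], numeric(1))
  list(perRound = perRound,
       summary = c(mean = mean(vals), sd = stats::sd(vals)),
       metric = key, values = vals)
}

## ---- hyperparameter search ------------------------------------------------

#' Default hyperparameter search spaces
#'
#' Editable per-algorithm box constraints used by [tuneHyperparameters()].
#' Each entry is `list(lower, upper, integer, log)`.
#'
#' @param algorithm learner name.
#' @return named list of parameter ranges.
#' @export
defaultSearchSpace <- function(algorithm) {
  p <- function(lower, upper, integer = FALSE, log = FALSE)
    list(lower = lower, upper = upper, integer = integer, log = log)
  switch(match.arg(algorithm, .ALGORITHMS),
    random_forest = list(num.trees = p(100, 800, integer = TRUE),
                         mtryFrac = p(0.02, 0.5),
                         min.node.size = p(1, 10, integer = TRUE)),
    knn = list(k = p(1, 25, integer = TRUE)),
    svm = list(cost = p(0.1, 100, log = TRUE),
               gamma = p(1e-4, 0.1, log = TRUE)),
    gbt_light = list(nrounds = p(50, 300, integer = TRUE),
                     eta = p(0.02, 0.3, log = TRUE),
                     max_leaves = p(8, 64, integer = TRUE),
                     min_child_weight = p(1, 10),
                     subsample = p(0.6, 1)),
    gbt_extreme = list(nrounds = p(50, 300, integer = TRUE),
                       eta = p(0.02, 0.3, log = TRUE),
                       max_depth = p(3, 9, integer = TRUE),
                       min_child_weight = p(1, 10),
                       subsample = p(0.6, 1)))
}

.decodeUnit <- function(u, space) {
  out <- list()
  for (j in seq_along(space)) {
    s <- space[[j]]
    v <- if (isTRUE(s$log))
      exp(log(s$lower) + u[j] * (log(s$upper) - log(s$lower)))
    else s$lower + u[j] * (s$upper - s$lower)
    if (isTRUE(s$integer)) v <- as.integer(round(v))
    out[[names(space)[j]]] <- v
  }
  out
}

#' Bayesian hyperparameter search
#'
#' Sequential model-based optimization of the cross-validated score
#' (balanced accuracy for classification, R2 for regression): a Latin
#' hypercube initial design, then a Gaussian-process surrogate
#' (kernlab) proposing the expected-improvement maximizer among random
#' candidates, until `budget` evaluations are spent. The full trial log is
#' returned.
#'
#' @inheritParams crossValidate
#' @param space search space as from [defaultSearchSpace()].
#' @param budget total number of configurations to evaluate.
#' @return list with `hyperparameters` (best found), `score`, and `log`
#'   (data.frame of all trials in evaluation order).
#' @export
tuneHyperparameters <- function(task, algorithm, X, y,
                                space = defaultSearchSpace(algorithm),
                                budget = 20L, folds = 3L, seed = 1L) {
  if (length(space) == 0L) stop("empty search space")
  d <- length(space)
  Xm <- .asBitMatrix(X)
  scoreOf <- function(hp) {
    cv <- crossValidate(task, algorithm, Xm, y, folds = folds, seed = seed,
                        hyperparameters = hp)
    key <- if (task == "regression") "r2" else "bacc"
    unname(cv$mean[key])
  }
  set.seed(seed)
  nInit <- min(budget, max(4L, ceiling(budget / 3)))
  U <- lhs::maximinLHS(nInit, d)
  trials <- list(); scores <- numeric()
  for (i in seq_len(nrow(U))) {
    hp <- .decodeUnit(U[i, ], space)
    trials[[length(trials) + 1L]] <- hp
    scores <- c(scores, scoreOf(hp))
  }
  Umat <- U
  while (length(scores) < budget) {
    cand <- matrix(stats::runif(256 * d), ncol = d)
    uNext <- cand[sample(nrow(cand), 1L), ]  # fallback: random
    fitOk <- length(unique(scores)) > 1L
    if (fitOk) {
      gp <- tryCatch(
        kernlab::gausspr(x = Umat, y = scores, variance.model = TRUE,
                         kpar = "automatic"),
        error = function(e) NULL)
      if (!is.null(gp)) {
        mu <- as.numeric(kernlab::predict(gp, cand))
        sdv <- tryCatch(
          as.numeric(kernlab::predict(gp, cand, type = "sdeviation")),
          error = function(e) rep(stats::sd(scores), nrow(cand)))
        sdv[!is.finite(sdv) | sdv < 1e-9] <- 1e-9
        best <- max(scores)
        z <- (mu - best) / sdv
        ei <- (mu - best) * stats::pnorm(z) + sdv * stats::dnorm(z)
        uNext <- cand[which.max(ei), ]
      }
    }
    hp <- .decodeUnit(uNext, space)
    trials[[length(trials) + 1L]] <- hp
    scores <- c(scores, scoreOf(hp))
    Umat <- rbind(Umat, uNext)
  }
  logDf <- do.call(rbind, lapply(trials, as.data.frame))
  logDf$score <- scores
  best <- which.max(scores)
  list(hyperparameters = trials[[best]], score = scores[best], log = logDf)
}

#' Save / load a trained model bundle
#'
#' The bundle (including the fingerprint spec and AD model) is written as a
#' single RDS file; gradient-boosting fits are stored as raw booster bytes,
#' so a reloaded bundle reproduces predictions bit-for-bit.
#'
#' @param model a [HergModel-class].
#' @param path file path.
#' @return `path` (save) or the restored [HergModel-class] (load).
#' @export
saveHergModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveHergModel
#' @export
loadHergModel <- function(path) readRDS(path)
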