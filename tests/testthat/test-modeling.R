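# brute-force confusion-matrix oracle, computed element-by-element
oracleClassification <- function(truth, predicted, positive) {
  tp <- fn <- tn <- fp <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == positive && predicted[i] == positive) tp <- tp + 1
    if (truth[i] == positive && predicted[i] != positive) fn <- fn + 1
    if (truth[i] != positive && predicted[i] != positive) tn <- tn + 1
    if (truth[i] != positive && predicted[i] == positive) fp <- fp + 1
  }
  se <- tp / (tp + fn); sp <- tn / (tn + fp)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  f1 <- if (!is.na(prec) && prec + se > 0) 2 * prec * se / (prec + se)
        else NA_real_
  list(bacc = (se + sp) / 2, se = se, sp = sp, precision = prec, f1 = f1,
       mcc = mcc)
}

test_that("classification metrics match the worked confusion matrix", {
  truth <- c(rep("blocker", 50), rep("nonblocker", 50))
  pred <- c(rep("blocker", 45), rep("nonblocker", 5),
            rep("blocker", 10), rep("nonblocker", 40))
  m <- evaluateClassification(truth, pred)
  expect_equal(m$se, 0.9)
  expect_equal(m$sp, 0.8)
  expect_equal(m$bacc, 0.85)
  expect_equal(m$mcc, 0.70352647, tolerance = 1e-7)
  perfect <- evaluateClassification(truth, truth)
  expect_equal(perfect$bacc, 1)
  expect_equal(perfect$mcc, 1)
  allOne <- evaluateClassification(truth, rep("blocker", 100))
  expect_equal(allOne$bacc, 0.5)
  expect_equal(allOne$mcc, 0)
})

test_that("metrics agree with a brute-force oracle on random vectors", {
  set.seed(7)
  for (rep in 1:400) {
    n <- sample(10:60, 1)
    truth <- sample(c("blocker", "nonblocker"), n, replace = TRUE)
    pred <- sample(c("blocker", "nonblocker"), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    m <- evaluateClassification(truth, pred)
    o <- oracleClassification(truth, pred, "blocker")
    for (k in c("bacc", "se", "sp", "precision", "f1", "mcc"))
      expect_equal(m[[k]], o[[k]], tolerance = 1e-9, info = k)
  }
})

test_that("regression metrics match hand arithmetic and the formulas", {
  m <- evaluateRegression(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$mse, 1 / 3)
  expect_equal(m$mae, 1 / 3)
  expect_equal(m$rmse, sqrt(1 / 3))
  expect_equal(m$r2, 0.5)
  ident <- evaluateRegression(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(ident), c(r2 = 1, mse = 0, mae = 0, rmse = 0))
  expect_error(evaluateRegression(c(2, 2, 2), c(1, 2, 3)), "variance")
  set.seed(8)
  for (rep in 1:400) {
    truth <- rnorm(sample(5:50, 1))
    pred <- truth + rnorm(length(truth), 0, 0.5)
    m <- evaluateRegression(truth, pred)
    expect_equal(m$rmse^2, m$mse, tolerance = 1e-12)
    expect_equal(m$mae, mean(abs(truth - pred)), tolerance = 1e-12)
    expect_equal(m$r2, 1 - sum((truth - pred)^2) /
                         sum((truth - mean(truth))^2), tolerance = 1e-12)
  }
})

test_that("stratified split preserves class proportions exactly", {
  y <- c(rep("blocker", 60), rep("nonblocker", 40))
  sp <- stratifiedSplit(y, 0.2, seed = 42)
  expect_length(sp$test, 20L)
  expect_equal(sum(y[sp$test] == "blocker"), 12L)
  expect_equal(sum(y[sp$test] == "nonblocker"), 8L)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  sp2 <- stratifiedSplit(y, 0.2, seed = 42)
  expect_identical(sp, sp2)
  sp3 <- stratifiedSplit(y, 0.2, seed = 43)
  expect_false(identical(sp$test, sp3$test))
  expect_error(stratifiedSplit(c("a", "b", "b"), 0.2, seed = 1), "class")
})

test_that("cross-validation partitions compounds into disjoint folds", {
  comp <- compounds(fxBinaryClean)
  n <- 100L
  X <- fpBits(fxFpsClean)[seq_len(n), ]
  y <- comp$label[seq_len(n)]
  cv <- crossValidate("binary", "knn", X, y, folds = 5, seed = 3,
                      hyperparameters = list(k = 3))
  expect_length(cv$foldAssignment, n)
  expect_true(all(table(cv$foldAssignment) >= floor(n / 5)))
  expect_equal(sort(unique(cv$foldAssignment)), 1:5)
  # mean equals the hand average of the per-fold metrics
  expect_equal(unname(cv$mean["bacc"]),
               mean(vapply(cv$perFold, `[[`, 0, "bacc")))
  cv2 <- crossValidate("binary", "knn", X, y, folds = 5, seed = 3,
                       hyperparameters = list(k = 3))
  expect_identical(cv$foldAssignment, cv2$foldAssignment)
})

test_that("degenerate training inputs are rejected", {
  X <- matrix(rbinom(200, 1, 0.5), 20)
  expect_error(trainModel("binary", "gbt_light", X,
                          rep("blocker", 20)), "single class")
  expect_error(trainModel("regression", "svm", X, rep(5, 20)), "variance")
})

test_that("every learner family fits and predicts both task kinds", {
  comp <- compounds(fxBinaryClean)
  idx <- seq_len(80L)
  X <- fpBits(fxFpsClean)[idx, ]
  y <- comp$label[idx]
  yr <- comp$pic50[idx]
  for (algo in c("random_forest", "knn", "svm", "gbt_extreme")) {
    m <- trainModel("binary", algo, X, y, seed = 2, fitADModel = FALSE,
                    hyperparameters = list(nrounds = 30, num.trees = 100))
    lab <- predict(m, X, type = "label")
    expect_s3_class(lab, "factor")
    prob <- predict(m, X, type = "prob")
    expect_equal(dim(prob), c(80L, 2L))
    expect_true(all(abs(rowSums(prob) - 1) < 1e-6), info = algo)
    mr <- trainModel("regression", algo, X, yr, seed = 2,
                     fitADModel = FALSE,
                     hyperparameters = list(nrounds = 30, num.trees = 100))
    expect_length(predict(mr, X), 80L)
  }
})

test_that("saved and reloaded bundles predict bit-for-bit identically", {
  X <- fpBits(fxFpsClean)[fxSplitClean$test, , drop = FALSE]
  path <- tempfile(fileext = ".rds")
  saveHergModel(fxBinaryModel, path)
  reloaded <- loadHergModel(path)
  expect_identical(predict(reloaded, X, type = "prob"),
                   predict(fxBinaryModel, X, type = "prob"))
})

test_that("the planted signal is recovered and ranks in top importance", {
  comp <- compounds(fxBinaryClean)
  Xte <- fpBits(fxFpsClean)[fxSplitClean$test, , drop = FALSE]
  ev <- evaluateClassification(
    comp$label[fxSplitClean$test],
    as.character(predict(fxBinaryModel, Xte, type = "label")),
    scores = predict(fxBinaryModel, Xte, type = "prob"))
  expect_gte(ev$bacc, 0.85)
  # split-gain importance puts the planted bits in the top decile
  booster <- xgboost::xgb.load.raw(fxBinaryModel@fit$raw)
  imp <- xgboost::xgb.importance(model = booster)
  planted <- sprintf("bit%d", fxClean@truth$signalBits)
  ranks <- match(planted, imp$Feature)
  expect_true(all(!is.na(ranks)))
  expect_true(all(ranks <= max(1, 0.1 * 1024)))
})

test_that("hyperparameter search logs trials and is reproducible", {
  comp <- compounds(fxBinaryClean)
  idx <- seq_len(60L)
  X <- fpBits(fxFpsClean)[idx, ]
  y <- comp$label[idx]
  one <- tuneHyperparameters("binary", "knn", X, y, budget = 1, folds = 3,
                             seed = 5)
  expect_equal(nrow(one$log), 1L)
  expect_equal(one$score, one$log$score[1])
  res <- tuneHyperparameters("binary", "knn", X, y, budget = 6, folds = 3,
                             seed = 5)
  expect_equal(nrow(res$log), 6L)
  expect_equal(res$score, max(res$log$score))
  res2 <- tuneHyperparameters("binary", "knn", X, y, budget = 6, folds = 3,
                              seed = 5)
  expect_equal(res$log, res2$log)
  expect_error(tuneHyperparameters("binary", "knn", X, y, space = list(),
                                   budget = 2), "empty")
})
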