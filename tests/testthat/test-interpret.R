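test_that("exact tree attributions match 2^6 brute-force Shapley", {
  set.seed(31)
  n <- 200
  X <- matrix(rbinom(n * 6, 1, 0.5), n)
  y <- 1.5 * X[, 1] - 2 * X[, 3] + X[, 2] * X[, 5] + rnorm(n, 0, 0.1)
  m <- trainModel("regression", "gbt_extreme", X, y,
                  hyperparameters = list(nrounds = 5, max_depth = 3,
                                         eta = 0.5),
                  seed = 31, fitADModel = FALSE)
  attr <- shapAttributions(m, X[1:10, , drop = FALSE])
  expect_equal(attr@method, "tree_exact")
  booster <- xgboost::xgb.load.raw(m@fit$raw)
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  base <- predict(booster, xgboost::xgb.DMatrix(X[1:10, , drop = FALSE]),
                  predcontrib = TRUE)[, 7]
  for (i in 1:10) {
    phi <- oracleShapley(dt, X[i, ], 6)
    expect_equal(unname(attributions(attr)[i, ]), phi, tolerance = 1e-4)
    # additivity against the margin output
    marg <- predict(booster,
                    xgboost::xgb.DMatrix(X[i, , drop = FALSE]),
                    outputmargin = TRUE)
    expect_equal(base[i] + sum(phi), marg, tolerance = 1e-4)
  }
})

test_that("a single-split stump credits its feature with the full margin", {
  set.seed(32)
  X <- matrix(rbinom(400, 1, 0.5), 100, 4)
  y <- 2 * X[, 2] + rnorm(100, 0, 0.01)
  m <- trainModel("regression", "gbt_extreme", X, y,
                  hyperparameters = list(nrounds = 1, max_depth = 1,
                                         eta = 1), seed = 1,
                  fitADModel = FALSE)
  attr <- shapAttributions(m, X)
  v <- attributions(attr)
  expect_true(all(abs(v[, -2]) < 1e-9))
  booster <- xgboost::xgb.load.raw(m@fit$raw)
  marg <- predict(booster, xgboost::xgb.DMatrix(X), outputmargin = TRUE)
  expect_equal(attr@baseValue + v[, 2], marg, tolerance = 1e-5)
})

test_that("identical rows get identical attributions", {
  X <- fpBits(fxFpsClean)[rep(1L, 5), , drop = FALSE]
  attr <- shapAttributions(fxBinaryModel, X)
  for (i in 2:5)
    expect_identical(attributions(attr)[i, ], attributions(attr)[1, ])
})

test_that("tree attributions are additive on fixture molecules", {
  X <- fpBits(fxFpsClean)[1:100, , drop = FALSE]
  attr <- shapAttributions(fxBinaryModel, X)
  booster <- xgboost::xgb.load.raw(fxBinaryModel@fit$raw)
  contrib <- predict(booster, xgboost::xgb.DMatrix(X), predcontrib = TRUE)
  marg <- predict(booster, xgboost::xgb.DMatrix(X), outputmargin = TRUE)
  expect_equal(unname(rowSums(contrib)), marg, tolerance = 1e-6)
  expect_equal(unname(rowSums(attributions(attr)) +
                        contrib[, ncol(contrib)]), marg, tolerance = 1e-6)
})

test_that("global importance ranks the planted signal bits on top", {
  X <- fpBits(fxFpsClean)[fxSplitClean$test, , drop = FALSE]
  attr <- shapAttributions(fxBinaryModel, X)
  imp <- globalImportance(attr, topN = 10)
  expect_true(all(fxClean@truth$signalBits %in% imp$bit))
  expect_true(all(diff(imp$meanAbs) <= 0))
  full <- globalImportance(attr, topN = 1e6)
  expect_equal(nrow(full), 1024L)
})

test_that("global importance breaks ties by bit index", {
  v <- matrix(0, 2, 5)
  v[, 2] <- c(1, -1); v[, 4] <- c(1, 1)
  attr <- new("AttributionMatrix", values = v, baseValue = 0,
              ids = c("a", "b"), method = "tree_exact")
  imp <- globalImportance(attr, 5)
  expect_equal(imp$bit[1:2], c(2L, 4L))
  expect_equal(imp$signTendency[1:2], c(0, 1))
})

test_that("atom maps conserve the bit attribution mass", {
  for (s in fxLibrarySmall[1:5]) {
    map <- atomAttribution(fxBinaryModel, s)
    expect_equal(sum(atomWeights(map)), sum(map@bitAttributions),
                 tolerance = 1e-9)
    natoms <- length(hergsuite:::molecularGraph(map@smiles)$symbol)
    expect_length(atomWeights(map), natoms)
  }
})

test_that("an environment's attribution is shared equally by its atoms", {
  # synthetic one-bit case: craft an attribution matrix by hand through the
  # projection arithmetic of a two-atom molecule
  spec <- fingerprintSpec("ecfp", 0, 1024)
  bam <- bitAtomMap("CO", spec)
  fp <- fingerprint("CO", spec)
  expect_equal(length(bam), sum(fp))
  # radius 0: every environment is a single atom, so equal split is exact
  for (b in names(bam))
    for (env in bam[[b]]) expect_length(env, 1L)
})

test_that("masking attributions exist and flag signal-carrying atoms", {
  comp <- compounds(fxBinaryClean)
  s <- comp$smiles[which.max(comp$pic50)]  # a confident blocker
  map <- atomAttribution(fxBinaryModel, s, method = "masking")
  expect_equal(map@method, "masking")
  expect_length(atomWeights(map),
                length(hergsuite:::molecularGraph(map@smiles)$symbol))
})

test_that("sampling attributions are produced for non-tree models", {
  comp <- compounds(fxBinaryClean)
  idx <- seq_len(60L)
  Xs <- fpBits(fxFpsClean)[idx, 1:64]  # small bit space keeps this fast
  m <- trainModel("binary", "knn", Xs, comp$label[idx], seed = 3,
                  fitADModel = FALSE, hyperparameters = list(k = 3))
  attr <- shapAttributions(m, Xs[1:3, , drop = FALSE], nsim = 10,
                           backgroundSize = 5, seed = 9)
  expect_equal(attr@method, "sampling")
  expect_equal(dim(attributions(attr)), c(3L, 64L))
  attr2 <- shapAttributions(m, Xs[1:3, , drop = FALSE], nsim = 10,
                            backgroundSize = 5, seed = 9)
  expect_identical(attributions(attr), attributions(attr2))
})
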