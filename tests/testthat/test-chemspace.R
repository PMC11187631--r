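makeAssayTable <- function(smiles, assay, pic50) {
  recs <- data.frame(compoundId = sprintf("A%d", seq_along(smiles)),
                     smiles = smiles, assayType = assay, relation = "eq",
                     value = 10^(6 - pic50), units = "uM",
                     stringsAsFactors = FALSE)
  activityTable(recs)
}

test_that("assay correlation reproduces closed-form Pearson cases", {
  smi <- fxLibrarySmall[1:6]
  # identical ordering across assays: y = 2x - 4 is a perfect correlation
  x <- c(4, 4.5, 5, 5.5, 6, 6.5)
  tab <- makeAssayTable(c(smi, smi), rep(c("SP", "HEK"), each = 6),
                        c(x, 2 * x - 4))
  res <- assayCorrelation(tab)
  row <- res[res$assayA == "SP" & res$assayB == "HEK", ]
  expect_equal(row$r, 1, tolerance = 1e-12)
  expect_lt(row$p, 0.001)
  expect_equal(row$n, 6L)
  # anti-correlated and a hand-computed r = 0.5 triple
  tab2 <- makeAssayTable(c(smi[1:3], smi[1:3]),
                         rep(c("SP", "CHO"), each = 3),
                         c(1, 2, 3, 6, 4, 2))
  r2 <- assayCorrelation(tab2)
  expect_equal(r2$r[r2$assayA == "SP" & r2$assayB == "CHO"], -1,
               tolerance = 1e-12)
  tab3 <- makeAssayTable(c(smi[1:3], smi[1:3]),
                         rep(c("HEK", "CHO"), each = 3),
                         c(1, 2, 3, 1, 3, 2))
  r3 <- assayCorrelation(tab3)
  expect_equal(r3$r[r3$assayA == "HEK" & r3$assayB == "CHO"], 0.5,
               tolerance = 1e-12)
  # fewer than three shared compounds is undefined
  expect_true(is.na(r3$r[r3$assayA == "SP" & r3$assayB == "HEK"]))
})

test_that("cross-set Tanimoto matches the double-loop oracle", {
  A <- featurizeDataset(fxLibrarySmall[1:3], fingerprintSpec())
  B <- featurizeDataset(fxLibrarySmall[4:5], fingerprintSpec())
  got <- crossSetTanimoto(A, B)
  acc <- 0
  for (i in 1:3) for (j in 1:2)
    acc <- acc + tanimoto(fpBits(A)[i, ], fpBits(B)[j, ])
  expect_equal(got, acc / 6, tolerance = 1e-12)
  # same-set mode excludes self-pairs
  gotAA <- crossSetTanimoto(A, A)
  accAA <- 0
  for (i in 1:3) for (j in 1:3)
    if (i != j) accAA <- accAA + tanimoto(fpBits(A)[i, ], fpBits(A)[j, ])
  expect_equal(gotAA, accAA / 6, tolerance = 1e-12)
  # single-molecule set against itself
  one <- featurizeDataset(fxLibrarySmall[1], fingerprintSpec())
  expect_equal(crossSetTanimoto(one, one), 1)
  # disjoint bit supports
  m1 <- new("FingerprintMatrix", bits = matrix(c(1L, 1L, 0L, 0L), 1),
            spec = fingerprintSpec(nbits = 4), ids = "a")
  m2 <- new("FingerprintMatrix", bits = matrix(c(0L, 0L, 1L, 1L), 1),
            spec = fingerprintSpec(nbits = 4), ids = "b")
  expect_equal(crossSetTanimoto(m1, m2), 0)
  expect_error(crossSetTanimoto(m1, featurizeDataset(character(0),
                                                     fingerprintSpec())),
               "non-empty")
})

test_that("cliff detection agrees with brute-force pair enumeration", {
  ds <- curateDataset(fxNoisy, curationConfig("binary"))
  comp <- compounds(ds)[1:20, ]
  small <- new("CuratedDataset", compounds = comp, task = "binary",
               report = curationReport(ds), config = ds@config)
  spec <- fingerprintSpec("maccs")
  cliffs <- findCliffs(small, spec, similarityCutoff = 0.8,
                       potencyGapMin = 1)
  fps <- fpBits(featurizeDataset(comp$smiles, spec))
  expected <- 0
  for (i in 1:19) for (j in (i + 1):20) {
    sim <- tanimoto(fps[i, ], fps[j, ])
    if (sim < 0.8) next
    opposing <- (comp$label[i] == "blocker") != (comp$label[j] == "blocker")
    gap <- abs(comp$pic50[i] - comp$pic50[j])
    if (opposing || gap >= 1) expected <- expected + 1
  }
  expect_equal(nrow(cliffs), expected)
  if (nrow(cliffs)) {
    expect_true(all(cliffs$similarity >= 0.8))
    expect_true(all(cliffs$potencyGap >= 1 |
                      (cliffs$labelA == "blocker") !=
                        (cliffs$labelB == "blocker")))
  }
  # identical molecules with identical labels are not cliffs
  twin <- new("CuratedDataset",
              compounds = data.frame(smiles = fxLibrarySmall[1:2],
                                     pic50 = c(5.2, 5.2),
                                     label = c("blocker", "blocker")),
              task = "binary", report = curationReport(ds),
              config = ds@config)
  expect_equal(nrow(findCliffs(twin, spec, 0.99, 1)), 0L)
})

test_that("discontinuity matches the single-pair hand computation", {
  rep0 <- curationReport(curateDataset(fxNoisy, curationConfig("binary")))
  # two compounds, similarity known, delta pIC50 = 3
  smiles <- c("CCCCCCCC", "CCCCCCCCC")  # near-identical alkanes
  spec <- fingerprintSpec("ecfp")
  fps <- fpBits(featurizeDataset(smiles, spec))
  sim <- tanimoto(fps[1, ], fps[2, ])
  ds <- new("CuratedDataset",
            compounds = data.frame(smiles = smiles, pic50 = c(4, 7),
                                   label = c(4, 7)),
            task = "regression", report = rep0,
            config = curationConfig("regression"))
  cd <- continuityDiscontinuity(ds, spec, similarityCutoff = 0.5)
  expect_equal(unname(cd$global["disc"]), 3 * sim, tolerance = 1e-12)
  # identical potencies have zero discontinuity
  ds0 <- new("CuratedDataset",
             compounds = data.frame(smiles = smiles, pic50 = c(5, 5),
                                    label = c(5, 5)),
             task = "regression", report = rep0,
             config = curationConfig("regression"))
  cd0 <- continuityDiscontinuity(ds0, spec, similarityCutoff = 0.5)
  expect_equal(unname(cd0$global["disc"]), 0)
})

test_that("continuity/discontinuity equal brute-force enumeration", {
  ds <- curateDataset(fxNoisy, curationConfig("regression"))
  comp <- compounds(ds)[1:15, ]
  small <- new("CuratedDataset", compounds = comp, task = "regression",
               report = curationReport(ds), config = ds@config)
  spec <- fingerprintSpec("maccs")
  cutoff <- 0.6
  cd <- continuityDiscontinuity(small, spec, cutoff)
  fps <- fpBits(featurizeDataset(comp$smiles, spec))
  n <- nrow(comp)
  for (i in seq_len(n)) {
    num <- den <- 0
    dvals <- numeric(0)
    for (j in seq_len(n)) {
      if (i == j) next
      sim <- max(tanimoto(fps[i, ], fps[j, ]), 1e-6)
      w <- comp$pic50[i] * comp$pic50[j]
      num <- num + w / sim
      den <- den + w
      if (sim >= cutoff)
        dvals <- c(dvals, abs(comp$pic50[i] - comp$pic50[j]) * sim)
    }
    expect_equal(cd$perCompound$cont[i], num / den, tolerance = 1e-9)
    if (length(dvals))
      expect_equal(cd$perCompound$disc[i], mean(dvals), tolerance = 1e-9)
    else expect_true(is.na(cd$perCompound$disc[i]))
  }
})

test_that("2D embedding is deterministic and separates bit clusters", {
  set.seed(41)
  blockA <- cbind(matrix(rbinom(10 * 32, 1, 0.9), 10),
                  matrix(0L, 10, 32))
  blockB <- cbind(matrix(0L, 10, 32),
                  matrix(rbinom(10 * 32, 1, 0.9), 10))
  X <- rbind(blockA, blockB)
  fps <- new("FingerprintMatrix", bits = X,
             spec = fingerprintSpec(nbits = 64),
             ids = sprintf("m%d", 1:20))
  xy <- embed2D(fps, seed = 1)
  expect_equal(dim(xy), c(20L, 2L))
  expect_true(all(is.finite(xy)))
  expect_identical(xy, embed2D(fps, seed = 1))
  within <- as.matrix(dist(xy))[1:10, 1:10]
  across <- as.matrix(dist(xy))[1:10, 11:20]
  expect_gt(mean(across), mean(within[upper.tri(within)]))
  expect_error(embed2D(X[1:3, ]), "at least 5")
})
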