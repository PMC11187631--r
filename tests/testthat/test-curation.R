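test_that("structure standardization strips salts, stereo and flags junk", {
  res <- normalizeStructure(c("CC(=O)[O-].[Na+]", "[Na+].[Cl-]",
                              "C[C@H](N)C(=O)O", "CCO.CCC", "not_smiles"))
  expect_equal(res$smiles[1], canonicalSmiles("CC(=O)O"))
  expect_equal(res$reason[2], "inorganic")
  expect_equal(res$smiles[3], canonicalSmiles("CC(N)C(=O)O"))
  expect_equal(res$reason[4], "mixture")
  expect_equal(res$reason[5], "unparseable")
  # kept structures are canonical fixed points
  kept <- res$smiles[!is.na(res$smiles)]
  expect_equal(canonicalSmiles(kept), kept)
})

test_that("pIC50 conversion is -log10 of the molar IC50", {
  expect_equal(ic50ToPic50(1e-5), 5)
  expect_equal(ic50ToPic50(1e-6), 6)
  # 0.00285 uM, high-precision: 9 - log10(2.85)
  expect_equal(ic50ToPic50(toMolar(0.00285, "uM")), 9 - log10(2.85),
               tolerance = 1e-12)
  expect_equal(ic50ToPic50(toMolar(0.00285, "uM")), 8.545155140,
               tolerance = 1e-9)
  expect_error(ic50ToPic50(0), "positive")
})

test_that("qualifier filter implements the censoring rules at 10 uM", {
  # classification
  expect_equal(applyQualifierFilter("gt", toMolar(5, "uM"), "binary"),
               "exclude")
  expect_equal(applyQualifierFilter("gt", toMolar(10, "uM"), "binary"),
               "keep_as_inactive")
  expect_equal(applyQualifierFilter("gt", toMolar(50, "uM"), "multiclass"),
               "keep_as_inactive")
  expect_equal(applyQualifierFilter("lt", toMolar(8, "uM"), "binary"),
               "keep_as_active")
  expect_equal(applyQualifierFilter("lt", toMolar(10, "uM"), "binary"),
               "keep_as_active")
  expect_equal(applyQualifierFilter("lt", toMolar(20, "uM"), "binary"),
               "exclude")
  expect_equal(applyQualifierFilter("eq", toMolar(3, "uM"), "binary"),
               "keep_as_is")
  # le/ge are treated as their strict counterparts
  expect_equal(applyQualifierFilter("ge", toMolar(10, "uM"), "binary"),
               "keep_as_inactive")
  expect_equal(applyQualifierFilter("le", toMolar(10, "uM"), "multiclass"),
               "keep_as_active")
  # regression excludes every censored record
  expect_equal(applyQualifierFilter("lt", toMolar(3, "uM"), "regression"),
               "exclude")
  expect_equal(applyQualifierFilter("gt", toMolar(50, "uM"), "regression"),
               "exclude")
  expect_equal(applyQualifierFilter("eq", toMolar(3, "uM"), "regression"),
               "keep_as_is")
})

test_that("binary labels split exactly at 10 uM (pIC50 5)", {
  lab <- labelBinary(c(5.0, 5.01, 3.0, 7.2))
  expect_equal(as.character(lab),
               c("nonblocker", "blocker", "nonblocker", "blocker"))
})

test_that("multiclass tiers follow the 6/5 pIC50 boundaries", {
  lab <- labelMulticlass(c(6.0, 5.5, 4.99, 5.0, 7.1))
  expect_equal(as.character(lab),
               c("strong", "moderate_weak", "nonblocker", "moderate_weak",
                 "strong"))
})

test_that("classification duplicates resolve by majority or die together", {
  # unanimous pair keeps one
  r <- deduplicateClassification(c("A", "A"), c(6, 6.2),
                                 c("blocker", "blocker"))
  expect_equal(nrow(r$kept), 1L)
  expect_equal(r$mergedCount, 1L)
  expect_equal(r$removedConflict, 0L)
  # strict majority wins
  r <- deduplicateClassification(rep("A", 3), c(6, 6.2, 4),
                                 c("blocker", "blocker", "nonblocker"))
  expect_equal(r$kept$label, "blocker")
  expect_equal(r$kept$pic50, mean(c(6, 6.2)))
  expect_equal(r$mergedCount, 2L)
  # ties remove the whole group
  r <- deduplicateClassification(c("A", "A", "B"), c(6, 4, 5.5),
                                 c("blocker", "nonblocker", "blocker"))
  expect_equal(r$removedConflict, 2L)
  expect_equal(r$kept$smiles, "B")
})

test_that("regression duplicates are gated on sample SD 0.2 and averaged", {
  r <- deduplicateRegression(c("A", "A"), c(5.0, 5.1))
  expect_equal(r$kept$pic50, 5.05)
  expect_equal(r$removedHighSd, 0L)
  r <- deduplicateRegression(c("A", "A"), c(5.0, 6.0))
  expect_equal(nrow(r$kept), 0L)
  expect_equal(r$removedHighSd, 2L)
  r <- deduplicateRegression("A", 5.3)
  expect_equal(r$kept$pic50, 5.3)
  expect_length(r$duplicateGroups, 0L)
})

test_that("experimental MAE is the record-weighted mean deviation", {
  expect_equal(experimentalMae(list(c(5.0, 5.2))), 0.1)
  expect_equal(experimentalMae(list(c(5.0, 5.0, 5.0))), 0)
  expect_equal(experimentalMae(list(c(5.0, 5.2), c(6.0, 6.4))), 0.15)
  expect_warning(out <- experimentalMae(list(5)), "undefined")
  expect_true(is.na(out))
})

test_that("curation of a hand-built table yields the enumerated report", {
  df <- rbind(
    simpleCsvRow("K1", "Cc1ccc(Cl)cc1", value = 1, units = "uM"),    # keep
    simpleCsvRow("K2", "Oc1ccc(F)cc1", value = 50, units = "uM"),    # keep
    simpleCsvRow("I1", "[Na+].[Cl-]", value = 1, units = "uM"),      # inorganic
    simpleCsvRow("I2", "[Mg+2].[O-2]", value = 1, units = "uM"),     # inorganic
    simpleCsvRow("M1", "CCO.CCC", value = 1, units = "uM"),          # mixture
    simpleCsvRow("Q1", "CCN", relation = ">", value = 5,
                 units = "uM"),                                      # excluded
    simpleCsvRow("D1", "CCCC", value = 1, units = "uM"),             # conflict
    simpleCsvRow("D1b", "CCCC", value = 100, units = "uM"),          # conflict
    simpleCsvRow("S1", "CC(=O)[O-].[Na+]", value = 2, units = "uM"), # keep
    simpleCsvRow("U1", "zzz", value = 1, units = "uM"))              # unparseable
  tab <- readActivityTable(writeSimpleCsv(df), "simple_csv")
  ds <- curateDataset(tab, curationConfig("binary"))
  counts <- removalCounts(ds)
  expect_equal(unname(counts["kept"]), 3L)
  expect_equal(unname(counts["inorganic"]), 2L)
  expect_equal(unname(counts["mixture"]), 1L)
  expect_equal(unname(counts["unparseable"]), 1L)
  expect_equal(unname(counts["qualifier_excluded"]), 1L)
  expect_equal(unname(counts["duplicate_conflict"]), 2L)
  expect_equal(sum(counts), nrow(records(tab)))
})

test_that("curation is idempotent and conserves counts on fixtures", {
  for (task in c("binary", "multiclass", "regression")) {
    ds <- curateDataset(fxNoisy, curationConfig(task))
    counts <- removalCounts(ds)
    expect_equal(sum(counts), nrow(records(fxNoisy)), info = task)
    # a second pass removes nothing
    ds2 <- curateDataset(asActivityTable(ds), curationConfig(task))
    counts2 <- removalCounts(ds2)
    expect_equal(unname(counts2["kept"]), nrow(compounds(ds)), info = task)
    expect_equal(sum(counts2) - counts2[["kept"]], 0L, info = task)
    expect_equal(sort(compounds(ds2)$smiles), sort(compounds(ds)$smiles))
  }
})

test_that("curation is invariant to input row order", {
  recs <- records(fxNoisy)
  set.seed(99)
  shuffled <- activityTable(recs[sample(nrow(recs)), ])
  for (task in c("binary", "regression")) {
    a <- curateDataset(fxNoisy, curationConfig(task))
    b <- curateDataset(shuffled, curationConfig(task))
    expect_equal(removalCounts(a), removalCounts(b), info = task)
    ka <- compounds(a)[order(compounds(a)$smiles), ]
    kb <- compounds(b)[order(compounds(b)$smiles), ]
    rownames(ka) <- rownames(kb) <- NULL
    expect_equal(ka, kb, info = task)
  }
})

test_that("multiclass blockers above pIC50 5 are binary blockers too", {
  bin <- curateDataset(fxNoisy, curationConfig("binary"))
  mc <- curateDataset(fxNoisy, curationConfig("multiclass"))
  cb <- compounds(bin); cm <- compounds(mc)
  shared <- intersect(cb$smiles, cm$smiles)
  labB <- cb$label[match(shared, cb$smiles)]
  labM <- cm$label[match(shared, cm$smiles)]
  picM <- cm$pic50[match(shared, cm$smiles)]
  isBlockerM <- labM %in% c("strong", "moderate_weak")
  # the single documented exception is the shared boundary pIC50 = 5
  violations <- isBlockerM & labB == "nonblocker" & picM != 5
  expect_equal(sum(violations), 0L)
})

test_that("curating an empty table is an error", {
  expect_error(curateDataset(activityTable(data.frame())), "empty")
})
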