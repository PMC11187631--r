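# Shared fixtures, built once per test run. Everything is generated in code
# (no bundled data) and deterministic under the fixed seeds.

FX_SEED <- 11L

# small synthetic library for chemistry-level tests
fxLibrarySmall <- makeLibrary(30, seed = FX_SEED)

# noise-free planted-signal table: labels are an exact function of the
# signal bits, so model recovery and curation counts are analytic
fxClean <- plantActivity(
  makeLibrary(240, seed = FX_SEED),
  fixtureSpec(nCompounds = 240, noiseSd = 0, seed = FX_SEED))

# noisy table with all anomaly types for curation-report tests
fxNoisy <- plantActivity(
  makeLibrary(120, seed = FX_SEED + 1L),
  fixtureSpec(nCompounds = 120, noiseSd = 0.3, seed = FX_SEED + 1L))

fxBinaryClean <- curateDataset(fxClean, curationConfig("binary"))
fxFpsClean <- featurizeDataset(fxBinaryClean, fingerprintSpec(),
                               ids = compounds(fxBinaryClean)$smiles)
fxSplitClean <- stratifiedSplit(compounds(fxBinaryClean)$label, 0.2,
                                seed = 42)

# one trained binary gradient-boosted model shared by modeling/interpret/AD
# tests (modest size keeps the suite fast)
fxBinaryModel <- trainModel(
  "binary", "gbt_light",
  new("FingerprintMatrix",
      bits = fpBits(fxFpsClean)[fxSplitClean$train, , drop = FALSE],
      spec = fingerprintSpec(),
      ids = compounds(fxBinaryClean)$smiles[fxSplitClean$train]),
  compounds(fxBinaryClean)$label[fxSplitClean$train],
  hyperparameters = list(nrounds = 60), seed = 1)

# write a simple_csv activity file; returns the path
writeSimpleCsv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  path
}

simpleCsvRow <- function(id, smiles, relation = "=", value = 10,
                         units = "uM", assay = "SP") {
  data.frame(compound_id = id, smiles = smiles, assay_type = assay,
             relation = relation, value = value, units = units,
             stringsAsFactors = FALSE)
}
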