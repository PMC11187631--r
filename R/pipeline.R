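## End-to-end orchestration: curate -> featurize -> split -> train the three
## tasks -> predict -> applicability domain -> weighted consensus, with the
## run configuration serialized next to every output for provenance.

#' Default run configuration
#'
#' @param input path to a bioactivity CSV (or NULL to use a synthetic
#'   fixture).
#' @param dialect input dialect for [readActivityTable()].
#' @param outDir output directory (created if needed); NULL disables
#'   writing.
#' @param seed master seed: the 80/20 split uses it directly and model
#'   fits derive from it.
#' @param fingerprint list(family, radius, nbits).
#' @param algorithms named list: algorithm per task.
#' @param testFraction held-out fraction.
#' @param adK,adZ applicability-domain settings.
#' @param consensus a [ConsensusConfig-class].
#' @param fixture a [fixtureSpec()] used when `input` is NULL.
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(input = NULL, dialect = "simple_csv", outDir = NULL,
                      seed = 42L,
                      fingerprint = list(family = "ecfp", radius = 2L,
                                         nbits = 1024L),
                      algorithms = list(binary = "gbt_light",
                                        multiclass = "random_forest",
                                        regression = "svm"),
                      testFraction = 0.2, adK = 1L, adZ = 0.5,
                      consensus = consensusConfig(),
                      fixture = fixtureSpec()) {
  structure(list(input = input, dialect = dialect, outDir = outDir,
                 seed = as.integer(seed), fingerprint = fingerprint,
                 algorithms = algorithms, testFraction = testFraction,
                 adK = as.integer(adK), adZ = adZ, consensus = consensus,
                 fixture = fixture),
            class = "RunConfig")
}

#' Predict a set of compounds with the three-task model suite
#'
#' Featurizes the queries once per distinct fingerprint spec, runs the
#' binary, multiclass and regression models, checks the applicability
#' domain of each, and appends the weighted consensus score and call.
#'
#' @param models named list with elements `binary`, `multiclass`,
#'   `regression` ([HergModel-class] objects).
#' @param smiles character vector of query SMILES.
#' @param consensus a [ConsensusConfig-class].
#' @return data.frame: one row per query with per-model labels, predicted
#'   pIC50, AD flags, consensus score and call.
#' @export
predictCompounds <- function(models, smiles, consensus = consensusConfig()) {
  stopifnot(all(c("binary", "multiclass", "regression") %in% names(models)))
  fpCache <- list()
  getFps <- function(model) {
    key <- paste(fpSpec(model)@family, fpSpec(model)@nbits)
    if (is.null(fpCache[[key]]))
      fpCache[[key]] <<- featurizeDataset(smiles, fpSpec(model),
                                          ids = sprintf("q%d",
                                                        seq_along(smiles)))
    fpCache[[key]]
  }
  fb <- getFps(models$binary)
  binLab <- as.character(predict(models$binary, fb, type = "label"))
  binProb <- predict(models$binary, fb, type = "response")
  fm <- getFps(models$multiclass)
  mcLab <- as.character(predict(models$multiclass, fm, type = "label"))
  fr <- getFps(models$regression)
  pic50 <- predict(models$regression, fr)
  regLab <- as.character(regressionToLabel(pic50))
  cons <- consensusScore(binLab, mcLab, regLab, consensus)
  adOf <- function(model, fps) {
    if (is.null(model@ad)) rep(NA, length(smiles))
    else inDomain(model@ad, fps)$inDomain
  }
  data.frame(smiles = smiles,
             binaryLabel = binLab, binaryProb = binProb,
             multiclassLabel = mcLab,
             predictedPic50 = pic50, regressionLabel = regLab,
             adBinary = adOf(models$binary, fb),
             adMulticlass = adOf(models$multiclass, fm),
             adRegression = adOf(models$regression, fr),
             consensusScore = cons$score, consensusCall = cons$call,
             stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' Reads (or synthesizes) a bioactivity table, curates it once per task,
#' trains the three models on a stratified 80/20 split, evaluates them on
#' their test sets, and produces the per-compound prediction report over all
#' curated (binary-task) compounds with applicability-domain flags and the
#' weighted consensus. When `config$outDir` is set, writes report.csv, metrics.json,
#' models/*.rds and the serialized config.yaml for provenance.
#'
#' @param config a [runConfig()].
#' @return list with `report` (data.frame), `metrics`, `models`,
#'   `datasets` and `config`.
#' @export
runPipeline <- function(config = runConfig()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  table <- stage("input", {
    if (!is.null(config$input))
      readActivityTable(config$input, config$dialect)
    else plantActivity(makeLibrary(config$fixture$nCompounds,
                                   config$fixture$seed), config$fixture)
  })
  spec <- fingerprintSpec(config$fingerprint$family,
                          config$fingerprint$radius,
                          config$fingerprint$nbits)
  tasks <- c("binary", "multiclass", "regression")
  datasets <- stage("curate", lapply(stats::setNames(tasks, tasks),
    function(t) curateDataset(table, curationConfig(t))))
  models <- list(); metrics <- list(); testSmiles <- NULL
  for (t in tasks) {
    ds <- datasets[[t]]
    comp <- compounds(ds)
    y <- if (t == "regression") comp$pic50 else comp$label
    fps <- stage(paste0("featurize:", t),
                 featurizeDataset(ds, spec, ids = comp$smiles))
    split <- stage(paste0("split:", t),
                   stratifiedSplit(y, config$testFraction,
                                   seed = config$seed, task = t))
    Xtr <- fpBits(fps)[split$train, , drop = FALSE]
    Xte <- fpBits(fps)[split$test, , drop = FALSE]
    m <- stage(paste0("train:", t), trainModel(
      t, config$algorithms[[t]],
      new("FingerprintMatrix", bits = Xtr, spec = spec,
          ids = comp$smiles[split$train]),
      y[split$train],
      seed = config$seed + match(t, tasks), adK = config$adK,
      adZ = config$adZ))
    metrics[[t]] <- stage(paste0("evaluate:", t), {
      if (t == "regression") {
        evaluateRegression(y[split$test], predict(m, Xte))
      } else {
        evaluateClassification(
          y[split$test], as.character(predict(m, Xte, type = "label")),
          scores = predict(m, Xte, type = "prob"),
          positive = "blocker")
      }
    })
    m@metrics <- metrics[[t]]
    models[[t]] <- m
    if (t == "binary") reportSmiles <- comp$smiles
  }
  report <- stage("predict",
                  predictCompounds(models, reportSmiles, config$consensus))
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(config$outDir, "models"), showWarnings = FALSE)
    utils::write.csv(report, file.path(config$outDir, "report.csv"),
                     row.names = FALSE)
    jsonlite::write_json(metrics, file.path(config$outDir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    for (t in tasks)
      saveHergModel(models[[t]],
                    file.path(config$outDir, "models", paste0(t, ".rds")))
    serializable <- config
    serializable$consensus <- list(
      wBinary = config$consensus@wBinary, wAgree = config$consensus@wAgree,
      wDisagree = config$consensus@wDisagree,
      threshold = config$consensus@threshold)
    serializable$fixture <- unclass(config$fixture)
    serializable$fixture$fingerprint <- list(
      family = config$fixture$fingerprint@family,
      radius = config$fixture$fingerprint@radius,
      nbits = config$fixture$fingerprint@nbits)
    yaml::write_yaml(unclass(serializable),
                     file.path(config$outDir, "config.yaml"))
  }
  list(report = report, metrics = metrics, models = models,
       datasets = datasets, config = config)
}
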