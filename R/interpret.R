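## Shapley-value attribution: exact TreeSHAP (via the gradient-boosting
## backend) for tree models, a seeded permutation-sampling estimator for the
## others, global importance summaries, and projection of bit attributions
## onto atoms for fragment contribution maps.

# permutation-sampling Shapley estimate for one instance x against a
# background sample; predfun maps a matrix of rows to numeric outputs.
# Only features differing from the background row can carry credit, so the
# permutation walk is restricted to them.
.samplingShapRow <- function(predfun, x, background, nsim) {
  phi <- numeric(length(x))
  nb <- nrow(background)
  for (s in seq_len(nsim)) {
    b <- background[(s - 1L) %% nb + 1L, ]
    diff <- which(x != b)
    if (length(diff) == 0L) next
    perm <- diff[sample.int(length(diff))]
    cur <- b
    prev <- predfun(matrix(cur, nrow = 1L))
    for (j in perm) {
      cur[j] <- x[j]
      val <- predfun(matrix(cur, nrow = 1L))
      phi[j] <- phi[j] + (val - prev)
      prev <- val
    }
  }
  phi / nsim
}

#' Shapley-value bit attributions
#'
#' Decomposes each compound's model output into additive per-bit
#' contributions plus a base value. Gradient-boosting models use the exact
#' tree-path algorithm (attributions are on the raw margin scale and satisfy
#' base + row sum = margin output). Other learners use a seeded
#' permutation-sampling approximation on the probability (or response)
#' scale against a background sample of the supplied matrix.
#'
#' @param model a [HergModel-class] (binary or regression; multiclass
#'   attribution is supported for sampling only, against the blocker-side
#'   probability mass).
#' @param X a [FingerprintMatrix-class] or 0/1 matrix to explain.
#' @param nsim permutations per compound for the sampling method.
#' @param backgroundSize background rows for the sampling method.
#' @param seed RNG seed for the sampling method.
#' @return An [AttributionMatrix-class].
#' @export
shapAttributions <- function(model, X, nsim = 50L, backgroundSize = 20L,
                             seed = 1L) {
  Xm <- .asBitMatrix(X)
  ids <- if (is(X, "FingerprintMatrix")) compoundIds(X)
         else sprintf("cpd%d", seq_len(nrow(Xm)))
  if (model@fit$kind == "xgb" && model@task != "multiclass") {
    booster <- .xgbBooster(model@fit)
    contrib <- predict(booster, xgboost::xgb.DMatrix(Xm),
                       predcontrib = TRUE)
    base <- contrib[, ncol(contrib)]
    values <- contrib[, -ncol(contrib), drop = FALSE]
    colnames(values) <- colnames(Xm)
    return(new("AttributionMatrix", values = values,
               baseValue = mean(base), ids = ids, method = "tree_exact"))
  }
  predfun <- if (model@task == "regression") {
    function(m) .predictLearner(model@fit, model@task, model@classLevels,
                                m)$response
  } else if (length(model@classLevels) == 2L) {
    function(m) .predictLearner(model@fit, model@task, model@classLevels,
                                m)$prob[, model@classLevels[2L]]
  } else {
    blockers <- setdiff(model@classLevels, "nonblocker")
    function(m) rowSums(.predictLearner(model@fit, model@task,
                                        model@classLevels,
                                        m)$prob[, blockers, drop = FALSE])
  }
  set.seed(seed)
  bgIdx <- sample.int(nrow(Xm), min(backgroundSize, nrow(Xm)))
  background <- Xm[bgIdx, , drop = FALSE]
  base <- mean(predfun(background))
  values <- matrix(0, nrow(Xm), ncol(Xm), dimnames = dimnames(Xm))
  for (i in seq_len(nrow(Xm))) {
    values[i, ] <- .samplingShapRow(predfun, Xm[i, ], background, nsim)
  }
  new("AttributionMatrix", values = values, baseValue = base, ids = ids,
      method = "sampling")
}

#' Global feature importance from attributions
#'
#' Ranks bits by mean absolute Shapley value over the explained compounds,
#' ties broken by bit index; the sign tendency is the mean sign of the
#' nonzero attributions (positive = pushes towards blocker).
#'
#' @param attr an [AttributionMatrix-class].
#' @param topN number of bits to return (capped at the bit count).
#' @return data.frame with columns bit (1-based index), meanAbs,
#'   signTendency.
#' @export
globalImportance <- function(attr, topN = 20L) {
  v <- attributions(attr)
  if (nrow(v) == 0L) stop("empty attribution matrix")
  meanAbs <- colMeans(abs(v))
  signT <- apply(v, 2, function(col) {
    nz <- col[col != 0]
    if (length(nz) == 0L) 0 else mean(sign(nz))
  })
  ord <- order(-meanAbs, seq_along(meanAbs))
  take <- seq_len(min(topN, length(ord)))
  data.frame(bit = ord[take], meanAbs = meanAbs[ord[take]],
             signTendency = signT[ord[take]], row.names = NULL)
}

#' Per-atom fragment contribution map
#'
#' Projects bit attributions onto atoms: each on-bit's attribution is split
#' equally among the atom environments that set it (bit collisions share the
#' mass) and, within an environment, equally among its atoms. The atom
#' weights therefore sum exactly to the total on-bit attribution
#' (conservation). With `method = "masking"` the weight is instead the drop
#' in blocker probability when the atom's bits are cleared from the
#' fingerprint.
#'
#' @param model a [HergModel-class] trained on a hashed circular
#'   fingerprint.
#' @param smiles a single SMILES string.
#' @param method `"shap"` (default) or `"masking"`.
#' @param ... passed to [shapAttributions()] (sampling controls).
#' @return An [AtomAttributionMap-class].
#' @export
atomAttribution <- function(model, smiles, method = c("shap", "masking"),
                            ...) {
  method <- match.arg(method)
  spec <- fpSpec(model)
  if (spec@family == "maccs")
    stop("atom attribution needs a hashed circular fingerprint model")
  canon <- canonicalSmiles(smiles)
  if (is.na(canon)) stop("unparseable SMILES: ", smiles)
  fp <- .fingerprintCanonical(canon, spec)
  bam <- bitAtomMap(canon, spec)
  natoms <- length(molecularGraph(canon)$symbol)
  weights <- numeric(natoms)
  if (method == "shap") {
    X <- matrix(fp, nrow = 1L,
                dimnames = list(canon, sprintf("bit%d", seq_along(fp))))
    attr <- shapAttributions(model, X, ...)
    onBits <- which(fp == 1L)
    bitAttr <- stats::setNames(attributions(attr)[1L, onBits],
                               sprintf("b%d", onBits))
    for (bit in names(bitAttr)) {
      envs <- bam[[bit]]
      if (is.null(envs)) next
      share <- bitAttr[[bit]] / length(envs)
      for (env in envs)
        weights[env] <- weights[env] + share / length(env)
    }
    return(new("AtomAttributionMap", smiles = canon, weights = weights,
               bitAttributions = bitAttr, method = "shap"))
  }
  # masking: clear each atom's bits and measure the probability drop
  predProb <- function(m) {
    if (model@task == "regression")
      .predictLearner(model@fit, model@task, model@classLevels, m)$response
    else .predictLearner(model@fit, model@task, model@classLevels,
                         m)$prob[, setdiff(model@classLevels, "nonblocker"),
                                 drop = FALSE] |> rowSums()
  }
  p0 <- predProb(matrix(fp, nrow = 1L))
  onBits <- which(fp == 1L)
  bitNames <- sprintf("b%d", onBits)
  for (a in seq_len(natoms)) {
    touches <- vapply(bitNames, function(bn) {
      envs <- bam[[bn]]
      !is.null(envs) && any(vapply(envs, function(e) a %in% e, logical(1)))
    }, logical(1))
    if (!any(touches)) next
    masked <- fp
    masked[onBits[touches]] <- 0L
    weights[a] <- p0 - predProb(matrix(masked, nrow = 1L))
  }
  new("AtomAttributionMap", smiles = canon, weights = weights,
      bitAttributions = stats::setNames(rep(NA_real_, length(onBits)),
                                        bitNames),
      method = "masking")
}

#' Export an atom attribution map as JSON
#'
#' @param map an [AtomAttributionMap-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAtomAttribution <- function(map, path) {
  jsonlite::write_json(list(smiles = map@smiles,
                            weights = map@weights,
                            method = map@method),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
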