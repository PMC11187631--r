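## Synthetic bioactivity generator: a drug-like SMILES library from scaffold
## x substituent enumeration, a planted fingerprint-bit -> activity signal
## with Gaussian noise, and controlled injection of the anomalies the
## curation stage must handle (duplicates, conflicting duplicates, censored
## qualifiers, salt forms). Everything is bookkept so curation outcomes are
## checkable in closed form.

# substituents in suffix form (inside parentheses) and the equivalent
# prefix form (attachment atom written last, so "Xc1..." bonds correctly)
.SUB_SUFFIX <- c("C", "CC", "CCC", "CO", "CCO", "OC", "OCC",
                 "N", "NC", "CN", "CCN", "F", "Cl", "Br", "I", "C#N",
                 "C(F)(F)F", "C(=O)O", "C(=O)N", "S", "SC")
.SUB_PREFIX <- c("C", "CC", "CCC", "CO", "CCO", "OC", "OCC",
                 "N", "NC", "CN", "CCN", "F", "Cl", "Br", "I", "N#C",
                 "FC(F)(F)", "C(=O)O", "C(=O)N", "S", "SC")

.TEMPLATES <- list(
  function(x, y) paste0(x, "c1ccc(", y, ")cc1"),      # para-benzene
  function(x, y) paste0(x, "c1ccc(", y, ")cn1"),      # pyridine
  function(x, y) paste0(x, "C(=O)Nc1ccc(", y, ")cc1") # anilide
)

#' Enumerate a synthetic compound library
#'
#' Produces `n` distinct, valid, drug-like SMILES by combining built-in
#' scaffolds (benzene, pyridine, anilide) with substituent pairs, then
#' canonicalizing and deduplicating. Enumeration order is shuffled
#' deterministically by the seed.
#'
#' @param n number of compounds.
#' @param seed RNG seed.
#' @return character vector of `n` distinct canonical SMILES.
#' @export
makeLibrary <- function(n, seed = 1L) {
  stopifnot(n >= 1L)
  combos <- expand.grid(t = seq_along(.TEMPLATES),
                        x = seq_along(.SUB_PREFIX),
                        y = seq_along(.SUB_SUFFIX), stringsAsFactors = FALSE)
  raw <- vapply(seq_len(nrow(combos)), function(i)
    .TEMPLATES[[combos$t[i]]](.SUB_PREFIX[combos$x[i]],
                              .SUB_SUFFIX[combos$y[i]]), character(1))
  set.seed(seed)
  raw <- raw[sample.int(length(raw))]
  out <- character(0)
  taken <- 0L
  step <- max(4L * n, 64L)
  while (length(out) < n && taken < length(raw)) {
    chunk <- raw[seq(taken + 1L, min(taken + step, length(raw)))]
    taken <- taken + length(chunk)
    canon <- canonicalSmiles(chunk)
    canon <- canon[!is.na(canon)]
    out <- unique(c(out, canon))
  }
  if (length(out) < n)
    stop("requested ", n, " compounds but only ", length(out),
         " distinct structures are enumerable")
  out[seq_len(n)]
}

#' Fixture generation settings
#'
#' Defaults define the reference synthetic study conditions: a latent
#' activity with intercept pIC50 4.5 (below every class boundary, so
#' unexposed compounds are nonblockers), 1.5 pIC50 units per planted
#' signal bit, Gaussian noise SD 0.3, and modest anomaly fractions.
#'
#' @param nCompounds library size.
#' @param signalBits integer bit indices (1-based) carrying the activity
#'   signal; when NULL, `nSignalBits` bits of intermediate prevalence are
#'   chosen deterministically from the library.
#' @param nSignalBits number of signal bits to auto-pick.
#' @param effectPerBit pIC50 increase per set signal bit.
#' @param noiseSd Gaussian noise SD on the latent pIC50.
#' @param duplicateFraction fraction of compounds duplicated with identical
#'   values.
#' @param conflictFraction fraction duplicated with an opposing-class value.
#' @param qualifierFraction fraction turned into censored (`<`/`>`) records
#'   that every task must exclude.
#' @param saltFraction fraction rewritten as a sodium-salt form (same
#'   structure after standardization).
#' @param seed RNG seed.
#' @param fingerprint [FingerprintSpec-class] defining the signal bits.
#' @return list of class `FixtureSpec`.
#' @export
fixtureSpec <- function(nCompounds = 300L, signalBits = NULL,
                        nSignalBits = 2L, effectPerBit = 1.5,
                        noiseSd = 0.3, duplicateFraction = 0.1,
                        conflictFraction = 0.05, qualifierFraction = 0.05,
                        saltFraction = 0.05, seed = 1L,
                        fingerprint = fingerprintSpec()) {
  fr <- c(duplicateFraction, conflictFraction, qualifierFraction,
          saltFraction)
  stopifnot(all(fr >= 0 & fr <= 1), noiseSd >= 0, effectPerBit >= 0,
            nCompounds >= 1L)
  structure(list(nCompounds = as.integer(nCompounds),
                 signalBits = signalBits, nSignalBits = as.integer(nSignalBits),
                 effectPerBit = effectPerBit, noiseSd = noiseSd,
                 duplicateFraction = duplicateFraction,
                 conflictFraction = conflictFraction,
                 qualifierFraction = qualifierFraction,
                 saltFraction = saltFraction, seed = as.integer(seed),
                 fingerprint = fingerprint),
            class = "FixtureSpec")
}

#' Generate a synthetic bioactivity table with a planted signal
#'
#' Assigns every library compound a latent pIC50 of
#' 4.5 + effectPerBit * (number of its set signal bits) + N(0, noiseSd),
#' emits one measurement per compound in uM with a random assay context,
#' then injects (on disjoint compound subsets, sizes `round(n * fraction)`)
#' exact duplicates, conflicting duplicates (a second measurement on the
#' other side of 10 uM), censored qualifier records (rewritten so every
#' task excludes them) and sodium-salt forms. The returned table's `truth`
#' slot records per-row roles and the closed-form expected curation counts
#' per task.
#'
#' @param library character vector of canonical SMILES (see
#'   [makeLibrary()]).
#' @param spec a [fixtureSpec()].
#' @return An [ActivityTable-class] with populated `truth`.
#' @export
plantActivity <- function(library, spec = fixtureSpec()) {
  n <- length(library)
  set.seed(spec$seed)
  fps <- featurizeDataset(library, spec$fingerprint)
  bits <- fpBits(fps)
  signalBits <- spec$signalBits
  if (is.null(signalBits)) {
    prev <- colMeans(bits)
    cand <- which(prev >= 0.15 & prev <= 0.6)
    if (length(cand) < spec$nSignalBits)
      cand <- order(abs(prev - 0.3))[seq_len(spec$nSignalBits)]
    signalBits <- cand[order(abs(prev[cand] - 0.3),
                             cand)][seq_len(spec$nSignalBits)]
  }
  signalCount <- unname(rowSums(bits[, signalBits, drop = FALSE]))
  latent <- 4.5 + spec$effectPerBit * signalCount +
    stats::rnorm(n, 0, spec$noiseSd)
  value <- 10^(6 - latent)  # uM; pIC50 = -log10(value * 1e-6) = latent
  assay <- sample(c("SP", "HEK", "CHO"), n, replace = TRUE)
  ids <- sprintf("FX%04d", seq_len(n))

  nDup <- round(n * spec$duplicateFraction)
  nConf <- round(n * spec$conflictFraction)
  nQual <- round(n * spec$qualifierFraction)
  nSalt <- round(n * spec$saltFraction)
  if (nDup + nConf + nQual + nSalt > n)
    stop("anomaly fractions overlap: they must sum to at most 1")
  pool <- sample.int(n)
  dupIdx <- pool[seq_len(nDup)]
  confIdx <- pool[nDup + seq_len(nConf)]
  qualIdx <- pool[nDup + nConf + seq_len(nQual)]
  saltIdx <- pool[nDup + nConf + nQual + seq_len(nSalt)]

  role <- rep("base", n)
  role[dupIdx] <- "duplicated"
  role[confIdx] <- "conflicted"
  role[qualIdx] <- "qualifier"
  role[saltIdx] <- "salt"

  smiles <- library
  smiles[saltIdx] <- paste0(smiles[saltIdx], ".[Na+]")
  relation <- rep("eq", n)
  relation[qualIdx] <- ifelse(value[qualIdx] > 10, "lt", "gt")

  recs <- data.frame(compoundId = ids, smiles = smiles, assayType = assay,
                     relation = relation, value = value,
                     units = "uM", stringsAsFactors = FALSE)
  extra <- data.frame()
  if (nDup) extra <- rbind(extra, recs[dupIdx, ])
  if (nConf) {
    conf <- recs[confIdx, ]
    conf$value <- ifelse(latent[confIdx] > 5, 100, 1)  # flip the class
    extra <- rbind(extra, conf)
  }
  all <- rbind(recs, extra)
  rownames(all) <- NULL

  expected <- function(task) {
    counts <- stats::setNames(integer(length(REMOVAL_RULES)), REMOVAL_RULES)
    counts["qualifier_excluded"] <- nQual
    counts["duplicate_merged"] <- nDup
    if (task == "regression") counts["duplicate_high_sd"] <- 2L * nConf
    else counts["duplicate_conflict"] <- 2L * nConf
    c(counts, kept = n - nConf - nQual)
  }
  truth <- list(
    role = role, latent = latent, signalBits = signalBits,
    signalCount = signalCount,
    blocker = latent > 5,
    nInput = nrow(all),
    expectedCounts = list(binary = expected("binary"),
                          multiclass = expected("multiclass"),
                          regression = expected("regression")))
  activityTable(all, provenance = "synthetic:plantActivity", truth = truth)
}

#' Reference worked-example records
#'
#' Four bundled measurements spanning the activity scale, from a deeply
#' inactive 75,000 uM to a 2.85 nM strong blocker, attached to simple
#' synthetic stand-in structures. Useful for demonstrating unit conversion,
#' pIC50 arithmetic and labeling.
#'
#' @return An [ActivityTable-class] with four records.
#' @export
workedExamples <- function() {
  recs <- data.frame(
    compoundId = c("EX1", "EX2", "EX3", "EX4"),
    smiles = c("Cc1ccc(Cl)cc1", "Oc1ccc(Cl)cc1",
               "Nc1ccc(F)cc1", "Cc1ccc(Br)cc1"),
    assayType = "SP", relation = "eq",
    value = c(75000, 579, 23.5, 0.00285), units = "uM",
    stringsAsFactors = FALSE)
  activityTable(recs, provenance = "synthetic:workedExamples")
}
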