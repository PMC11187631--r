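#' @import methods
NULL

RECORD_COLUMNS <- c("compoundId", "smiles", "assayType", "relation",
                    "value", "units", "pic50")

# guard band for threshold comparisons on the pIC50 scale: far below any
# meaningful activity difference, wide enough to absorb unit-conversion
# round-off (e.g. 10 * 1e-6 != 1e-5 in binary floating point)
.PIC50_TOL <- 1e-12

REMOVAL_RULES <- c("unparseable", "inorganic", "mixture", "qualifier_excluded",
                   "duplicate_conflict", "duplicate_high_sd", "duplicate_merged")

BINARY_LEVELS     <- c("nonblocker", "blocker")
MULTICLASS_LEVELS <- c("nonblocker", "moderate_weak", "strong")
REGRESSION_LEVELS <- c("nonblocker", "weak", "moderate", "strong")

#' Fingerprint specification
#'
#' Describes a molecular fingerprint: the family (`ecfp` or `fcfp` hashed
#' circular fingerprints, or the 166 `maccs` structural keys), the circular
#' radius (diameter 4 = radius 2 for the usual ECFP-4/FCFP-4) and the number
#' of hashed bits. For `maccs` the bit count is fixed at 166.
#'
#' @slot family character, one of `"ecfp"`, `"fcfp"`, `"maccs"`.
#' @slot radius integer bond radius of the atom environments (hashed families).
#' @slot nbits integer length of the bit vector.
#' @export
setClass("FingerprintSpec",
  representation(family = "character", radius = "integer", nbits = "integer"),
  prototype(family = "ecfp", radius = 2L, nbits = 1024L))

setValidity("FingerprintSpec", function(object) {
  msg <- character()
  if (length(object@family) != 1L ||
      !object@family %in% c("ecfp", "fcfp", "maccs"))
    msg <- c(msg, "family must be one of 'ecfp', 'fcfp', 'maccs'")
  if (length(object@radius) != 1L || is.na(object@radius) || object@radius < 0L)
    msg <- c(msg, "radius must be a non-negative integer")
  if (length(object@nbits) != 1L || is.na(object@nbits) || object@nbits < 1L)
    msg <- c(msg, "nbits must be a positive integer")
  if (length(msg) == 0L && object@family == "maccs" && object@nbits != 166L)
    msg <- c(msg, "maccs fingerprints have exactly 166 bits")
  if (length(msg) == 0L && object@family != "maccs" &&
      bitwAnd(object@nbits, object@nbits - 1L) != 0L)
    msg <- c(msg, "nbits must be a power of two for hashed families")
  if (length(msg)) msg else TRUE
})

#' Construct a FingerprintSpec
#'
#' @param family fingerprint family: `"ecfp"`, `"fcfp"` or `"maccs"`.
#' @param radius environment radius in bonds (default 2, i.e. ECFP-4).
#' @param nbits hashed vector length (1024 or 2048 are conventional); ignored
#'   for `"maccs"`, which always has 166 keys.
#' @return A [FingerprintSpec-class] object.
#' @examples
#' fingerprintSpec("ecfp", radius = 2, nbits = 1024)
#' @export
fingerprintSpec <- function(family = c("ecfp", "fcfp", "maccs"),
                            radius = 2L, nbits = 1024L) {
  family <- match.arg(family)
  if (family == "maccs") nbits <- 166L
  new("FingerprintSpec", family = family, radius = as.integer(radius),
      nbits = as.integer(nbits))
}

#' Bioactivity table
#'
#' One assay measurement per row (compound id, SMILES, assay context,
#' relation qualifier, IC50 value and units, derived pIC50). Rows rejected at
#' parse time are retained in `rejects` with a reason, never silently dropped.
#' `truth` carries generator bookkeeping for synthetic tables.
#'
#' @slot records data.frame with columns compoundId, smiles, assayType,
#'   relation, value, units, pic50.
#' @slot rejects data.frame with columns row, reason (plus the raw fields).
#' @slot provenance free-text description of the source.
#' @slot truth list of ground-truth bookkeeping for synthetic fixtures.
#' @export
setClass("ActivityTable",
  representation(records = "data.frame", rejects = "data.frame",
                 provenance = "character", truth = "list"),
  prototype(records = data.frame(), rejects = data.frame(),
            provenance = "", truth = list()))

setValidity("ActivityTable", function(object) {
  if (nrow(object@records) &&
      !all(RECORD_COLUMNS %in% colnames(object@records)))
    return(paste("records must have columns:",
                 paste(RECORD_COLUMNS, collapse = ", ")))
  if (nrow(object@records) && any(!is.na(object@records$value) &
                                  object@records$value <= 0))
    return("all IC50 values must be positive")
  TRUE
})

#' Curation configuration
#'
#' Thresholds governing labeling and duplicate resolution. The binary split is
#' at IC50 10 uM (pIC50 5): IC50 >= 10 uM is nonblocker. Multiclass adds
#' strong (pIC50 >= 6) and moderate/weak ([5, 6)) tiers. Regression duplicate
#' groups whose pIC50 sample standard deviation exceeds `dupSdMax` are dropped.
#'
#' @slot inactiveIc50 molar IC50 at/above which a compound is inactive (1e-5).
#' @slot strongPic50 pIC50 lower bound of the strong-blocker tier (6).
#' @slot moderatePic50 pIC50 lower bound of the moderate/weak tier (5).
#' @slot dupSdMax maximum pIC50 sample SD tolerated in a regression
#'   duplicate group (0.2).
#' @slot task one of `"binary"`, `"multiclass"`, `"regression"`.
#' @export
setClass("CurationConfig",
  representation(inactiveIc50 = "numeric", strongPic50 = "numeric",
                 moderatePic50 = "numeric", dupSdMax = "numeric",
                 task = "character"),
  prototype(inactiveIc50 = 1e-5, strongPic50 = 6, moderatePic50 = 5,
            dupSdMax = 0.2, task = "binary"))

setValidity("CurationConfig", function(object) {
  msg <- character()
  if (!object@task %in% c("binary", "multiclass", "regression"))
    msg <- c(msg, "task must be binary, multiclass or regression")
  if (!isTRUE(object@strongPic50 > object@moderatePic50))
    msg <- c(msg, "strongPic50 must exceed moderatePic50")
  if (!isTRUE(object@dupSdMax > 0))
    msg <- c(msg, "dupSdMax must be positive")
  if (!isTRUE(object@inactiveIc50 > 0))
    msg <- c(msg, "inactiveIc50 must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a CurationConfig
#'
#' @param task dataset flavor to curate towards.
#' @param inactiveIc50 molar inactivity threshold (default 1e-5, i.e. 10 uM).
#' @param strongPic50,moderatePic50 multiclass tier bounds (defaults 6 and 5).
#' @param dupSdMax regression duplicate pIC50 SD gate (default 0.2).
#' @return A [CurationConfig-class] object.
#' @export
curationConfig <- function(task = c("binary", "multiclass", "regression"),
                           inactiveIc50 = 1e-5, strongPic50 = 6,
                           moderatePic50 = 5, dupSdMax = 0.2) {
  new("CurationConfig", inactiveIc50 = inactiveIc50,
      strongPic50 = strongPic50, moderatePic50 = moderatePic50,
      dupSdMax = dupSdMax, task = match.arg(task))
}

#' Curation report
#'
#' Per-rule removal counts for one curation run. The counts plus `kept`
#' always sum to the number of input records (`nInput`); `duplicate_merged`
#' counts rows collapsed into a retained representative during duplicate
#' resolution, so the balance is exact.
#'
#' @slot counts named integer vector over the removal rules plus `kept`.
#' @slot nInput integer number of input records.
#' @slot experimentalMae numeric; mean absolute deviation from the group mean
#'   over regression duplicate groups (the experimental error), NA when there
#'   were no duplicate groups.
#' @export
setClass("CurationReport",
  representation(counts = "integer", nInput = "integer",
                 experimentalMae = "numeric"),
  prototype(counts = integer(), nInput = 0L, experimentalMae = NA_real_))

setValidity("CurationReport", function(object) {
  need <- c(REMOVAL_RULES, "kept")
  if (!all(need %in% names(object@counts)))
    return("counts must cover every removal rule plus 'kept'")
  if (any(object@counts < 0L)) return("counts must be non-negative")
  if (sum(object@counts) != object@nInput)
    return("removal counts plus kept must equal the input record count")
  TRUE
})

#' Curated dataset
#'
#' Deduplicated, labeled compounds for one modeling task, with the
#' [CurationReport-class] documenting what was removed and why. No two
#' compounds share a canonical SMILES.
#'
#' @slot compounds data.frame with columns smiles, pic50, label (label is a
#'   class label for classification tasks and equals pic50 for regression).
#' @slot task the modeling task the labels target.
#' @slot report a [CurationReport-class].
#' @slot config the [CurationConfig-class] used.
#' @export
setClass("CuratedDataset",
  representation(compounds = "data.frame", task = "character",
                 report = "CurationReport", config = "CurationConfig"))

setValidity("CuratedDataset", function(object) {
  if (nrow(object@compounds)) {
    if (!all(c("smiles", "pic50", "label") %in% colnames(object@compounds)))
      return("compounds must have columns smiles, pic50, label")
    if (anyDuplicated(object@compounds$smiles))
      return("no two compounds may share a canonical SMILES")
  }
  TRUE
})

#' Fingerprint matrix
#'
#' Binary compounds-by-bits matrix plus the [FingerprintSpec-class] that
#' produced it. Rows are aligned with (and named by) the compound ids.
#'
#' @slot bits integer 0/1 matrix, compounds in rows.
#' @slot spec the [FingerprintSpec-class].
#' @slot ids character compound identifiers, one per row.
#' @export
setClass("FingerprintMatrix",
  representation(bits = "matrix", spec = "FingerprintSpec", ids = "character"))

setValidity("FingerprintMatrix", function(object) {
  if (nrow(object@bits) != length(object@ids))
    return("row count must equal the number of compound ids")
  if (ncol(object@bits) != object@spec@nbits)
    return("column count must equal spec nbits")
  if (length(object@bits) && !all(object@bits %in% c(0L, 1L)))
    return("entries must be 0/1")
  TRUE
})

#' Applicability-domain model
#'
#' Distance-to-training-set applicability domain: a query is inside the
#' domain when its mean Euclidean distance to the `k` nearest training
#' fingerprints does not exceed the cutoff Dc = mean + z * sd of the
#' training set's own leave-self-out k-nearest-neighbor distances.
#'
#' @slot reference training fingerprint matrix (0/1).
#' @slot k integer number of neighbors (default 1).
#' @slot z numeric width multiplier (default 0.5).
#' @slot cutoff numeric distance cutoff Dc.
#' @slot nnMean,nnSd numeric mean and SD of the training NN distances.
#' @export
setClass("ADModel",
  representation(reference = "matrix", k = "integer", z = "numeric",
                 cutoff = "numeric", nnMean = "numeric", nnSd = "numeric"))

setValidity("ADModel", function(object) {
  if (nrow(object@reference) < 2L)
    return("at least two reference compounds are required")
  if (object@k < 1L) return("k must be >= 1")
  if (object@cutoff < 0) return("cutoff must be non-negative")
  TRUE
})

#' Trained model bundle
#'
#' A fitted learner for one task, together with everything needed to make it
#' reproducible: the fingerprint spec, the hyperparameters, the seed, the
#' training ids, the applicability-domain model and evaluation metrics.
#'
#' @slot task `"binary"`, `"multiclass"` or `"regression"`.
#' @slot algorithm one of `"random_forest"`, `"knn"`, `"svm"`, `"gbt_light"`,
#'   `"gbt_extreme"`.
#' @slot hyperparameters named list of learner settings.
#' @slot fingerprint the [FingerprintSpec-class] the model expects.
#' @slot seed integer seed used at fit time.
#' @slot fit the opaque fitted learner.
#' @slot classLevels character class levels (classification tasks).
#' @slot trainIds ids of the training compounds.
#' @slot ad the [ADModel-class] fitted on the training fingerprints (or NULL).
#' @slot metrics named list of evaluation results.
#' @export
setClass("HergModel",
  representation(task = "character", algorithm = "character",
                 hyperparameters = "list", fingerprint = "FingerprintSpec",
                 seed = "integer", fit = "ANY", classLevels = "character",
                 trainIds = "character", ad = "ANY", metrics = "list"))

setValidity("HergModel", function(object) {
  if (!object@task %in% c("binary", "multiclass", "regression"))
    return("task must be binary, multiclass or regression")
  if (!object@algorithm %in%
      c("random_forest", "knn", "svm", "gbt_light", "gbt_extreme"))
    return("unknown algorithm")
  TRUE
})

#' Consensus configuration
#'
#' Weights and threshold of the weighted consensus call. The binary model
#' carries weight 0.6; the multiclass and regression models carry 0.2 when
#' their blocker/nonblocker dichotomy agrees with the binary call and 0.1
#' when it does not. Labels are encoded as levels 0-3 (nonblocker 0, weak 1,
#' moderate/weak 2, strong 3, binary blocker 3); a weighted level sum at or
#' above the threshold (default 2) is called blocker.
#'
#' @slot wBinary,wAgree,wDisagree numeric weights.
#' @slot threshold numeric blocker decision threshold on the score.
#' @slot levels named numeric level encoding of the label vocabulary.
#' @export
setClass("ConsensusConfig",
  representation(wBinary = "numeric", wAgree = "numeric",
                 wDisagree = "numeric", threshold = "numeric",
                 levels = "numeric"),
  prototype(wBinary = 0.6, wAgree = 0.2, wDisagree = 0.1, threshold = 2,
            levels = c(nonblocker = 0, weak = 1, moderate_weak = 2,
                       moderate = 2, strong = 3, blocker = 3)))

setValidity("ConsensusConfig", function(object) {
  if (!isTRUE(object@wBinary > object@wAgree &&
              object@wAgree > object@wDisagree && object@wDisagree > 0))
    return("weights must satisfy wBinary > wAgree > wDisagree > 0")
  if (!isTRUE(object@threshold > 0)) return("threshold must be positive")
  if (is.null(names(object@levels))) return("levels must be named")
  TRUE
})

#' Construct a ConsensusConfig
#'
#' @param wBinary weight of the binary model (default 0.6).
#' @param wAgree weight of an auxiliary model agreeing with the binary
#'   dichotomy (default 0.2).
#' @param wDisagree weight when it disagrees (default 0.1).
#' @param threshold score at/above which the call is blocker (default 2).
#' @param levels named numeric label-level encoding.
#' @return A [ConsensusConfig-class].
#' @export
consensusConfig <- function(wBinary = 0.6, wAgree = 0.2, wDisagree = 0.1,
                            threshold = 2,
                            levels = c(nonblocker = 0, weak = 1,
                                       moderate_weak = 2, moderate = 2,
                                       strong = 3, blocker = 3)) {
  new("ConsensusConfig", wBinary = wBinary, wAgree = wAgree,
      wDisagree = wDisagree, threshold = threshold, levels = levels)
}

#' Shapley attribution matrix
#'
#' Signed per-compound, per-bit contributions to a model's output, plus the
#' base value (expected model output). For exact tree attributions, base +
#' row sum reproduces the model's raw output for every compound.
#'
#' @slot values numeric matrix, compounds by bits.
#' @slot baseValue numeric expected-output offset.
#' @slot ids character compound ids.
#' @slot method `"tree_exact"` or `"sampling"`.
#' @export
setClass("AttributionMatrix",
  representation(values = "matrix", baseValue = "numeric", ids = "character",
                 method = "character"))

#' Per-atom attribution map
#'
#' Signed per-atom weights for one molecule, obtained by projecting bit
#' attributions onto the atoms of the environments that set each bit. Positive
#' weights push the model towards the blocker class (rendered red), negative
#' weights away from it (green).
#'
#' @slot smiles canonical SMILES of the molecule.
#' @slot weights numeric per-atom signed weights (heavy atoms, SDF order).
#' @slot bitAttributions named numeric attribution of each on-bit.
#' @slot method attribution method used.
#' @export
setClass("AtomAttributionMap",
  representation(smiles = "character", weights = "numeric",
                 bitAttributions = "numeric", method = "character"))
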