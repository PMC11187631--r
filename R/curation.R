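## Curation: structure standardization -> pIC50 conversion -> activity
## qualifier filtering -> labeling -> duplicate resolution, with an exactly
## balanced removal ledger.

#' Convert a molar IC50 to pIC50
#'
#' pIC50 = -log10(IC50 in molar); higher values mean exponentially greater
#' potency.
#'
#' @param ic50 positive molar concentration(s).
#' @return numeric pIC50.
#' @examples
#' ic50ToPic50(1e-5)            # 5: the 10 uM blocker boundary
#' ic50ToPic50(toMolar(0.00285, "uM"))
#' @export
ic50ToPic50 <- function(ic50) {
  if (any(!is.finite(ic50) | ic50 <= 0))
    stop("IC50 must be positive and finite")
  -log10(ic50)
}

#' Activity qualifier filter
#'
#' Decides what to do with a measurement given its relation qualifier. For
#' classification tasks: `>` with IC50 below 10 uM is uninformative and
#' excluded, `>` at/above 10 uM proves inactivity (`keep_as_inactive`),
#' `<` at/below 10 uM proves activity (`keep_as_active`), `<` above 10 uM is
#' excluded; exact values are kept as-is. Regression keeps only exact values.
#' `<=`/`>=` qualifiers are treated like `<`/`>`.
#'
#' @param relation character vector over eq/lt/gt/le/ge.
#' @param molar numeric molar IC50 values.
#' @param task `"binary"`, `"multiclass"` or `"regression"`.
#' @param inactiveIc50 molar threshold (default 1e-5 = 10 uM).
#' @return character vector over `keep_as_is`, `keep_as_active`,
#'   `keep_as_inactive`, `exclude`.
#' @export
applyQualifierFilter <- function(relation, molar,
                                 task = c("binary", "multiclass",
                                          "regression"),
                                 inactiveIc50 = 1e-5) {
  task <- match.arg(task)
  stopifnot(length(relation) == length(molar))
  rel <- ifelse(relation == "le", "lt", ifelse(relation == "ge", "gt",
                                               relation))
  if (task == "regression")
    return(ifelse(rel == "eq", "keep_as_is", "exclude"))
  # compare on the pIC50 scale with a tiny guard so that unit conversion
  # round-off cannot move a measurement across the 10 uM boundary
  pv <- -log10(molar)
  cut <- -log10(inactiveIc50)
  out <- rep("exclude", length(rel))
  out[rel == "eq"] <- "keep_as_is"
  out[rel == "gt" & pv <= cut + .PIC50_TOL] <- "keep_as_inactive"
  out[rel == "lt" & pv >= cut - .PIC50_TOL] <- "keep_as_active"
  out
}

#' Binary blocker label
#'
#' IC50 at or above 10 uM (pIC50 <= 5) is nonblocker; anything more potent is
#' blocker.
#'
#' @param pic50 numeric pIC50 values.
#' @param config a [CurationConfig-class] (the inactivity threshold).
#' @return factor over nonblocker/blocker.
#' @export
labelBinary <- function(pic50, config = curationConfig("binary")) {
  cut <- ic50ToPic50(config@inactiveIc50)
  factor(ifelse(pic50 <= cut + .PIC50_TOL, "nonblocker", "blocker"),
         levels = BINARY_LEVELS)
}

#' Multiclass blocker label
#'
#' pIC50 >= 6 is strong, 5 <= pIC50 < 6 is moderate/weak, pIC50 < 5 is
#' nonblocker.
#'
#' @param pic50 numeric pIC50 values.
#' @param config a [CurationConfig-class] (tier bounds).
#' @return factor over nonblocker/moderate_weak/strong.
#' @export
labelMulticlass <- function(pic50, config = curationConfig("multiclass")) {
  out <- ifelse(pic50 >= config@strongPic50 - .PIC50_TOL, "strong",
                ifelse(pic50 >= config@moderatePic50 - .PIC50_TOL,
                       "moderate_weak", "nonblocker"))
  factor(out, levels = MULTICLASS_LEVELS)
}

#' Resolve classification duplicates
#'
#' Groups labeled records by canonical SMILES. Groups with a single label
#' keep one representative; groups with a strict majority label keep one
#' representative of the majority; groups with tied, conflicting labels are
#' removed entirely.
#'
#' @param smiles character canonical SMILES per record.
#' @param pic50 numeric pIC50 per record.
#' @param label character/factor label per record.
#' @return list with `kept` (data.frame smiles, pic50, label; pic50 is the
#'   mean over the majority-label records), `removedConflict` and
#'   `mergedCount` (records collapsed into kept representatives).
#' @export
deduplicateClassification <- function(smiles, pic50, label) {
  label <- as.character(label)
  keptS <- character(); keptP <- numeric(); keptL <- character()
  removed <- 0L; merged <- 0L
  for (s in unique(smiles)) {
    idx <- which(smiles == s)
    tab <- table(label[idx])
    top <- max(tab)
    winners <- names(tab)[tab == top]
    if (length(winners) > 1L) {        # tie: conflicting outcomes
      removed <- removed + length(idx)
      next
    }
    maj <- winners[1]
    majIdx <- idx[label[idx] == maj]
    keptS <- c(keptS, s)
    keptP <- c(keptP, mean(pic50[majIdx]))
    keptL <- c(keptL, maj)
    merged <- merged + length(idx) - 1L
  }
  list(kept = data.frame(smiles = keptS, pic50 = keptP, label = keptL,
                         stringsAsFactors = FALSE),
       removedConflict = removed, mergedCount = merged)
}

#' Resolve regression duplicates
#'
#' Groups records by canonical SMILES; a group whose pIC50 sample standard
#' deviation exceeds `sdMax` is removed entirely, otherwise one compound is
#' kept with the arithmetic-mean pIC50. Also returns the duplicate groups
#' (size >= 2) seen before removal, for experimental-error estimation.
#'
#' @param smiles character canonical SMILES per record.
#' @param pic50 numeric pIC50 per record.
#' @param sdMax maximum tolerated sample SD (default 0.2).
#' @return list with `kept` (data.frame smiles, pic50), `removedHighSd`,
#'   `mergedCount` and `duplicateGroups` (list of pIC50 vectors).
#' @export
deduplicateRegression <- function(smiles, pic50, sdMax = 0.2) {
  keptS <- character(); keptP <- numeric()
  removed <- 0L; merged <- 0L
  groups <- list()
  for (s in unique(smiles)) {
    idx <- which(smiles == s)
    vals <- pic50[idx]
    if (length(idx) >= 2L) {
      groups[[length(groups) + 1L]] <- vals
      if (stats::sd(vals) > sdMax) { removed <- removed + length(idx); next }
      merged <- merged + length(idx) - 1L
    }
    keptS <- c(keptS, s)
    keptP <- c(keptP, mean(vals))
  }
  list(kept = data.frame(smiles = keptS, pic50 = keptP,
                         stringsAsFactors = FALSE),
       removedHighSd = removed, mergedCount = merged,
       duplicateGroups = groups)
}

#' Experimental error from duplicate measurements
#'
#' Mean absolute deviation of each duplicate measurement from its group mean,
#' averaged over all records in groups of size >= 2. Computed on the
#' regression data before duplicates are resolved, this estimates the
#' irreducible experimental error of the assay data on the pIC50 scale.
#'
#' @param groups list of numeric pIC50 vectors (one per duplicate group).
#' @return numeric mean absolute error; NA (with a warning) when no group
#'   has two or more members.
#' @examples
#' experimentalMae(list(c(5.0, 5.2)))            # 0.1
#' experimentalMae(list(c(5.0, 5.2), c(6.0, 6.4)))  # 0.15
#' @export
experimentalMae <- function(groups) {
  groups <- Filter(function(g) length(g) >= 2L, groups)
  if (length(groups) == 0L) {
    warning("no duplicate group of size >= 2; experimental MAE undefined")
    return(NA_real_)
  }
  devs <- unlist(lapply(groups, function(g) abs(g - mean(g))))
  mean(devs)
}

#' Curate a bioactivity table into a modeling dataset
#'
#' Runs the full curation cascade for one task: structure standardization
#' (salt stripping, neutralization, stereo flattening; inorganics and
#' mixtures removed), unit conversion and pIC50 computation, activity
#' qualifier filtering, labeling, and duplicate resolution keyed on the
#' canonical SMILES. The returned [CuratedDataset-class] carries a
#' [CurationReport-class] whose per-rule counts plus kept compounds balance
#' the input record count exactly.
#'
#' @param table an [ActivityTable-class] with at least one record.
#' @param config a [CurationConfig-class]; its `task` selects the labeling
#'   and duplicate rules.
#' @return A [CuratedDataset-class].
#' @export
curateDataset <- function(table, config = curationConfig("binary")) {
  recs <- records(table)
  if (nrow(recs) == 0L) stop("cannot curate an empty table")
  task <- config@task
  counts <- stats::setNames(integer(length(REMOVAL_RULES)), REMOVAL_RULES)

  norm <- normalizeStructure(recs$smiles)
  for (r in c("unparseable", "inorganic", "mixture"))
    counts[r] <- sum(norm$reason == r, na.rm = TRUE)
  live <- is.na(norm$reason)
  recs <- recs[live, , drop = FALSE]
  recs$canonical <- norm$smiles[live]

  molar <- toMolar(recs$value, recs$units)
  recs$pic50 <- ic50ToPic50(molar)
  decision <- applyQualifierFilter(recs$relation, molar, task,
                                   config@inactiveIc50)
  counts["qualifier_excluded"] <- sum(decision == "exclude")
  keep <- decision != "exclude"
  recs <- recs[keep, , drop = FALSE]
  decision <- decision[keep]

  mae <- NA_real_
  if (task == "regression") {
    dd <- deduplicateRegression(recs$canonical, recs$pic50, config@dupSdMax)
    counts["duplicate_high_sd"] <- dd$removedHighSd
    counts["duplicate_merged"] <- dd$mergedCount
    if (length(dd$duplicateGroups))
      mae <- suppressWarnings(experimentalMae(dd$duplicateGroups))
    comp <- dd$kept
    comp$label <- comp$pic50
  } else {
    lab <- if (task == "binary") as.character(labelBinary(recs$pic50, config))
           else as.character(labelMulticlass(recs$pic50, config))
    # censored measurements: the qualifier, not the point value, decides
    lab[decision == "keep_as_inactive"] <- "nonblocker"
    if (task == "binary") {
      lab[decision == "keep_as_active"] <- "blocker"
    } else {
      bump <- decision == "keep_as_active" & lab == "nonblocker"
      lab[bump] <- "moderate_weak"
    }
    dd <- deduplicateClassification(recs$canonical, recs$pic50, lab)
    counts["duplicate_conflict"] <- dd$removedConflict
    counts["duplicate_merged"] <- dd$mergedCount
    comp <- dd$kept
  }
  counts <- c(counts, kept = nrow(comp))
  report <- new("CurationReport", counts = as.integer(counts) |>
                  stats::setNames(names(counts)),
                nInput = nrow(records(table)), experimentalMae = mae)
  rownames(comp) <- NULL
  new("CuratedDataset", compounds = comp, task = task, report = report,
      config = config)
}

#' Re-express a curated dataset as an activity table
#'
#' Useful for round-tripping (for example to check curation idempotence) and
#' for writing curated compounds back out through [writeDataset()]. All
#' records get relation `eq` and molar units.
#'
#' @param dataset a [CuratedDataset-class].
#' @param assayType assay annotation to stamp on the records.
#' @return An [ActivityTable-class].
#' @export
asActivityTable <- function(dataset, assayType = "SP") {
  comp <- compounds(dataset)
  recs <- data.frame(compoundId = sprintf("CUR%04d", seq_len(nrow(comp))),
                     smiles = comp$smiles, assayType = assayType,
                     relation = "eq", value = 10^(-comp$pic50), units = "M",
                     stringsAsFactors = FALSE)
  activityTable(recs, provenance = sprintf("curated:%s", dataset@task))
}
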