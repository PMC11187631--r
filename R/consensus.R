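## Weighted consensus of the three tasks, the regression -> label mapping,
## and Cohen's kappa for inter-model agreement.

#' Map a predicted pIC50 to a four-level blocker label
#'
#' strong for pIC50 >= 6, moderate for [5, 6), weak for [4.5, 5),
#' nonblocker below 4.5.
#'
#' @param pic50 numeric predicted pIC50 values.
#' @return factor over nonblocker/weak/moderate/strong.
#' @examples
#' regressionToLabel(c(6.2, 4.7, 4.4))
#' @export
regressionToLabel <- function(pic50) {
  out <- ifelse(pic50 >= 6 - .PIC50_TOL, "strong",
                ifelse(pic50 >= 5 - .PIC50_TOL, "moderate",
                       ifelse(pic50 >= 4.5 - .PIC50_TOL, "weak",
                              "nonblocker")))
  factor(out, levels = REGRESSION_LEVELS)
}

.isBlockerLabel <- function(label) {
  !(as.character(label) %in% "nonblocker")
}

#' Weighted consensus call
#'
#' Combines the binary, multiclass and regression predictions into one
#' blocker/nonblocker call. Each label is encoded as a level (nonblocker 0,
#' weak 1, moderate/weak 2, strong 3; a binary blocker counts as 3) and the
#' score is the weighted level sum: the binary model weighs `wBinary` (0.6),
#' and each auxiliary model weighs `wAgree` (0.2) when its
#' blocker/nonblocker dichotomy matches the binary call, `wDisagree` (0.1)
#' otherwise. A score at or above the threshold (2) is called blocker.
#'
#' @param binaryLabel,multiclassLabel,regressionLabel equal-length label
#'   vectors (regression labels from [regressionToLabel()]).
#' @param config a [ConsensusConfig-class].
#' @return data.frame with columns score, call, binaryLabel,
#'   multiclassLabel, regressionLabel, agreeMulticlass, agreeRegression.
#' @examples
#' consensusScore("blocker", "strong", "strong")            # score 3, blocker
#' consensusScore("blocker", "nonblocker", "nonblocker")    # score 1.8
#' @export
consensusScore <- function(binaryLabel, multiclassLabel, regressionLabel,
                           config = consensusConfig()) {
  b <- as.character(binaryLabel)
  m <- as.character(multiclassLabel)
  r <- as.character(regressionLabel)
  stopifnot(length(b) == length(m), length(b) == length(r))
  lv <- config@levels
  bad <- setdiff(unique(c(b, m, r)), names(lv))
  if (length(bad)) stop("unknown label token(s): ",
                        paste(bad, collapse = ", "))
  bIsBlocker <- .isBlockerLabel(b)
  agreeM <- .isBlockerLabel(m) == bIsBlocker
  agreeR <- .isBlockerLabel(r) == bIsBlocker
  wM <- ifelse(agreeM, config@wAgree, config@wDisagree)
  wR <- ifelse(agreeR, config@wAgree, config@wDisagree)
  score <- config@wBinary * lv[b] + wM * lv[m] + wR * lv[r]
  data.frame(score = unname(score),
             call = ifelse(score >= config@threshold, "blocker",
                           "nonblocker"),
             binaryLabel = b, multiclassLabel = m, regressionLabel = r,
             agreeMulticlass = agreeM, agreeRegression = agreeR,
             stringsAsFactors = FALSE)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between two label assignments:
#' kappa = (po - pe) / (1 - pe), with pe the marginal-product expected
#' agreement.
#'
#' @param a,b equal-length label vectors (length >= 2).
#' @return numeric kappa in [-1, 1]; NA (with a warning) when the expected
#'   agreement is 1 and kappa is undefined.
#' @examples
#' cohensKappa(c("B", "B", "N", "N"), c("B", "N", "B", "N"))  # 0
#' @export
cohensKappa <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  stopifnot(length(a) == length(b), length(a) >= 2L)
  lev <- unique(c(a, b))
  po <- mean(a == b)
  pa <- table(factor(a, levels = lev)) / length(a)
  pb <- table(factor(b, levels = lev)) / length(b)
  pe <- sum(pa * pb)
  if (isTRUE(all.equal(pe, 1))) {
    warning("expected agreement is 1; kappa undefined")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}
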