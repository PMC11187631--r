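## Chemical-space diagnostics: inter-assay correlation, cross-set Tanimoto
## similarity, activity-cliff detection, SAR continuity/discontinuity, and a
## 2D embedding of fingerprint space.

# full Tanimoto similarity matrix between two 0/1 matrices
.tanimotoMatrix <- function(A, B) {
  inter <- A %*% t(B)
  ca <- rowSums(A); cb <- rowSums(B)
  uni <- outer(ca, cb, "+") - inter
  sim <- ifelse(uni == 0, 1, inter / uni)
  sim
}

#' Inter-assay activity correlation
#'
#' For every pair of assay contexts (SP/HEK/CHO), matches compounds measured
#' in both (by canonical SMILES, per-assay mean pIC50) and reports the
#' Pearson correlation with its two-sided p-value (t distribution, n-2 df).
#' Pairs with fewer than 3 shared compounds are reported with NA.
#'
#' @param table an [ActivityTable-class] whose records carry assayType and
#'   pIC50; SMILES are canonicalized for matching.
#' @param assays assay labels to correlate (default SP/HEK/CHO).
#' @return data.frame with columns assayA, assayB, r, p, n.
#' @export
assayCorrelation <- function(table, assays = c("SP", "HEK", "CHO")) {
  recs <- records(table)
  recs <- recs[recs$assayType %in% assays, , drop = FALSE]
  recs$canonical <- canonicalSmiles(recs$smiles)
  recs <- recs[!is.na(recs$canonical), , drop = FALSE]
  agg <- stats::aggregate(pic50 ~ canonical + assayType, data = recs, FUN = mean)
  pairs <- utils::combn(assays, 2)
  out <- data.frame()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    xa <- agg[agg$assayType == a, ]
    xb <- agg[agg$assayType == b, ]
    shared <- intersect(xa$canonical, xb$canonical)
    n <- length(shared)
    if (n >= 3L) {
      va <- xa$pic50[match(shared, xa$canonical)]
      vb <- xb$pic50[match(shared, xb$canonical)]
      ct <- stats::cor.test(va, vb, method = "pearson")
      out <- rbind(out, data.frame(assayA = a, assayB = b,
                                   r = unname(ct$estimate),
                                   p = ct$p.value, n = n))
    } else {
      out <- rbind(out, data.frame(assayA = a, assayB = b, r = NA_real_,
                                   p = NA_real_, n = n))
    }
  }
  out
}

#' Mean cross-set Tanimoto similarity
#'
#' Mean of all pairwise Tanimoto similarities between two compound sets
#' (for example training vs test). When both arguments are the same set,
#' self-pairs are excluded.
#'
#' @param A,B [FingerprintMatrix-class] objects (or 0/1 matrices) with the
#'   same fingerprint spec.
#' @return numeric mean similarity.
#' @export
crossSetTanimoto <- function(A, B) {
  Am <- .asBitMatrix(A); Bm <- .asBitMatrix(B)
  if (nrow(Am) == 0L || nrow(Bm) == 0L) stop("both sets must be non-empty")
  if (ncol(Am) != ncol(Bm)) stop("fingerprint lengths differ")
  sim <- .tanimotoMatrix(Am, Bm)
  if (identical(Am, Bm)) {
    if (nrow(Am) == 1L) return(1)
    diag(sim) <- NA
    return(mean(sim, na.rm = TRUE))
  }
  mean(sim)
}

#' Find activity cliffs
#'
#' Reports every unordered compound pair whose fingerprint similarity meets
#' the cutoff (default 80%, MACCS keys) and whose activities diverge: either
#' opposing blocker/nonblocker labels or an absolute pIC50 gap of at least
#' `potencyGapMin` log units.
#'
#' @param dataset a [CuratedDataset-class] with pIC50 values (classification
#'   datasets derive the dichotomy from their labels; regression datasets
#'   from pIC50 > 5).
#' @param spec fingerprint used for similarity (default MACCS).
#' @param similarityCutoff minimum Tanimoto similarity (default 0.8).
#' @param potencyGapMin minimum |delta pIC50| for a same-label cliff
#'   (default 1).
#' @return data.frame of cliff pairs: smilesA, smilesB, similarity, pic50A,
#'   pic50B, labelA, labelB, potencyGap.
#' @export
findCliffs <- function(dataset, spec = fingerprintSpec("maccs"),
                       similarityCutoff = 0.8, potencyGapMin = 1) {
  comp <- compounds(dataset)
  if (nrow(comp) < 2L)
    return(data.frame())
  fps <- featurizeDataset(dataset, spec)
  sim <- .tanimotoMatrix(fpBits(fps), fpBits(fps))
  blocker <- if (dataset@task == "regression") comp$pic50 > 5
             else .isBlockerLabel(comp$label)
  out <- data.frame()
  for (i in seq_len(nrow(comp) - 1L)) {
    for (j in seq(i + 1L, nrow(comp))) {
      if (sim[i, j] < similarityCutoff) next
      gap <- abs(comp$pic50[i] - comp$pic50[j])
      if (blocker[i] != blocker[j] || gap >= potencyGapMin) {
        out <- rbind(out, data.frame(
          smilesA = comp$smiles[i], smilesB = comp$smiles[j],
          similarity = sim[i, j], pic50A = comp$pic50[i],
          pic50B = comp$pic50[j],
          labelA = as.character(comp$label[i]),
          labelB = as.character(comp$label[j]),
          potencyGap = gap, stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' SAR continuity and discontinuity scores
#'
#' Raw (non-normalized) neighborhood smoothness statistics. For compound i,
#' continuity is the potency-weighted mean of reciprocal similarities over
#' all other compounds (weights pIC50_i * pIC50_j; high values flag potent
#' compounds in sparse neighborhoods), and discontinuity is the mean of
#' |delta pIC50| * similarity over neighbors with similarity at or above the
#' cutoff (high values flag activity cliffs). Global scores are means over
#' compounds; global discontinuity averages only compounds with at least one
#' qualifying neighbor and is NA when there are none.
#'
#' @param dataset a [CuratedDataset-class] with pIC50 values (>= 2
#'   compounds).
#' @param spec fingerprint spec (default MACCS).
#' @param similarityCutoff neighbor cutoff for discontinuity (default 0.8).
#' @return list with `perCompound` (data.frame smiles, cont, disc) and
#'   `global` (named numeric cont, disc).
#' @export
continuityDiscontinuity <- function(dataset, spec = fingerprintSpec("maccs"),
                                    similarityCutoff = 0.8) {
  comp <- compounds(dataset)
  if (nrow(comp) < 2L) stop("need at least two compounds")
  fps <- featurizeDataset(dataset, spec)
  sim <- .tanimotoMatrix(fpBits(fps), fpBits(fps))
  n <- nrow(comp)
  cont <- disc <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    w <- comp$pic50[i] * comp$pic50[others]
    s <- pmax(sim[i, others], 1e-6)
    cont[i] <- sum(w / s) / sum(w)
    nb <- others[sim[i, others] >= similarityCutoff]
    if (length(nb))
      disc[i] <- mean(abs(comp$pic50[i] - comp$pic50[nb]) * sim[i, nb])
  }
  list(perCompound = data.frame(smiles = comp$smiles, cont = cont,
                                disc = disc, stringsAsFactors = FALSE),
       global = c(cont = mean(cont),
                  disc = if (all(is.na(disc))) NA_real_
                         else mean(disc, na.rm = TRUE)))
}

#' 2D embedding of fingerprint space
#'
#' Embeds compounds in two dimensions by classical multidimensional scaling
#' (principal coordinates) of the 1 - Tanimoto distance matrix. The
#' embedding is deterministic; the seed argument is accepted for interface
#' uniformity and signs are fixed so repeated calls are identical.
#'
#' @param fps a [FingerprintMatrix-class] (>= 5 compounds).
#' @param seed unused beyond determinism bookkeeping.
#' @return numeric matrix (compounds x 2) with rownames from the ids.
#' @export
embed2D <- function(fps, seed = 1L) {
  Xm <- .asBitMatrix(fps)
  if (nrow(Xm) < 5L) stop("need at least 5 compounds to embed")
  d <- stats::as.dist(1 - .tanimotoMatrix(Xm, Xm))
  coords <- stats::cmdscale(d, k = 2)
  # fix reflection: force positive skew on each axis
  for (j in 1:2) if (sum(coords[, j]^3) < 0) coords[, j] <- -coords[, j]
  if (is(fps, "FingerprintMatrix")) rownames(coords) <- compoundIds(fps)
  colnames(coords) <- c("x", "y")
  coords
}
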