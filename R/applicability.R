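## Distance-based applicability domain: a query is reliable when it is no
## farther from the training set than training compounds typically are from
## each other.

# mean distance of each row of `query` to its k nearest rows of `ref`;
# when selfIdx is given, row i of query skips reference row selfIdx[i]
.knnMeanDist <- function(query, ref, k, selfIdx = NULL) {
  refSq <- rowSums(ref^2)
  out <- numeric(nrow(query))
  for (i in seq_len(nrow(query))) {
    d2 <- refSq - 2 * as.numeric(ref %*% query[i, ]) + sum(query[i, ]^2)
    d2[d2 < 0] <- 0
    if (!is.null(selfIdx)) d2[selfIdx[i]] <- Inf
    out[i] <- mean(sqrt(sort(d2)[seq_len(k)]))
  }
  out
}

#' Fit an applicability-domain model
#'
#' Computes every training compound's mean Euclidean distance to its `k`
#' nearest other training fingerprints (leave-self-out) and sets the domain
#' cutoff Dc = mean + z * sd of that distance distribution.
#'
#' @param X a [FingerprintMatrix-class] or 0/1 matrix with >= 2 rows.
#' @param k number of nearest neighbors (default 1).
#' @param z cutoff width multiplier (default 0.5).
#' @return An [ADModel-class].
#' @export
fitAD <- function(X, k = 1L, z = 0.5) {
  Xm <- .asBitMatrix(X)
  if (nrow(Xm) < 2L) stop("need at least two training compounds")
  k <- as.integer(k)
  stopifnot(k >= 1L, k <= nrow(Xm) - 1L)
  nn <- .knnMeanDist(Xm, Xm, k, selfIdx = seq_len(nrow(Xm)))
  m <- mean(nn); s <- stats::sd(nn)
  new("ADModel", reference = Xm, k = k, z = z,
      cutoff = m + z * s, nnMean = m, nnSd = s)
}

#' Applicability-domain check
#'
#' Flags whether each query fingerprint lies inside the domain: its mean
#' distance to the `k` nearest training compounds must not exceed the
#' cutoff Dc.
#'
#' @param ad an [ADModel-class].
#' @param query a [FingerprintMatrix-class], 0/1 matrix or single bit vector
#'   of matching length.
#' @return data.frame with columns `inDomain` (logical), `distance` and
#'   `cutoff`.
#' @export
inDomain <- function(ad, query) {
  Qm <- if (is(query, "FingerprintMatrix")) fpBits(query)
        else if (is.matrix(query)) query
        else matrix(query, nrow = 1L)
  if (ncol(Qm) != ncol(ad@reference))
    stop("query fingerprint length does not match the reference")
  d <- .knnMeanDist(Qm, ad@reference, ad@k)
  data.frame(inDomain = d <= ad@cutoff, distance = d, cutoff = ad@cutoff)
}
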