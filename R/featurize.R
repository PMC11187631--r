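## Hashed circular fingerprints (ECFP/FCFP flavors) with an explicit
## bit -> atom-environment map, plus MACCS keys via OpenBabel. The circular
## fingerprints are computed on the canonical structure, so any SMILES
## rewriting of the same molecule (kekulized vs aromatic) yields the same
## bits.

# deterministic 31-bit polynomial hash of an integer vector
.hashInts <- function(x) {
  h <- 17
  for (v in x) h <- (h * 31 + (v %% 2147483647)) %% 2147483647
  as.integer(h)
}

.ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl",
               "Br", "I", "Se", "As")

# ECFP-style initial invariant: element, degree, H count, charge, ring flag
.ecfpInvariant <- function(g) {
  elem <- match(g$symbol, .ELEMENTS, nomatch = 99L)
  vapply(seq_along(g$symbol), function(i)
    .hashInts(c(1L, elem[i], g$degree[i], g$nH[i], g$charge[i] + 10L,
                as.integer(g$inRing[i]))), integer(1))
}

# FCFP-style initial invariant: simplified pharmacophore feature flags
# (H-bond donor/acceptor, positively/negatively charged, halogen, in-ring)
.fcfpInvariant <- function(g) {
  donor    <- g$symbol %in% c("N", "O") & g$nH >= 1L
  acceptor <- g$symbol %in% c("N", "O") & g$charge <= 0L
  pos      <- g$charge > 0L
  neg      <- g$charge < 0L
  halogen  <- g$symbol %in% c("F", "Cl", "Br", "I")
  vapply(seq_along(g$symbol), function(i)
    .hashInts(c(2L, as.integer(donor[i]), as.integer(acceptor[i]),
                as.integer(pos[i]), as.integer(neg[i]),
                as.integer(halogen[i]), as.integer(g$inRing[i]))),
    integer(1))
}

# all circular environment identifiers of a molecule, with their atom sets
.circularEnvironments <- function(g, spec) {
  natoms <- length(g$symbol)
  if (natoms == 0L) return(list())
  neighbors <- vector("list", natoms)
  if (nrow(g$bonds)) {
    for (j in seq_len(nrow(g$bonds))) {
      a <- g$bonds$from[j]; b <- g$bonds$to[j]; o <- g$bonds$order[j]
      neighbors[[a]] <- rbind(neighbors[[a]], c(b, o))
      neighbors[[b]] <- rbind(neighbors[[b]], c(a, o))
    }
  }
  inv <- if (spec@family == "fcfp") .fcfpInvariant(g) else .ecfpInvariant(g)
  envs <- list()
  covered <- list()  # atom sets already emitted (lowest radius wins)
  emit <- function(id, atoms) {
    key <- paste(sort(atoms), collapse = ",")
    if (!is.null(covered[[key]])) return()
    covered[[key]] <<- TRUE
    envs[[length(envs) + 1L]] <<- list(id = id, atoms = sort(atoms))
  }
  atomsWithin <- lapply(seq_len(natoms), function(i) i)
  for (i in seq_len(natoms)) emit(inv[i], i)
  r <- 0L
  while (r < spec@radius) {
    r <- r + 1L
    newInv <- integer(natoms)
    newAtoms <- vector("list", natoms)
    for (i in seq_len(natoms)) {
      nb <- neighbors[[i]]
      if (is.null(nb)) {
        newInv[i] <- .hashInts(c(3L, r, inv[i]))
        newAtoms[[i]] <- atomsWithin[[i]]
      } else {
        pairs <- cbind(nb[, 2], inv[nb[, 1]])
        ord <- order(pairs[, 1], pairs[, 2])
        newInv[i] <- .hashInts(c(3L, r, inv[i], t(pairs[ord, , drop = FALSE])))
        newAtoms[[i]] <- sort(unique(c(atomsWithin[[i]],
                                       unlist(atomsWithin[nb[, 1]]))))
      }
    }
    inv <- newInv
    atomsWithin <- newAtoms
    for (i in seq_len(natoms)) emit(inv[i], atomsWithin[[i]])
  }
  envs
}

.maccsBits <- function(smiles) {
  mols <- ChemmineOB::forEachMol("SMILES",
                                 paste(smiles, collapse = "\n"), identity)
  m <- ChemmineOB::fingerprint_OB(mols, "MACCS")
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  # OpenBabel pads MACCS to a 256-bit word; the defined keys are the first 166
  m <- m[, seq_len(166L), drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

#' Compute a molecular fingerprint
#'
#' Returns the binary fingerprint of one molecule under `spec`. Hashed
#' circular families (`ecfp`, `fcfp`) fold environment identifiers into
#' `nbits` buckets; `maccs` returns the 166 structural keys. Input SMILES are
#' canonicalized first, so equivalent writings of a molecule map to the same
#' vector.
#'
#' @param smiles a single SMILES string.
#' @param spec a [FingerprintSpec-class].
#' @return integer 0/1 vector of length `spec@nbits`.
#' @examples
#' sum(fingerprint("c1ccccc1O", fingerprintSpec("ecfp")))
#' @export
fingerprint <- function(smiles, spec = fingerprintSpec()) {
  stopifnot(length(smiles) == 1L)
  canon <- canonicalSmiles(smiles)
  if (is.na(canon)) stop("unparseable SMILES: ", smiles)
  if (spec@family == "maccs") {
    bits <- .maccsBits(canon)[1L, ]
    return(as.integer(bits))
  }
  .fingerprintCanonical(canon, spec)
}

.fingerprintCanonical <- function(canon, spec) {
  g <- molecularGraph(canon)
  envs <- .circularEnvironments(g, spec)
  v <- integer(spec@nbits)
  for (e in envs) v[e$id %% spec@nbits + 1L] <- 1L
  v
}

#' Fingerprint a set of compounds
#'
#' Computes the fingerprint matrix of a [CuratedDataset-class], a character
#' vector of SMILES, or an [ActivityTable-class] (its records' SMILES).
#'
#' @param x compounds to featurize.
#' @param spec a [FingerprintSpec-class].
#' @param ids optional row identifiers (defaults to the SMILES).
#' @return A [FingerprintMatrix-class] with rows aligned to the input order.
#' @export
featurizeDataset <- function(x, spec = fingerprintSpec(), ids = NULL) {
  smiles <- if (is(x, "CuratedDataset")) compounds(x)$smiles
            else if (is(x, "ActivityTable")) records(x)$smiles
            else as.character(x)
  if (is.null(ids)) {
    ids <- if (anyDuplicated(smiles)) sprintf("cpd%d", seq_along(smiles))
           else smiles
  }
  if (length(smiles) == 0L) {
    return(new("FingerprintMatrix",
               bits = matrix(integer(), 0L, spec@nbits),
               spec = spec, ids = character()))
  }
  canon <- canonicalSmiles(smiles)
  if (anyNA(canon)) stop("unparseable SMILES at rows: ",
                         paste(which(is.na(canon)), collapse = ", "))
  if (spec@family == "maccs") {
    bits <- .maccsBits(canon)
  } else {
    bits <- t(vapply(canon, .fingerprintCanonical, integer(spec@nbits),
                     spec = spec))
  }
  dimnames(bits) <- list(ids, sprintf("bit%d", seq_len(ncol(bits))))
  new("FingerprintMatrix", bits = bits, spec = spec, ids = ids)
}

#' Map fingerprint bits to atom environments
#'
#' For a hashed circular fingerprint, returns which atom environments set
#' each on-bit. Every on-bit of [fingerprint()] appears as a key; each value
#' is a list of integer atom-index vectors (central atom plus neighbors
#' within the radius, in canonical SDF order). Two different environments can
#' collide on one bit; both are listed.
#'
#' @param smiles a single SMILES string.
#' @param spec a hashed-family [FingerprintSpec-class] (`ecfp` or `fcfp`).
#' @return named list: names are bit indices (1-based, as `"b<index>"`),
#'   values lists of atom-index vectors.
#' @export
bitAtomMap <- function(smiles, spec = fingerprintSpec()) {
  if (spec@family == "maccs")
    stop("bit-atom maps are only defined for hashed circular fingerprints")
  canon <- canonicalSmiles(smiles)
  if (is.na(canon)) stop("unparseable SMILES: ", smiles)
  g <- molecularGraph(canon)
  envs <- .circularEnvironments(g, spec)
  out <- list()
  for (e in envs) {
    key <- sprintf("b%d", e$id %% spec@nbits + 1L)
    out[[key]] <- c(out[[key]], list(e$atoms))
  }
  out
}

#' Tanimoto similarity between two fingerprints
#'
#' @param a,b integer 0/1 vectors of equal length.
#' @return numeric similarity |intersection| / |union| (1 when both empty).
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(1)
  inter / uni
}
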