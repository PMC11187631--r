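## Structure handling on top of OpenBabel (via ChemmineR/ChemmineOB).
## All SMILES entering the modeling layers pass through normalizeStructure(),
## so downstream code can assume canonical, stereo-free, single-fragment,
## neutralized input.

# cache: canonical SMILES -> parsed molecular graph
.graphCache <- new.env(parent = emptyenv())

.obConvert <- function(smiles,
                       options = data.frame(names = character(),
                                            args = character())) {
  # Batch SMILES -> canonical SMILES through OpenBabel; unparseable entries
  # come back NA. Ids track rows because OB drops failed molecules.
  if (length(smiles) == 0L) return(character(0))
  ids <- sprintf("m%d", seq_along(smiles))
  src <- paste0(paste(smiles, ids, sep = "\t"), collapse = "\n")
  out <- suppressWarnings(tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", source = src, options = options),
    error = function(e) ""))
  res <- rep(NA_character_, length(smiles))
  if (nzchar(out)) {
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(trimws(lines))]
    for (ln in lines) {
      fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(fields) >= 2L) {
        idx <- match(trimws(fields[2]), ids)
        if (!is.na(idx)) res[idx] <- trimws(fields[1])
      }
    }
  }
  res[!is.na(res) & !nzchar(res)] <- NA_character_
  res
}

#' Canonicalize SMILES
#'
#' Converts SMILES strings to OpenBabel canonical form. Unparseable inputs
#' yield `NA`.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES (NA where unparseable).
#' @examples
#' canonicalSmiles(c("OCC", "C1=CC=CC=C1"))
#' @export
canonicalSmiles <- function(smiles) .obConvert(smiles)

.stripStereo <- function(smiles) {
  s <- gsub("[/\\\\]", "", smiles)
  # remove chirality tags inside bracket atoms: [C@@H] -> [CH]
  gsub("@", "", s, fixed = TRUE)
}

# does a single SMILES fragment contain carbon?
.hasCarbon <- function(fragment) {
  # bracket atoms: carbon iff symbol is C/c not followed by another lowercase
  brackets <- regmatches(fragment,
                         gregexpr("\\[[^]]*\\]", fragment))[[1]]
  for (b in brackets) {
    if (grepl("^\\[[0-9]*[Cc]($|[^a-z])", b)) return(TRUE)
  }
  bare <- gsub("\\[[^]]*\\]", "", fragment)
  if (grepl("c", bare, fixed = TRUE)) return(TRUE)
  # outside brackets, 'C' not followed by 'l' is carbon
  grepl("C(?!l)", bare, perl = TRUE)
}

#' Standardize a chemical structure
#'
#' Applies the curation-grade standardization used throughout the package:
#' stereo descriptors are stripped, counter-ions and solvent fragments without
#' carbon are removed, charges are neutralized where a proton can be added or
#' removed (charge-separated groups such as nitro are left intact), and the
#' result is canonicalized. Structures with no carbon-bearing fragment are
#' flagged `inorganic`; structures with two or more distinct organic fragments
#' are flagged `mixture`; strings OpenBabel cannot parse are `unparseable`.
#'
#' @param smiles character vector of SMILES strings.
#' @return data.frame with columns `input`, `smiles` (canonical or NA) and
#'   `reason` (NA when kept, else one of `unparseable`, `inorganic`,
#'   `mixture`).
#' @examples
#' normalizeStructure(c("CC(=O)[O-].[Na+]", "[Na+].[Cl-]", "C[C@H](N)C(=O)O"))
#' @export
normalizeStructure <- function(smiles) {
  n <- length(smiles)
  out <- data.frame(input = as.character(smiles),
                    smiles = NA_character_, reason = NA_character_,
                    stringsAsFactors = FALSE)
  work <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- trimws(smiles[i])
    if (is.na(s) || !nzchar(s)) { out$reason[i] <- "unparseable"; next }
    s <- .stripStereo(s)
    frags <- strsplit(s, ".", fixed = TRUE)[[1]]
    frags <- frags[nzchar(frags)]
    organic <- frags[vapply(frags, .hasCarbon, logical(1))]
    if (length(organic) == 0L) {
      # distinguish a genuinely carbon-free structure from garbage
      out$reason[i] <- if (is.na(.obConvert(s))) "unparseable" else "inorganic"
      next
    }
    organic <- unique(organic)
    if (length(organic) > 1L) {
      # distinct raw strings may still encode one molecule; compare canonically
      canon <- .obConvert(organic)
      if (anyNA(canon)) { out$reason[i] <- "unparseable"; next }
      organic <- organic[!duplicated(canon)]
      if (length(organic) > 1L) { out$reason[i] <- "mixture"; next }
    }
    work[i] <- organic[1]
  }
  todo <- which(!is.na(work))
  if (length(todo)) {
    canon <- .obConvert(work[todo],
                        options = data.frame(names = "neutralize", args = "",
                                             stringsAsFactors = FALSE))
    # neutralization can reintroduce nothing stereo, but canonical output may
    # still carry tags when OB retains ring-bond info; strip and re-canonicalize
    redo <- !is.na(canon) & grepl("[@/\\\\]", canon)
    if (any(redo)) canon[redo] <- .obConvert(.stripStereo(canon[redo]))
    out$smiles[todo] <- canon
    out$reason[todo][is.na(canon)] <- "unparseable"
  }
  out
}

.chargeFromCode <- function(code) {
  # V2000 atom-block charge codes: 1..7 -> +3,+2,+1,radical,-1,-2,-3
  map <- c(3L, 2L, 1L, 0L, -1L, -2L, -3L)
  ifelse(code >= 1 & code <= 7, map[pmax(code, 1)], 0L)
}

.defaultValence <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                     F = 1, Cl = 1, Br = 1, I = 1)

#' Molecular graph of a SMILES string
#'
#' Parses a (preferably standardized) SMILES into a heavy-atom graph:
#' element symbols, formal charges, implicit hydrogen counts, bond list with
#' orders, degree and ring membership. This is the substrate for the hashed
#' circular fingerprints and the atom attribution maps.
#'
#' @param smiles a single SMILES string.
#' @return list with elements `symbol`, `charge`, `nH`, `degree`, `inRing`
#'   (per atom, SDF order) and `bonds` (data.frame from, to, order).
#' @export
molecularGraph <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  key <- smiles
  hit <- get0(key, envir = .graphCache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  sdfset <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                     error = function(e) NULL)
  if (is.null(sdfset) || length(sdfset) == 0L)
    stop("unparseable SMILES: ", smiles)
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  symbol <- sub("_\\d+$", "", rownames(ab))
  natoms <- length(symbol)
  chargeCol <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, natoms)
  charge <- .chargeFromCode(as.integer(chargeCol))
  if (is.null(dim(bb)) || nrow(bb) == 0L || ncol(bb) < 3L ||
      all(bb[, 1] == 0)) {  # bond-free molecules get a zero-filled stub
    bonds <- data.frame(from = integer(), to = integer(), order = integer())
  } else {
    bonds <- data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  }
  degree <- tabulate(c(bonds$from, bonds$to), nbins = natoms)
  bondSum <- numeric(natoms)
  for (j in seq_len(nrow(bonds))) {
    o <- bonds$order[j]
    bondSum[bonds$from[j]] <- bondSum[bonds$from[j]] + o
    bondSum[bonds$to[j]] <- bondSum[bonds$to[j]] + o
  }
  defv <- .defaultValence[symbol]
  defv[is.na(defv)] <- 0
  nH <- pmax(0, defv - bondSum + charge)
  inRing <- .ringAtoms(natoms, bonds)
  g <- list(symbol = symbol, charge = charge, nH = as.integer(nH),
            degree = as.integer(degree), inRing = inRing, bonds = bonds)
  assign(key, g, envir = .graphCache)
  g
}

# atoms incident to at least one cycle edge (non-bridge) are ring atoms
.ringAtoms <- function(natoms, bonds) {
  inRing <- rep(FALSE, natoms)
  if (nrow(bonds) == 0L) return(inRing)
  adj <- vector("list", natoms)
  for (j in seq_len(nrow(bonds))) {
    a <- bonds$from[j]; b <- bonds$to[j]
    adj[[a]] <- c(adj[[a]], j)
    adj[[b]] <- c(adj[[b]], j)
  }
  reachable <- function(src, dst, skipEdge) {
    seen <- rep(FALSE, natoms)
    stack <- src; seen[src] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v == dst) return(TRUE)
      for (j in adj[[v]]) {
        if (j == skipEdge) next
        w <- if (bonds$from[j] == v) bonds$to[j] else bonds$from[j]
        if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
      }
    }
    FALSE
  }
  for (j in seq_len(nrow(bonds))) {
    if (reachable(bonds$from[j], bonds$to[j], j)) {
      inRing[bonds$from[j]] <- TRUE
      inRing[bonds$to[j]] <- TRUE
    }
  }
  inRing
}
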