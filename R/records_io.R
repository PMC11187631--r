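## Reading/writing bioactivity tables. All concentrations are held in their
## reported units in the records and converted to molar exactly once, at
## pIC50 computation time.

.RELATION_TOKENS <- c("=" = "eq", "<" = "lt", ">" = "gt",
                      "<=" = "le", ">=" = "ge",
                      "eq" = "eq", "lt" = "lt", "gt" = "gt",
                      "le" = "le", "ge" = "ge")

.UNIT_TOKENS <- c("nM" = "nM", "nm" = "nM",
                  "uM" = "uM", "um" = "uM", "µM" = "uM", "μM" = "uM",
                  "M" = "M")

#' Convert a concentration to molar
#'
#' @param value positive numeric concentration(s).
#' @param units `"nM"`, `"uM"` or `"M"` (recycled).
#' @return numeric molar concentration.
#' @examples
#' toMolar(10, "uM")   # 1e-5
#' toMolar(1, "nM")    # 1e-9
#' @export
toMolar <- function(value, units) {
  if (any(!is.finite(value) | value <= 0))
    stop("concentrations must be positive and finite")
  factor <- c(nM = 1e-9, uM = 1e-6, M = 1)[units]
  if (anyNA(factor)) stop("unsupported units: ",
                          paste(unique(units[is.na(factor)]), collapse = ", "))
  unname(value * factor)
}

#' Default mapping from assay cell-line annotations to assay types
#'
#' hERG bioactivity exports annotate measurements with the expression system:
#' HEK293 or CHO cell lines, or none for single-protein (patch clamp on the
#' channel itself, SP). The mapping is a heuristic and user-replaceable.
#'
#' @param x character vector of cell-line annotations.
#' @return character vector over SP/HEK/CHO/other.
#' @export
defaultAssayMap <- function(x) {
  x <- ifelse(is.na(x), "", x)
  out <- rep("SP", length(x))
  out[grepl("HEK", x, ignore.case = TRUE)] <- "HEK"
  out[grepl("CHO", x, ignore.case = TRUE)] <- "CHO"
  out
}

#' Construct an activity table from records
#'
#' @param records data.frame with columns compoundId, smiles, assayType,
#'   relation, value, units (pic50 is derived).
#' @param rejects optional data.frame of rejected rows.
#' @param provenance free-text source description.
#' @param truth optional generator bookkeeping list.
#' @return An [ActivityTable-class].
#' @export
activityTable <- function(records, rejects = data.frame(),
                          provenance = "", truth = list()) {
  if (nrow(records)) {
    records$pic50 <- -log10(toMolar(records$value, records$units))
    records <- records[, RECORD_COLUMNS]
    rownames(records) <- NULL
  }
  new("ActivityTable", records = records, rejects = rejects,
      provenance = provenance, truth = truth)
}

#' Read a bioactivity table
#'
#' Parses a CSV of assay measurements into an [ActivityTable-class]. Two
#' dialects are supported: `simple_csv` (columns compound_id, smiles,
#' assay_type, relation, value, units) and `chembl_csv` (a ChEMBL-style
#' export with molecule_chembl_id, canonical_smiles, standard_relation,
#' standard_value, standard_units and a cell-line annotation column mapped
#' to assay types via `assayMap`). Rows that cannot be interpreted (missing
#' SMILES, unknown relation token, unsupported units, non-positive value)
#' are collected in the rejects slot with a reason, never silently dropped.
#'
#' @param source path to a CSV file.
#' @param dialect `"simple_csv"` or `"chembl_csv"`.
#' @param assayMap function mapping cell-line annotations to assay types
#'   (chembl dialect only).
#' @param provenance free-text source description.
#' @return An [ActivityTable-class].
#' @export
readActivityTable <- function(source,
                              dialect = c("simple_csv", "chembl_csv"),
                              assayMap = defaultAssayMap,
                              provenance = source) {
  dialect <- match.arg(dialect)
  if (!file.exists(source)) stop("no such file: ", source)
  raw <- utils::read.csv(source, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (dialect == "simple_csv") {
    need <- c("compound_id", "smiles", "assay_type", "relation",
              "value", "units")
    if (!all(need %in% colnames(raw)))
      stop("missing required column(s): ",
           paste(setdiff(need, colnames(raw)), collapse = ", "))
    df <- data.frame(compoundId = raw$compound_id, smiles = raw$smiles,
                     assayRaw = raw$assay_type, relation = raw$relation,
                     value = raw$value, units = raw$units,
                     stringsAsFactors = FALSE)
    df$assayType <- ifelse(df$assayRaw %in% c("SP", "HEK", "CHO"),
                           df$assayRaw, "other")
  } else {
    need <- c("molecule_chembl_id", "canonical_smiles", "standard_relation",
              "standard_value", "standard_units")
    if (!all(need %in% colnames(raw)))
      stop("missing required column(s): ",
           paste(setdiff(need, colnames(raw)), collapse = ", "))
    cellCol <- intersect(c("assay_cell_type", "cell_line", "assay_type"),
                         colnames(raw))
    cells <- if (length(cellCol)) raw[[cellCol[1]]] else rep("", nrow(raw))
    df <- data.frame(compoundId = raw$molecule_chembl_id,
                     smiles = raw$canonical_smiles,
                     assayRaw = cells, relation = raw$standard_relation,
                     value = raw$standard_value, units = raw$standard_units,
                     stringsAsFactors = FALSE)
    df$assayType <- assayMap(df$assayRaw)
  }
  reason <- rep(NA_character_, nrow(df))
  df$relation <- trimws(df$relation)
  rel <- .RELATION_TOKENS[df$relation]
  reason[is.na(rel)] <- "unknown relation"
  unit <- .UNIT_TOKENS[trimws(df$units)]
  reason[is.na(reason) & is.na(unit)] <- "unsupported units"
  val <- suppressWarnings(as.numeric(df$value))
  reason[is.na(reason) & (is.na(val) | val <= 0)] <- "non-positive value"
  noSmiles <- is.na(df$smiles) | !nzchar(trimws(df$smiles))
  reason[is.na(reason) & noSmiles] <- "missing smiles"

  bad <- !is.na(reason)
  rejectDf <- if (any(bad)) {
    cbind(data.frame(row = which(bad), reason = reason[bad],
                     stringsAsFactors = FALSE),
          df[bad, c("compoundId", "smiles", "relation", "value", "units")])
  } else data.frame()
  keepDf <- df[!bad, , drop = FALSE]
  recs <- data.frame(compoundId = keepDf$compoundId,
                     smiles = trimws(keepDf$smiles),
                     assayType = keepDf$assayType,
                     relation = unname(rel[!bad]),
                     value = val[!bad],
                     units = unname(unit[!bad]),
                     stringsAsFactors = FALSE)
  rownames(rejectDf) <- NULL
  activityTable(recs, rejects = rejectDf, provenance = provenance)
}

#' Write a dataset to disk
#'
#' Writes an [ActivityTable-class] as CSV (the `simple_csv` dialect, which
#' round-trips field-for-field through [readActivityTable()]), as a SMILES
#' file (`smiles<TAB>id` lines) or as an SDF V2000 with the record fields
#' attached as molecule properties.
#'
#' @param table an [ActivityTable-class]; all records must carry a SMILES.
#' @param dest output path.
#' @param format `"csv"`, `"smi"` or `"sdf"`.
#' @return `dest`, invisibly.
#' @export
writeDataset <- function(table, dest, format = c("csv", "smi", "sdf")) {
  format <- match.arg(format)
  recs <- records(table)
  if (nrow(recs) == 0L && format != "csv")
    stop("refusing to write an empty table as ", format)
  if (nrow(recs) && any(is.na(recs$smiles) | !nzchar(recs$smiles)))
    stop("all records must have a SMILES before writing")
  if (format == "csv") {
    out <- data.frame(compound_id = recs$compoundId, smiles = recs$smiles,
                      assay_type = recs$assayType, relation = recs$relation,
                      value = sprintf("%.17g", recs$value),
                      units = recs$units, stringsAsFactors = FALSE)
    utils::write.csv(out, dest, row.names = FALSE, quote = TRUE)
  } else if (format == "smi") {
    writeLines(paste(recs$smiles, recs$compoundId, sep = "\t"), dest)
  } else {
    sdf <- ChemmineR::smiles2sdf(stats::setNames(recs$smiles,
                                                 recs$compoundId))
    ChemmineR::datablock(sdf) <- lapply(seq_along(sdf), function(i)
      c(compound_id = recs$compoundId[i], assay_type = recs$assayType[i],
        relation = recs$relation[i],
        value = sprintf("%.17g", recs$value[i]), units = recs$units[i]))
    ChemmineR::write.SDF(sdf, dest, cid = TRUE)
  }
  invisible(dest)
}
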