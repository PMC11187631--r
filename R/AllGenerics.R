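#' @include AllClasses.R
NULL

#' Records of an activity table
#' @param x an [ActivityTable-class].
#' @return data.frame of activity records.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname records
#' @export
setMethod("records", "ActivityTable", function(x) x@records)

#' Rejected rows of an activity table
#' @param x an [ActivityTable-class].
#' @return data.frame of rejected rows with reasons.
#' @export
setGeneric("rejects", function(x) standardGeneric("rejects"))

#' @rdname rejects
#' @export
setMethod("rejects", "ActivityTable", function(x) x@rejects)

#' Compounds of a curated dataset
#' @param x a [CuratedDataset-class].
#' @return data.frame with smiles, pic50 and label.
#' @export
setGeneric("compounds", function(x) standardGeneric("compounds"))

#' @rdname compounds
#' @export
setMethod("compounds", "CuratedDataset", function(x) x@compounds)

#' Curation report of a dataset
#' @param x a [CuratedDataset-class].
#' @return the [CurationReport-class].
#' @export
setGeneric("curationReport", function(x) standardGeneric("curationReport"))

#' @rdname curationReport
#' @export
setMethod("curationReport", "CuratedDataset", function(x) x@report)

#' Per-rule removal counts
#' @param x a [CurationReport-class] or [CuratedDataset-class].
#' @return named integer vector of removal counts plus `kept`.
#' @export
setGeneric("removalCounts", function(x) standardGeneric("removalCounts"))

#' @rdname removalCounts
#' @export
setMethod("removalCounts", "CurationReport", function(x) x@counts)

#' @rdname removalCounts
#' @export
setMethod("removalCounts", "CuratedDataset", function(x) x@report@counts)

#' Task of a dataset or model
#' @param x a [CuratedDataset-class] or [HergModel-class].
#' @return character task name.
#' @export
setGeneric("modelTask", function(x) standardGeneric("modelTask"))

#' @rdname modelTask
#' @export
setMethod("modelTask", "CuratedDataset", function(x) x@task)

#' @rdname modelTask
#' @export
setMethod("modelTask", "HergModel", function(x) x@task)

#' Bit matrix of a fingerprint matrix
#' @param x a [FingerprintMatrix-class].
#' @return integer 0/1 matrix.
#' @export
setGeneric("fpBits", function(x) standardGeneric("fpBits"))

#' @rdname fpBits
#' @export
setMethod("fpBits", "FingerprintMatrix", function(x) x@bits)

#' Fingerprint specification of an object
#' @param x a [FingerprintMatrix-class] or [HergModel-class].
#' @return the [FingerprintSpec-class].
#' @export
setGeneric("fpSpec", function(x) standardGeneric("fpSpec"))

#' @rdname fpSpec
#' @export
setMethod("fpSpec", "FingerprintMatrix", function(x) x@spec)

#' @rdname fpSpec
#' @export
setMethod("fpSpec", "HergModel", function(x) x@fingerprint)

#' Compound ids
#' @param x a [FingerprintMatrix-class] or [AttributionMatrix-class].
#' @return character vector of ids.
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' @rdname compoundIds
#' @export
setMethod("compoundIds", "FingerprintMatrix", function(x) x@ids)

#' @rdname compoundIds
#' @export
setMethod("compoundIds", "AttributionMatrix", function(x) x@ids)

#' Applicability-domain cutoff
#' @param x an [ADModel-class].
#' @return numeric distance cutoff Dc.
#' @export
setGeneric("adCutoff", function(x) standardGeneric("adCutoff"))

#' @rdname adCutoff
#' @export
setMethod("adCutoff", "ADModel", function(x) x@cutoff)

#' Attribution values
#' @param x an [AttributionMatrix-class].
#' @return numeric matrix of signed per-bit contributions.
#' @export
setGeneric("attributions", function(x) standardGeneric("attributions"))

#' @rdname attributions
#' @export
setMethod("attributions", "AttributionMatrix", function(x) x@values)

#' Per-atom weights of an attribution map
#' @param x an [AtomAttributionMap-class].
#' @return numeric vector of signed atom weights.
#' @export
setGeneric("atomWeights", function(x) standardGeneric("atomWeights"))

#' @rdname atomWeights
#' @export
setMethod("atomWeights", "AtomAttributionMap", function(x) x@weights)

setMethod("show", "FingerprintSpec", function(object) {
  cat(sprintf("FingerprintSpec: %s, radius %d, %d bits\n",
              toupper(object@family), object@radius, object@nbits))
})

setMethod("show", "ActivityTable", function(object) {
  cat(sprintf("ActivityTable: %d records, %d rejects\n",
              nrow(object@records), nrow(object@rejects)))
  if (nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "CurationReport", function(object) {
  cat(sprintf("CurationReport: %d records in, %d kept\n",
              object@nInput, object@counts[["kept"]]))
  rem <- object@counts[setdiff(names(object@counts), "kept")]
  rem <- rem[rem > 0L]
  if (length(rem))
    cat("  removed: ",
        paste(sprintf("%s=%d", names(rem), rem), collapse = ", "), "\n")
  if (!is.na(object@experimentalMae))
    cat(sprintf("  experimental MAE (duplicates): %.3f\n",
                object@experimentalMae))
})

setMethod("show", "CuratedDataset", function(object) {
  cat(sprintf("CuratedDataset (%s): %d compounds\n",
              object@task, nrow(object@compounds)))
  if (object@task != "regression" && nrow(object@compounds))
    print(table(object@compounds$label))
})

setMethod("show", "FingerprintMatrix", function(object) {
  cat(sprintf("FingerprintMatrix: %d compounds x %d bits (%s, radius %d)\n",
              nrow(object@bits), ncol(object@bits),
              toupper(object@spec@family), object@spec@radius))
})

setMethod("show", "ADModel", function(object) {
  cat(sprintf(
    "ADModel: %d reference compounds, k=%d, z=%.2f, cutoff Dc=%.4f\n",
    nrow(object@reference), object@k, object@z, object@cutoff))
})

setMethod("show", "HergModel", function(object) {
  cat(sprintf("HergModel: %s %s on %s-%d (%d training compounds, seed %d)\n",
              object@task, object@algorithm,
              toupper(object@fingerprint@family), object@fingerprint@nbits,
              length(object@trainIds), object@seed))
})

setMethod("show", "AttributionMatrix", function(object) {
  cat(sprintf("AttributionMatrix (%s): %d compounds x %d bits, base %.4f\n",
              object@method, nrow(object@values), ncol(object@values),
              object@baseValue))
})

setMethod("show", "AtomAttributionMap", function(object) {
  cat(sprintf("AtomAttributionMap (%s): %s\n", object@method, object@smiles))
  cat("  atom weights:",
      paste(sprintf("%.3f", object@weights), collapse = " "), "\n")
})
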