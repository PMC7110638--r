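#' @name accessors
#' @title Accessors for IdMapper classes
#'
#' @description Small accessor generics so user code never touches slots
#' directly: source keys and element counts of a [SourceIndex-class], field
#' labels and record counts of a [ParsedTable-class], pair counts of a
#' [MappingSet-class], and the candidate table of a
#' [FieldClassification-class].
#'
#' @param x The object to access.
#' @return The corresponding slot value; see each method.
NULL

#' @rdname accessors
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))
#' @rdname accessors
#' @export
setGeneric("subsetId", function(x) standardGeneric("subsetId"))
#' @rdname accessors
#' @export
setGeneric("elementCount", function(x) standardGeneric("elementCount"))
#' @rdname accessors
#' @export
setGeneric("fieldLabels", function(x) standardGeneric("fieldLabels"))
#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))
#' @rdname accessors
#' @export
setGeneric("nFields", function(x) standardGeneric("nFields"))
#' @rdname accessors
#' @export
setGeneric("headerRowsRemoved", function(x) standardGeneric("headerRowsRemoved"))
#' @rdname accessors
#' @export
setGeneric("sourceFormat", function(x) standardGeneric("sourceFormat"))
#' @rdname accessors
#' @export
setGeneric("sampleValues", function(x) standardGeneric("sampleValues"))
#' @rdname accessors
#' @export
setGeneric("fieldSpecs", function(x) standardGeneric("fieldSpecs"))
#' @rdname accessors
#' @export
setGeneric("fromSource", function(x) standardGeneric("fromSource"))
#' @rdname accessors
#' @export
setGeneric("toSource", function(x) standardGeneric("toSource"))
#' @rdname accessors
#' @export
setGeneric("pairCount", function(x) standardGeneric("pairCount"))
#' @rdname accessors
#' @export
setGeneric("mappingPairs", function(x) standardGeneric("mappingPairs"))
#' @rdname accessors
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))
#' @rdname accessors
#' @export
setGeneric("isHighConfidence", function(x) standardGeneric("isHighConfidence"))
#' @rdname accessors
#' @export
setGeneric("reportCounts", function(x) standardGeneric("reportCounts"))

setMethod("sourceId", "SourceIndex", function(x) x@sourceId)
setMethod("sourceId", "SourceMetadata", function(x) x@sourceId)
setMethod("subsetId", "SourceIndex", function(x) x@subsetId)
setMethod("elementCount", "SourceIndex", function(x) x@elementCount)

setMethod("fieldLabels", "ParsedTable", function(x) x@labels)
setMethod("records", "ParsedTable", function(x) x@records)
setMethod("nRecords", "ParsedTable", function(x) nrow(x@records))
setMethod("nFields", "ParsedTable", function(x) length(x@labels))
setMethod("headerRowsRemoved", "ParsedTable", function(x) x@headerRowsRemoved)
setMethod("sourceFormat", "ParsedTable", function(x) x@sourceFormat)
setMethod("sampleValues", "ParsedTable", function(x) x@sampleValues)
setMethod("fieldSpecs", "ParsedTable", function(x) {
  data.frame(
    index = seq_along(x@labels) - 1L,
    label = x@labels,
    sampleValues = I(x@sampleValues),
    row.names = NULL
  )
})

setMethod("fromSource", "MappingSet", function(x) x@fromSource)
setMethod("toSource", "MappingSet", function(x) x@toSource)
setMethod("fromSource", "TranslationReport", function(x) x@fromSource)
setMethod("toSource", "TranslationReport", function(x) x@toSource)
setMethod("pairCount", "MappingSet", function(x) nrow(x@pairs))
setMethod("mappingPairs", "MappingSet", function(x) x@pairs)

setMethod("candidates", "FieldClassification", function(x) x@candidates)
setMethod("isHighConfidence", "FieldClassification", function(x) x@highConfidence)

setMethod("reportCounts", "TranslationReport", function(x) {
  c(
    totalRows = x@totalRows,
    distinctValues = x@distinctValues,
    matchedUnique = x@matchedUnique,
    ambiguous = x@ambiguous,
    missing = x@missing,
    versionStrippedMatches = x@versionStrippedMatches,
    rowsDropped = x@rowsDropped
  )
})

setMethod("show", "BloomFilter", function(object) {
  cat(sprintf(
    "BloomFilter: m=%d bits, k=%d, %d insertions, analytic FPR %.3g\n",
    as.integer(object@m), object@k, as.integer(object@nInserted),
    analyticFPR(object)
  ))
})

setMethod("show", "SourceIndex", function(object) {
  cat(sprintf(
    "SourceIndex '%s'%s: %d identifiers, m=%d, k=%d\n",
    object@sourceId,
    if (nzchar(object@subsetId)) sprintf(" [%s]", object@subsetId) else "",
    as.integer(object@elementCount),
    as.integer(object@filter@m), object@filter@k
  ))
})

setMethod("show", "ParsedTable", function(object) {
  cat(sprintf(
    "ParsedTable (%s): %d records x %d fields, %d header row(s) removed\n",
    object@sourceFormat, nrow(object@records), length(object@labels),
    object@headerRowsRemoved
  ))
  cat("  fields:", paste(object@labels, collapse = ", "), "\n")
})

setMethod("show", "MappingSet", function(object) {
  cat(sprintf(
    "MappingSet %s -> %s: %d pairs, %d distinct left values\n",
    object@fromSource, object@toSource, nrow(object@pairs),
    length(ls(object@index, all.names = TRUE))
  ))
})

setMethod("show", "FieldClassification", function(object) {
  if (object@empty) {
    cat(sprintf("FieldClassification[field %d]: empty field\n",
                object@fieldIndex))
    return(invisible(NULL))
  }
  cat(sprintf(
    "FieldClassification[field %d]: %d candidate(s), high confidence: %s\n",
    object@fieldIndex, nrow(object@candidates), object@highConfidence
  ))
  if (nrow(object@candidates)) {
    top <- utils::head(object@candidates, 3L)
    for (i in seq_len(nrow(top))) {
      cat(sprintf("  %d. %s  match_rate=%.3f coverage=%.3f\n", i,
                  top$sourceId[i], top$matchRate[i], top$coverage[i]))
    }
  }
})

setMethod("show", "TranslationReport", function(object) {
  cat(sprintf("TranslationReport %s -> %s\n", object@fromSource,
              object@toSource))
  counts <- reportCounts(object)
  for (nm in names(counts)) cat(sprintf("  %s: %d\n", nm, counts[[nm]]))
})
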