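# Field classification: aggregate a column's values, query every source
# index, rank candidates by match rate then coverage. Matching is exact-case
# and byte-exact; the only tolerated variation is an optional second pass
# with trailing ".digit" version suffixes stripped, which is always flagged.

#' Aggregate the distinct values of one field
#'
#' Values are whitespace-trimmed, empties dropped, duplicates removed, and
#' first-occurrence order preserved. Beyond trimming, the original text is
#' untouched — no case folding, no number parsing.
#'
#' @param table A [ParsedTable-class].
#' @param fieldIndex 1-based column index.
#' @return Character vector (possibly empty).
#' @export
aggregateValues <- function(table, fieldIndex) {
  stopifnot(is(table, "ParsedTable"))
  if (fieldIndex < 1L || fieldIndex > nFields(table))
    idmStop("InvalidArgument", "fieldIndex %d out of range (1..%d)",
            fieldIndex, nFields(table))
  v <- trimws(table@records[, fieldIndex])
  unique(v[nzchar(v)])
}

.stripVersion <- function(x) sub("\\.[0-9]+$", "", x)

# Score one index against a value list. Returns NULL when nothing matches.
.scoreIndex <- function(values, idx, threshold) {
  hits <- bloomContains(idx@filter, values)
  versionStripped <- FALSE
  if (mean(hits) < threshold && any(grepl("\\.[0-9]+$", values))) {
    stripped <- bloomContains(idx@filter, .stripVersion(values))
    if (sum(hits | stripped) > sum(hits)) {
      hits <- hits | stripped
      versionStripped <- TRUE
    }
  }
  matched <- sum(hits)
  if (matched == 0L) return(NULL)
  data.frame(
    sourceId = idx@sourceId,
    subsetId = idx@subsetId,
    matchRate = matched / length(values),
    coverage = matched / idx@elementCount,
    elementCount = idx@elementCount,
    versionStripped = versionStripped,
    matchedSamples = I(list(utils::head(values[hits], 5L))),
    stringsAsFactors = FALSE
  )
}

#' Classify one field against a set of source indexes
#'
#' For every index, the match rate (fraction of the distinct values found in
#' the index) and coverage (matched values / source size) are computed via
#' Bloom membership. Candidates that match nothing are dropped; the rest are
#' ranked by match rate (desc), coverage (desc), source size (asc), then
#' source key — a total order, so ranking is deterministic. The field is
#' high-confidence when the top match rate reaches `threshold`, except that
#' integer-looking fields with two or more candidates at or above the
#' threshold are never auto-confirmed: bare integers are exactly where
#' namespaces collide.
#'
#' @param values Distinct field values from [aggregateValues()].
#' @param indexes List of [SourceIndex-class] objects.
#' @param threshold High-confidence match-rate threshold (default 0.95).
#' @param fieldIndex 1-based ordinal recorded on the result.
#' @return A [FieldClassification-class].
#' @section Errors: `EmptyField` when `values` is empty — classification of
#'   an empty column is undefined, not zero.
#' @export
classifyField <- function(values, indexes, threshold = 0.95,
                          fieldIndex = 1L) {
  if (!length(indexes))
    idmStop("InvalidArgument", "at least one source index is required")
  if (!length(values))
    idmStop("EmptyField", "field %d has no non-empty values", fieldIndex)
  values <- as.character(values)
  scored <- Filter(Negate(is.null),
                   lapply(indexes, .scoreIndex, values = values,
                          threshold = threshold))
  if (length(scored)) {
    cand <- do.call(rbind, c(scored, list(make.row.names = FALSE)))
    ord <- order(-cand$matchRate, -cand$coverage, cand$elementCount,
                 cand$sourceId, cand$subsetId)
    cand <- cand[ord, , drop = FALSE]
    rownames(cand) <- NULL
  } else {
    cand <- data.frame(
      sourceId = character(), subsetId = character(),
      matchRate = numeric(), coverage = numeric(),
      elementCount = numeric(), versionStripped = logical(),
      matchedSamples = I(list())
    )
  }
  high <- nrow(cand) > 0L && cand$matchRate[1] >= threshold
  if (high && all(grepl("^[0-9]+$", values)) &&
      sum(cand$matchRate >= threshold) >= 2L)
    high <- FALSE
  new("FieldClassification",
    fieldIndex = as.integer(fieldIndex), candidates = cand,
    highConfidence = high, empty = FALSE, nValues = length(values)
  )
}

#' Classify every field of a table
#'
#' Empty fields are flagged (`empty = TRUE`) rather than failing the batch.
#'
#' @param table A [ParsedTable-class].
#' @param indexes List of [SourceIndex-class] objects.
#' @param threshold See [classifyField()].
#' @return List of [FieldClassification-class], one per field.
#' @export
classifyTable <- function(table, indexes, threshold = 0.95) {
  stopifnot(is(table, "ParsedTable"))
  lapply(seq_len(nFields(table)), function(j) {
    vals <- aggregateValues(table, j)
    tryCatch(
      classifyField(vals, indexes, threshold = threshold, fieldIndex = j),
      EmptyField = function(e) new("FieldClassification",
        fieldIndex = j,
        candidates = data.frame(
          sourceId = character(), subsetId = character(),
          matchRate = numeric(), coverage = numeric(),
          elementCount = numeric(), versionStripped = logical(),
          matchedSamples = I(list())
        ),
        highConfidence = FALSE, empty = TRUE, nValues = 0L
      )
    )
  })
}
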