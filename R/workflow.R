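# End-to-end run: ingest -> classify -> translate -> export, with the
# analysis log threaded through every stage. This is what the command-line
# wrapper drives.

#' Run the full translation pipeline on one document
#'
#' Parses the document, classifies the chosen field against the supplied
#' indexes (recording a warning in the log when the top classification
#' disagrees with the mapping's origin source), translates it in place, and
#' writes the complete export archive.
#'
#' @param doc A [RawDocument-class] or file path.
#' @param field 1-based column index, or a field label.
#' @param mapping A [MappingSet-class].
#' @param registry Named list of [SourceMetadata-class] from
#'   [loadSourceRegistry()]; must contain both of the mapping's sources.
#' @param outZip Output archive path.
#' @param indexes Optional named list of [SourceIndex-class] used to
#'   classify the field before translating.
#' @param policy A [TranslationPolicy-class].
#' @param keepOriginal Append the translated column instead of replacing;
#'   see [translateTable()].
#' @param threshold Classification threshold, see [classifyField()].
#' @param timestamp Injected ISO-8601 timestamp used throughout.
#' @param runId Run identifier; defaults to a digest of input and mapping.
#' @return List with `table`, `report`, `classification` (or `NULL`),
#'   `log`, and `zipPath`.
#' @export
runTranslation <- function(doc, field, mapping, registry, outZip,
                           indexes = NULL,
                           policy = translationPolicy(),
                           keepOriginal = FALSE,
                           threshold = 0.95,
                           timestamp = "1970-01-01T00:00:00Z",
                           runId = NULL) {
  if (is.character(doc)) doc <- readDocument(doc)
  inputDigest <- digest::digest(doc@content, algo = "sha256",
                                serialize = FALSE)
  if (is.null(runId))
    runId <- substr(digest::digest(
      list(inputDigest, mapping@fromSource, mapping@toSource),
      algo = "sha256"
    ), 1, 12)
  log <- analysisLog(runId, inputDigest = inputDigest)

  fmt <- detectFormat(doc)
  table <- buildTable(doc)
  log <- logEntry(log, "ingest",
    sprintf("parsed %s document: %d records, %d fields, %d header row(s)",
            fmt, nRecords(table), nFields(table),
            headerRowsRemoved(table)),
    details = list(format = fmt, records = nRecords(table),
                   fields = nFields(table)),
    timestamp = timestamp)

  if (is.character(field)) {
    idx <- match(field, fieldLabels(table))
    if (is.na(idx))
      idmStop("InvalidArgument", "no field labelled '%s' (have: %s)",
              field, paste(fieldLabels(table), collapse = ", "))
    field <- idx
  }
  field <- as.integer(field)

  classification <- NULL
  expected <- NULL
  if (!is.null(indexes) && length(indexes)) {
    values <- aggregateValues(table, field)
    classification <- classifyField(values, indexes,
                                    threshold = threshold,
                                    fieldIndex = field)
    cand <- candidates(classification)
    topSource <- if (nrow(cand)) cand$sourceId[1] else NA_character_
    expected <- topSource
    log <- logEntry(log, "classify",
      sprintf("field %d ('%s'): top candidate %s, high confidence: %s",
              field, fieldLabels(table)[field],
              ifelse(is.na(topSource), "<none>", topSource),
              isHighConfidence(classification)),
      details = list(
        field = field,
        top_source = topSource,
        match_rate = if (nrow(cand)) cand$matchRate[1] else 0,
        coverage = if (nrow(cand)) cand$coverage[1] else 0,
        high_confidence = isHighConfidence(classification)
      ),
      timestamp = timestamp)
    if (!is.na(topSource) && topSource != mapping@fromSource)
      log <- logEntry(log, "classify",
        sprintf(
          "warning: field classified as '%s' but mapping translates from '%s'",
          topSource, mapping@fromSource),
        timestamp = timestamp)
  } else {
    log <- logEntry(log, "classify",
      "classification skipped: no indexes supplied (user-specified source)",
      timestamp = timestamp)
  }

  res <- withCallingHandlers(
    translateTable(table, field, mapping, policy = policy,
                   keepOriginal = keepOriginal,
                   expectedSource = NULL, timestamp = timestamp),
    warning = function(w) invokeRestart("muffleWarning")
  )
  counts <- reportCounts(res$report)
  log <- logEntry(log, "translate",
    sprintf("translated field %d: %d distinct values (%d unique, %d ambiguous, %d missing)",
            field, counts[["distinctValues"]], counts[["matchedUnique"]],
            counts[["ambiguous"]], counts[["missing"]]),
    details = as.list(counts), timestamp = timestamp)

  for (key in c(mapping@fromSource, mapping@toSource)) {
    if (is.null(registry[[key]]))
      idmStop("IncompleteMetadata",
              "source '%s' has no entry in the metadata registry", key)
  }
  log <- logEntry(log, "export",
    sprintf("writing archive '%s'", basename(outZip)),
    timestamp = timestamp)
  bundle <- exportBundle(res$table, res$report,
                         registry[[mapping@fromSource]],
                         registry[[mapping@toSource]], log)
  writeArchive(bundle, outZip, timestamp = timestamp)
  list(table = res$table, report = res$report,
       classification = classification, log = log, zipPath = outZip)
}
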