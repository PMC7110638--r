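#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib IdMapper, .registration = TRUE
NULL

#' Bloom filter over identifier strings
#'
#' A plain Bloom filter: a bit array of length `m`, `k` hash probes per value,
#' and a recorded hash seed. Membership queries have no false negatives; false
#' positives occur at approximately `(1 - exp(-k*n/m))^k` for `n` inserted
#' elements. Values are hashed as their exact bytes — no case folding or
#' whitespace normalization happens at this layer.
#'
#' @slot bits Raw vector holding the packed bit array (`ceiling(m/8)` bytes).
#' @slot m Number of bits.
#' @slot k Number of hash probes per value (1--32).
#' @slot nInserted Number of add operations performed (distinctness is the
#'   caller's accounting).
#' @slot seed Integer hash salt recorded so indexes are reproducible across
#'   runs and machines.
#' @seealso [bloomCreate()], [bloomAdd()], [bloomContains()]
#' @exportClass BloomFilter
setClass("BloomFilter",
  representation(
    bits = "raw",
    m = "numeric",
    k = "integer",
    nInserted = "numeric",
    seed = "integer"
  )
)

setValidity("BloomFilter", function(object) {
  msg <- character()
  if (length(object@m) != 1L || is.na(object@m) || object@m < 1)
    msg <- c(msg, "m must be a single positive number")
  if (length(object@k) != 1L || is.na(object@k) ||
      object@k < 1L || object@k > 32L)
    msg <- c(msg, "k must be in [1, 32]")
  if (length(object@m) == 1L && !is.na(object@m) &&
      length(object@bits) != ceiling(object@m / 8))
    msg <- c(msg, "bit array length does not match m")
  if (object@nInserted < 0)
    msg <- c(msg, "nInserted must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Membership index for one identifier source
#'
#' Couples a [BloomFilter-class] with the identity of the identifier source it
#' indexes: a source key (e.g. `"ensembl_gene"`), a subset tag (species or
#' assembly), the exact number of distinct identifiers loaded, and a reference
#' into the source-metadata registry used for citations and access dates.
#'
#' @slot sourceId Source key, e.g. `"ensembl_gene"`.
#' @slot subsetId Subset tag (species/assembly), may be `""`.
#' @slot filter The [BloomFilter-class] over the source's identifiers.
#' @slot elementCount Exact number of distinct identifiers loaded (>= 1).
#' @slot metadataRef Key into the provenance registry.
#' @seealso [buildSourceIndex()], [indexSave()], [indexLoad()]
#' @exportClass SourceIndex
setClass("SourceIndex",
  representation(
    sourceId = "character",
    subsetId = "character",
    filter = "BloomFilter",
    elementCount = "numeric",
    metadataRef = "character"
  )
)

setValidity("SourceIndex", function(object) {
  msg <- character()
  if (length(object@sourceId) != 1L || !nzchar(object@sourceId))
    msg <- c(msg, "sourceId must be a non-empty string")
  if (length(object@elementCount) != 1L || object@elementCount < 1)
    msg <- c(msg, "elementCount must be >= 1")
  if (object@filter@nInserted != object@elementCount)
    msg <- c(msg, "filter@nInserted must equal elementCount")
  if (length(msg)) msg else TRUE
})

#' Parsed tabular document
#'
#' A user document after format detection, parsing, and header-heuristic
#' processing. Cells are opaque text throughout — identifiers survive
#' byte-exact and no locale-dependent number parsing is applied. Every record
#' has exactly one cell per field (short rows are padded with empty cells at
#' parse time); empty cells are preserved as empty strings so in-place
#' translation keeps row geometry.
#'
#' @slot labels Field labels; never empty (synthesized `"Column <i>"` labels
#'   fill gaps).
#' @slot sampleValues List (one element per field) of the first distinct
#'   non-empty values observed, at most 10 per field.
#' @slot records Character matrix, one row per record, one column per field.
#' @slot headerRowsRemoved Number of leading rows removed as headers.
#' @slot sourceFormat `"TSV"`, `"CSV"`, or `"XLSX"`.
#' @seealso [buildTable()], [writeTableCSV()]
#' @exportClass ParsedTable
setClass("ParsedTable",
  representation(
    labels = "character",
    sampleValues = "list",
    records = "matrix",
    headerRowsRemoved = "integer",
    sourceFormat = "character"
  )
)

setValidity("ParsedTable", function(object) {
  msg <- character()
  nf <- length(object@labels)
  if (nf < 1L) msg <- c(msg, "a table must have at least one field")
  if (any(!nzchar(object@labels)))
    msg <- c(msg, "field labels must be non-empty")
  if (ncol(object@records) != nf)
    msg <- c(msg, "records must have one column per field")
  if (length(object@sampleValues) != nf)
    msg <- c(msg, "sampleValues must have one entry per field")
  if (!is.character(object@records))
    msg <- c(msg, "records must be a character matrix")
  else if (anyNA(object@records))
    msg <- c(msg, "cells must be text (empty cells are \"\", never NA)")
  if (any(vapply(object@sampleValues, anyDuplicated, 0L) > 0L))
    msg <- c(msg, "sampleValues must not contain duplicates")
  if (!object@sourceFormat %in% c("TSV", "CSV", "XLSX"))
    msg <- c(msg, "sourceFormat must be TSV, CSV or XLSX")
  if (object@headerRowsRemoved < 0L)
    msg <- c(msg, "headerRowsRemoved must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Directed many-to-many identifier mapping between two sources
#'
#' Holds the distinct (source value -> target value) pairs of one directed
#' cross-reference set, plus a prebuilt hash index for constant-time forward
#' lookup. Mappings are directional: translating in the reverse direction
#' requires its own `MappingSet` (see [invertMapping()]), because 1:many
#' relations invert to many:1 with different ambiguity semantics.
#'
#' @slot fromSource,toSource Source keys for the two ends of the mapping.
#' @slot pairs `data.frame` with character columns `from` and `to`; duplicate
#'   pairs are collapsed at load time.
#' @slot index Environment hashing each left value to its sorted target
#'   vector.
#' @seealso [loadMapping()], [lookupTargets()], [translateTable()]
#' @exportClass MappingSet
setClass("MappingSet",
  representation(
    fromSource = "character",
    toSource = "character",
    pairs = "data.frame",
    index = "environment"
  )
)

setValidity("MappingSet", function(object) {
  msg <- character()
  if (!all(c("from", "to") %in% names(object@pairs)))
    msg <- c(msg, "pairs must have 'from' and 'to' columns")
  else if (anyDuplicated(paste0(object@pairs$from, "\r", object@pairs$to)))
    msg <- c(msg, "pairs must be distinct")
  if (length(msg)) msg else TRUE
})

#' Per-source provenance metadata
#'
#' The citation, version, and access-date record kept for every loaded
#' identifier source, sufficient to cite the source and reproduce the run.
#' `citation` and `accessDate` are mandatory: exports refuse to render methods
#' text from incomplete metadata.
#'
#' @slot sourceId Source key this record describes.
#' @slot displayName Human-readable source name.
#' @slot citation Full citation text.
#' @slot referenceKey Short bibliography key.
#' @slot fetchDate,accessDate ISO dates of the last fetch/access.
#' @slot versionLabel Source release/version label.
#' @slot licenseNote Usage-limitation note (may be empty).
#' @seealso [loadSourceRegistry()], [buildMethodsText()]
#' @exportClass SourceMetadata
setClass("SourceMetadata",
  representation(
    sourceId = "character",
    displayName = "character",
    citation = "character",
    referenceKey = "character",
    fetchDate = "character",
    accessDate = "character",
    versionLabel = "character",
    licenseNote = "character"
  )
)

setValidity("SourceMetadata", function(object) {
  msg <- character()
  for (s in c("sourceId", "displayName", "citation", "accessDate",
              "fetchDate", "versionLabel")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || !nzchar(v))
      msg <- c(msg, sprintf("metadata field '%s' must be non-empty", s))
  }
  if (length(msg)) msg else TRUE
})

#' Ranked candidate sources for one table field
#'
#' The result of classifying one column against a set of source indexes.
#' `candidates` is ranked by match rate (descending), then coverage
#' (descending), then source size (ascending), then source key — a total
#' order, so ranking is deterministic. `highConfidence` marks fields whose top
#' candidate clears the match-rate threshold, except for integer-looking
#' fields with two or more strong candidates, which stay flagged as ambiguous.
#'
#' @slot fieldIndex 0-based column ordinal.
#' @slot candidates `data.frame` with columns `sourceId`, `subsetId`,
#'   `matchRate`, `coverage`, `elementCount`, `versionStripped`, and the
#'   list-column `matchedSamples` (up to 5 matching example values each).
#' @slot highConfidence Whether the top candidate clears the threshold.
#' @slot empty `TRUE` when the field had no classifiable values.
#' @slot nValues Number of distinct non-empty values classified.
#' @seealso [classifyField()], [classifyTable()]
#' @exportClass FieldClassification
setClass("FieldClassification",
  representation(
    fieldIndex = "integer",
    candidates = "data.frame",
    highConfidence = "logical",
    empty = "logical",
    nValues = "integer"
  )
)

#' Policy for resolving ambiguous and missing identifiers
#'
#' @slot ambiguousMode One of `"join_all"` (all targets joined with
#'   `joinDelimiter`), `"first"` (first target in sorted order), `"drop_row"`.
#' @slot joinDelimiter Delimiter for `"join_all"` (default `";"`).
#' @slot missingMode One of `"keep_empty"`, `"keep_original"`, `"drop_row"`.
#' @slot versionStrip Whether trailing `.digit` version suffixes may be
#'   stripped to find a match (reported per value, never silent).
#' @seealso [translationPolicy()], [translateTable()]
#' @exportClass TranslationPolicy
setClass("TranslationPolicy",
  representation(
    ambiguousMode = "character",
    joinDelimiter = "character",
    missingMode = "character",
    versionStrip = "logical"
  )
)

setValidity("TranslationPolicy", function(object) {
  msg <- character()
  if (!object@ambiguousMode %in% c("join_all", "first", "drop_row"))
    msg <- c(msg, "ambiguousMode must be join_all, first or drop_row")
  if (!object@missingMode %in% c("keep_empty", "keep_original", "drop_row"))
    msg <- c(msg, "missingMode must be keep_empty, keep_original or drop_row")
  if (object@ambiguousMode == "join_all" && !nzchar(object@joinDelimiter))
    msg <- c(msg, "joinDelimiter must be non-empty under join_all")
  if (length(msg)) msg else TRUE
})

#' Accounting of every identifier's fate in one translation run
#'
#' Every distinct non-empty value of the translated field falls into exactly
#' one of three categories: matched uniquely (one target), ambiguous (two or
#' more targets), or missing (no target). The conservation identity
#' `matchedUnique + ambiguous + missing == distinctValues` is asserted at
#' construction, not merely documented.
#'
#' @slot totalRows Number of records in the input table.
#' @slot distinctValues Number of distinct non-empty values in the field.
#' @slot matchedUnique Values with exactly one target.
#' @slot ambiguous Values with two or more targets.
#' @slot missing Values with no target.
#' @slot versionStrippedMatches Values matched only after version-suffix
#'   stripping (0 unless the policy enables stripping).
#' @slot rowsDropped Rows removed by a `drop_row` policy mode.
#' @slot policy The [TranslationPolicy-class] used.
#' @slot fromSource,toSource Source keys of the mapping used.
#' @slot timestamp Injected ISO-8601 run timestamp.
#' @seealso [translateTable()]
#' @exportClass TranslationReport
setClass("TranslationReport",
  representation(
    totalRows = "integer",
    distinctValues = "integer",
    matchedUnique = "integer",
    ambiguous = "integer",
    missing = "integer",
    versionStrippedMatches = "integer",
    rowsDropped = "integer",
    policy = "TranslationPolicy",
    fromSource = "character",
    toSource = "character",
    timestamp = "character"
  )
)

setValidity("TranslationReport", function(object) {
  msg <- character()
  if (object@matchedUnique + object@ambiguous + object@missing !=
      object@distinctValues)
    msg <- c(msg, "matchedUnique + ambiguous + missing must equal distinctValues")
  dropping <- object@policy@ambiguousMode == "drop_row" ||
    object@policy@missingMode == "drop_row"
  if (!dropping && object@rowsDropped != 0L)
    msg <- c(msg, "rowsDropped must be 0 unless a drop_row mode is active")
  if (length(msg)) msg else TRUE
})

#' Append-only analysis log for one run
#'
#' Records every processing step (ingest, classify, translate, export) with a
#' timestamp, stage tag, message, and structured details, plus the run id,
#' software version, and a digest of the input file — the provenance trail
#' shipped inside every export archive.
#'
#' @slot runId Run identifier.
#' @slot softwareVersion Package version string.
#' @slot inputDigest SHA-256 of the input document's bytes.
#' @slot entries `data.frame` with columns `timestamp`, `stage`, `message`,
#'   `details` (JSON text).
#' @seealso [analysisLog()], [logEntry()], [writeArchive()]
#' @exportClass AnalysisLog
setClass("AnalysisLog",
  representation(
    runId = "character",
    softwareVersion = "character",
    inputDigest = "character",
    entries = "data.frame"
  )
)

#' Complete export bundle for one translation run
#'
#' The five deliverables shipped as one ZIP archive: the remapped CSV, the
#' statistics (both JSON and human-readable text renderings of the same
#' [TranslationReport-class]), the methods text with bibliography, and the
#' analysis log — plus a manifest listing each member with its SHA-256 digest.
#'
#' @slot table The translated [ParsedTable-class].
#' @slot report The run's [TranslationReport-class].
#' @slot methodsText Templated methods prose naming both sources.
#' @slot bibliography Numbered citation list, one entry per distinct source.
#' @slot log The run's [AnalysisLog-class].
#' @seealso [exportBundle()], [writeArchive()]
#' @exportClass ExportBundle
setClass("ExportBundle",
  representation(
    table = "ParsedTable",
    report = "TranslationReport",
    methodsText = "character",
    bibliography = "character",
    log = "AnalysisLog"
  )
)

#' Synthetic identifier grammar
#'
#' Describes one family of syntactically valid identifiers: a fixed prefix
#' followed by a run of digits (optionally zero-padded, optionally carrying a
#' `.digit` version suffix), or — when `alphabet` is non-empty — symbol-style
#' identifiers drawn from the alphabet with lengths in `lengthRange` and a
#' leading letter. Used by the fixture generator to emulate real accession
#' grammars (Ensembl-style `ENSG` + 11 digits, RefSeq-style `NM_` + digits +
#' version, bare integers, gene symbols) without downloading any warehouse.
#'
#' @slot name Grammar name, used as the fixture source key.
#' @slot prefix Literal prefix (may be empty).
#' @slot digitCount Number of digits after the prefix (0 for symbol
#'   grammars).
#' @slot zeroPadded Whether digit runs are left-padded with zeros.
#' @slot versionSuffix Whether a `.digit` version suffix is appended.
#' @slot alphabet Symbol alphabet as a single string (`""` for numeric
#'   grammars).
#' @slot lengthRange Min/max symbol length (used only with a non-empty
#'   alphabet).
#' @seealso [identifierGrammar()], [generateSource()], [defaultGrammars()]
#' @exportClass IdentifierGrammar
setClass("IdentifierGrammar",
  representation(
    name = "character",
    prefix = "character",
    digitCount = "integer",
    zeroPadded = "logical",
    versionSuffix = "logical",
    alphabet = "character",
    lengthRange = "integer"
  )
)

setValidity("IdentifierGrammar", function(object) {
  msg <- character()
  if (!nzchar(object@name)) msg <- c(msg, "grammar name must be non-empty")
  if (object@digitCount < 0L) msg <- c(msg, "digitCount must be >= 0")
  if (nzchar(object@alphabet)) {
    if (length(object@lengthRange) != 2L ||
        any(object@lengthRange < 1L) ||
        object@lengthRange[1] > object@lengthRange[2])
      msg <- c(msg, "lengthRange must be two increasing positive integers")
  } else if (object@digitCount == 0L) {
    msg <- c(msg, "numeric grammars need digitCount >= 1")
  }
  if (length(msg)) msg else TRUE
})
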