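# Provenance: the analysis log, methods text with bibliography, statistics
# renderings, and the ZIP export bundle. Timestamps are injected by the
# caller — no writer here reads the clock — so archives from identical
# inputs are byte-identical.

#' Start an analysis log
#'
#' @param runId Run identifier (any stable string).
#' @param inputDigest SHA-256 of the input document, see [readDocument()].
#' @param softwareVersion Defaults to the installed package version.
#' @return An empty [AnalysisLog-class].
#' @export
analysisLog <- function(runId, inputDigest = "",
                        softwareVersion = as.character(
                          utils::packageVersion("IdMapper"))) {
  new("AnalysisLog",
    runId = runId, softwareVersion = softwareVersion,
    inputDigest = inputDigest,
    entries = data.frame(
      timestamp = character(), stage = character(),
      message = character(), details = character(),
      stringsAsFactors = FALSE
    )
  )
}

#' Append an entry to an analysis log
#'
#' @param log An [AnalysisLog-class].
#' @param stage One of `"ingest"`, `"classify"`, `"translate"`, `"export"`.
#' @param message Human-readable message.
#' @param details Named list of structured details (stored as JSON).
#' @param timestamp Injected ISO-8601 timestamp.
#' @return The updated log (functional append).
#' @export
logEntry <- function(log, stage, message, details = list(),
                     timestamp = "1970-01-01T00:00:00Z") {
  stopifnot(is(log, "AnalysisLog"))
  stage <- match.arg(stage, c("ingest", "classify", "translate", "export"))
  log@entries <- rbind(log@entries, data.frame(
    timestamp = timestamp, stage = stage, message = message,
    details = as.character(
      jsonlite::toJSON(details, auto_unbox = TRUE, digits = NA)),
    stringsAsFactors = FALSE
  ))
  log
}

.requireMeta <- function(meta, role) {
  bad <- tryCatch({ validObject(meta); NULL }, error = conditionMessage)
  if (!is.null(bad))
    idmStop("IncompleteMetadata", "%s source metadata incomplete: %s",
            role, bad)
}

#' Render the methods text and bibliography for one translation run
#'
#' Templated prose naming both sources with their version labels and
#' fetch/access dates, plus the run's accounting; the bibliography lists
#' each distinct source's citation exactly once (an identity mapping yields
#' a single entry).
#'
#' @param metaFrom,metaTo [SourceMetadata-class] for the two sources.
#' @param report The run's [TranslationReport-class].
#' @return List with character elements `text` and `bibliography`.
#' @section Errors: `IncompleteMetadata` when a required metadata field is
#'   empty.
#' @export
buildMethodsText <- function(metaFrom, metaTo, report) {
  .requireMeta(metaFrom, "origin")
  .requireMeta(metaTo, "target")
  counts <- reportCounts(report)
  text <- paste0(
    sprintf(
      paste0(
        "Identifiers were translated from %s (%s, version %s; fetched %s, ",
        "accessed %s) [1] to %s (%s, version %s; fetched %s, accessed %s) %s ",
        "using exact identifier matching over a precomputed cross-reference ",
        "set. "
      ),
      metaFrom@displayName, metaFrom@sourceId, metaFrom@versionLabel,
      metaFrom@fetchDate, metaFrom@accessDate,
      metaTo@displayName, metaTo@sourceId, metaTo@versionLabel,
      metaTo@fetchDate, metaTo@accessDate,
      if (metaTo@sourceId == metaFrom@sourceId) "[1]" else "[2]"
    ),
    sprintf(
      paste0(
        "Of %d distinct input identifiers, %d mapped to exactly one target, ",
        "%d were ambiguous (two or more targets), and %d had no mapping. "
      ),
      counts[["distinctValues"]], counts[["matchedUnique"]],
      counts[["ambiguous"]], counts[["missing"]]
    ),
    sprintf(
      "Ambiguous identifiers were handled with policy '%s'; unmapped identifiers with policy '%s'.",
      report@policy@ambiguousMode, report@policy@missingMode
    ),
    if (counts[["versionStrippedMatches"]] > 0)
      sprintf(
        " %d identifier(s) matched only after stripping a trailing version suffix.",
        counts[["versionStrippedMatches"]]
      ) else ""
  )
  metas <- list(metaFrom, metaTo)
  ids <- vapply(metas, function(m) m@sourceId, "")
  metas <- metas[!duplicated(ids)]
  bib <- vapply(seq_along(metas), function(i) {
    m <- metas[[i]]
    sprintf("[%d] %s. %s Version %s, accessed %s.",
            i, m@displayName, m@citation, m@versionLabel, m@accessDate)
  }, "")
  list(text = text, bibliography = paste(bib, collapse = "\n"))
}

#' Render a translation report as statistics
#'
#' Both renderings draw every number from the same
#' [TranslationReport-class] — the statistics file is a view, never a
#' recomputation.
#'
#' @param report A [TranslationReport-class].
#' @return List with elements `json` (character, pretty JSON) and `text`
#'   (character, human-readable).
#' @export
renderStatistics <- function(report) {
  counts <- reportCounts(report)
  payload <- c(
    list(
      from_source = report@fromSource,
      to_source = report@toSource,
      timestamp = report@timestamp,
      policy = list(
        ambiguous_mode = report@policy@ambiguousMode,
        join_delimiter = report@policy@joinDelimiter,
        missing_mode = report@policy@missingMode,
        version_strip = report@policy@versionStrip
      )
    ),
    as.list(counts)
  )
  json <- as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                        pretty = TRUE, digits = NA))
  text <- paste(c(
    sprintf("Translation: %s -> %s", report@fromSource, report@toSource),
    sprintf("Run timestamp: %s", report@timestamp),
    sprintf("%-24s %d", paste0(names(counts), ":"), counts)
  ), collapse = "\n")
  list(json = json, text = text)
}

#' Assemble an export bundle
#'
#' @param table The translated [ParsedTable-class].
#' @param report The run's [TranslationReport-class].
#' @param metaFrom,metaTo [SourceMetadata-class] for the sources used.
#' @param log The run's [AnalysisLog-class].
#' @return An [ExportBundle-class].
#' @export
exportBundle <- function(table, report, metaFrom, metaTo, log) {
  mt <- buildMethodsText(metaFrom, metaTo, report)
  new("ExportBundle",
    table = table, report = report,
    methodsText = mt$text, bibliography = mt$bibliography, log = log
  )
}

.renderLog <- function(log) {
  header <- sprintf(
    "run_id: %s\nsoftware_version: %s\ninput_sha256: %s\n",
    log@runId, log@softwareVersion, log@inputDigest
  )
  if (!nrow(log@entries)) return(header)
  body <- sprintf("%s  [%s]  %s  %s",
                  log@entries$timestamp, log@entries$stage,
                  log@entries$message, log@entries$details)
  paste0(header, paste(body, collapse = "\n"), "\n")
}

#' Write an export bundle as one ZIP archive
#'
#' The archive contains exactly six members: `remapped_data.csv`,
#' `statistics.json`, `statistics.txt`, `methods.txt` (methods text followed
#' by the bibliography), `analysis_log.txt`, and `manifest.json` listing the
#' other five with their SHA-256 digests. Writing refuses bundles whose log
#' is missing a pipeline stage (every run must have ingest, classify,
#' translate, and export entries). With a fixed `timestamp`, identical
#' inputs produce byte-identical archives.
#'
#' @param bundle An [ExportBundle-class].
#' @param path Output ZIP path.
#' @param timestamp Injected ISO-8601 timestamp used for the manifest and
#'   all archive member mtimes.
#' @return `path`, invisibly.
#' @export
writeArchive <- function(bundle, path,
                         timestamp = "1970-01-01T00:00:00Z") {
  stopifnot(is(bundle, "ExportBundle"))
  validObject(bundle)
  stages <- unique(bundle@log@entries$stage)
  needed <- c("ingest", "classify", "translate", "export")
  absent <- setdiff(needed, stages)
  if (length(absent))
    idmStop("InvalidArgument",
            "refusing to write archive: log has no entries for stage(s) %s",
            paste(absent, collapse = ", "))
  stats <- renderStatistics(bundle@report)
  staging <- file.path(tempfile("bundle"), "x")
  dir.create(staging, recursive = TRUE)
  on.exit(unlink(dirname(staging), recursive = TRUE), add = TRUE)
  writeTableCSV(bundle@table, file.path(staging, "remapped_data.csv"))
  writeChar(stats$json, file.path(staging, "statistics.json"), eos = NULL)
  writeChar(stats$text, file.path(staging, "statistics.txt"), eos = NULL)
  writeChar(paste0(bundle@methodsText, "\n\nReferences\n",
                   bundle@bibliography, "\n"),
            file.path(staging, "methods.txt"), eos = NULL)
  writeChar(.renderLog(bundle@log),
            file.path(staging, "analysis_log.txt"), eos = NULL)
  members <- c("remapped_data.csv", "statistics.json", "statistics.txt",
               "methods.txt", "analysis_log.txt")
  manifest <- list(
    created = timestamp,
    run_id = bundle@log@runId,
    members = lapply(members, function(f) {
      p <- file.path(staging, f)
      list(
        name = f,
        bytes = as.integer(file.size(p)),
        sha256 = digest::digest(p, algo = "sha256", file = TRUE)
      )
    })
  )
  jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  all_members <- c(members, "manifest.json")
  mtime <- as.POSIXct(timestamp, format = "%Y-%m-%dT%H:%M:%S",
                      tz = "UTC")
  if (is.na(mtime)) mtime <- as.POSIXct("1980-01-01", tz = "UTC")
  for (f in all_members) Sys.setFileTime(file.path(staging, f), mtime)
  zip::zip(file.path(normalizePath(dirname(path), mustWork = FALSE),
                     basename(path)),
           files = all_members, root = staging,
           include_directories = FALSE, mode = "cherry-pick")
  invisible(path)
}

#' Verify the manifest digests of an export archive
#'
#' @param path Path to a ZIP written by [writeArchive()].
#' @return `TRUE` invisibly when every member's digest matches; otherwise a
#'   `ChecksumMismatch` error naming the member.
#' @export
verifyArchive <- function(path) {
  tmp <- tempfile("verify")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  zip::unzip(path, exdir = tmp)
  manifest <- jsonlite::read_json(file.path(tmp, "manifest.json"))
  for (m in manifest$members) {
    p <- file.path(tmp, m$name)
    if (!file.exists(p))
      idmStop("ChecksumMismatch", "archive member '%s' is missing", m$name)
    got <- digest::digest(p, algo = "sha256", file = TRUE)
    if (!identical(got, m$sha256))
      idmStop("ChecksumMismatch",
              "archive member '%s' digest mismatch", m$name)
  }
  invisible(TRUE)
}
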