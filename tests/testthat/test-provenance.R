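# Methods text, statistics rendering, analysis log, ZIP export.

meta_fixture <- function(id = "ensembl_gene", name = "Ensembl Gene") {
  new("SourceMetadata",
    sourceId = id, displayName = name,
    citation = sprintf("Citation for %s.", name),
    referenceKey = id, fetchDate = "2026-01-05",
    accessDate = "2026-01-07", versionLabel = "r110",
    licenseNote = "")
}

report_fixture <- function() {
  new("TranslationReport",
    totalRows = 10L, distinctValues = 8L, matchedUnique = 6L,
    ambiguous = 1L, missing = 1L, versionStrippedMatches = 0L,
    rowsDropped = 0L, policy = translationPolicy(),
    fromSource = "ensembl_gene", toSource = "refseq_transcript",
    timestamp = "2026-02-03T04:05:06Z")
}

full_run <- function(tmpzip, timestamp = "2026-02-03T04:05:06Z") {
  b <- small_bundle()
  reg <- fixture_registry(b)
  doc <- fixture_doc(b$sources$ensembl_gene[1:60])
  runTranslation(doc, 1, b$mappings$ensembl_gene__refseq_transcript,
                 reg, tmpzip, indexes = NULL, timestamp = timestamp)
}

test_that("methods text names sources, versions, dates and counts", {
  mt <- buildMethodsText(meta_fixture(),
                         meta_fixture("refseq_transcript", "RefSeq Transcript"),
                         report_fixture())
  expect_match(mt$text, "r110")
  expect_match(mt$text, "2026-01-07")
  expect_match(mt$text, "8 distinct input identifiers")
  expect_match(mt$text, "6 mapped to exactly one target")
  expect_equal(length(strsplit(mt$bibliography, "\n")[[1]]), 2L)
  # identity mapping: one bibliography entry
  mt2 <- buildMethodsText(meta_fixture(), meta_fixture(), report_fixture())
  expect_equal(length(strsplit(mt2$bibliography, "\n")[[1]]), 1L)
})

test_that("incomplete metadata is refused by name", {
  broken <- meta_fixture()
  broken@citation <- ""
  err <- expect_error(
    buildMethodsText(broken, meta_fixture("x", "X"), report_fixture()),
    class = "IncompleteMetadata"
  )
  expect_match(conditionMessage(err), "citation")
})

test_that("statistics renderings mirror the report exactly", {
  rep <- report_fixture()
  st <- renderStatistics(rep)
  parsed <- jsonlite::fromJSON(st$json)
  counts <- reportCounts(rep)
  for (nm in names(counts))
    expect_equal(parsed[[nm]], unname(counts[[nm]]))
  expect_equal(parsed$from_source, "ensembl_gene")
  expect_match(st$text, "matchedUnique:\\s+6")
})

test_that("the log accumulates stage entries append-only", {
  log <- analysisLog("run1", inputDigest = "abc")
  expect_equal(nrow(log@entries), 0L)
  log <- logEntry(log, "ingest", "parsed")
  log <- logEntry(log, "classify", "classified", details = list(n = 3))
  expect_equal(log@entries$stage, c("ingest", "classify"))
  expect_match(log@entries$details[2], "\"n\":3", fixed = TRUE)
  expect_error(logEntry(log, "nonsense", "x"))
})

test_that("archives carry six members with verifying digests", {
  zp <- tempfile(fileext = ".zip")
  out <- full_run(zp)
  expect_true(file.exists(zp))
  members <- zip::zip_list(zp)$filename
  expect_setequal(members,
                  c("remapped_data.csv", "statistics.json", "statistics.txt",
                    "methods.txt", "analysis_log.txt", "manifest.json"))
  expect_true(verifyArchive(zp))
  # extraction reproduces the remapped CSV byte-exactly
  ex <- tempfile()
  zip::unzip(zp, exdir = ex)
  re <- buildTable(file.path(ex, "remapped_data.csv"))
  expect_identical(records(re), records(out$table))
  manifest <- jsonlite::read_json(file.path(ex, "manifest.json"))
  expect_equal(length(manifest$members), 5L)
  # every stage appears in the shipped log
  logtxt <- readLines(file.path(ex, "analysis_log.txt"), warn = FALSE)
  for (st in c("ingest", "classify", "translate", "export"))
    expect_true(any(grepl(paste0("[", st, "]"), logtxt, fixed = TRUE)))
})

test_that("identical inputs with a pinned timestamp give identical bytes", {
  d1 <- tempfile(); d2 <- tempfile()
  dir.create(d1); dir.create(d2)
  z1 <- file.path(d1, "result.zip")
  z2 <- file.path(d2, "result.zip")
  full_run(z1)
  full_run(z2)
  expect_identical(
    digest::digest(z1, algo = "sha256", file = TRUE),
    digest::digest(z2, algo = "sha256", file = TRUE)
  )
})

test_that("bundles with an incomplete log are refused", {
  rep <- report_fixture()
  tab <- new("ParsedTable",
    labels = "g", sampleValues = list(character()),
    records = matrix("NM_004552.3", ncol = 1),
    headerRowsRemoved = 0L, sourceFormat = "TSV")
  log <- logEntry(analysisLog("r"), "ingest", "only one stage")
  bundle <- exportBundle(tab, rep, meta_fixture(),
                         meta_fixture("refseq_transcript", "RefSeq"), log)
  expect_error(writeArchive(bundle, tempfile(fileext = ".zip")),
               class = "InvalidArgument")
})

test_that("tampered archives fail digest verification", {
  zp <- tempfile(fileext = ".zip")
  full_run(zp)
  ex <- tempfile()
  zip::unzip(zp, exdir = ex)
  writeLines("tampered", file.path(ex, "statistics.txt"))
  zp2 <- tempfile(fileext = ".zip")
  zip::zip(zp2, files = list.files(ex), root = ex, mode = "cherry-pick")
  expect_error(verifyArchive(zp2), class = "ChecksumMismatch")
})
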