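# Field aggregation and source classification.

test_that("aggregateValues dedupes, trims and drops empties in order", {
  tab <- new("ParsedTable",
    labels = "x", sampleValues = list(character()),
    records = matrix(c("A", "A", " B", "", "A "), ncol = 1),
    headerRowsRemoved = 0L, sourceFormat = "TSV")
  expect_equal(aggregateValues(tab, 1), c("A", "B"))
  empty <- new("ParsedTable",
    labels = "x", sampleValues = list(character()),
    records = matrix(c("", "", ""), ncol = 1),
    headerRowsRemoved = 0L, sourceFormat = "TSV")
  expect_length(aggregateValues(empty, 1), 0L)
  expect_error(aggregateValues(tab, 2), class = "InvalidArgument")
})

test_that("a single-source field classifies with full confidence", {
  b <- default_bundle()
  idx <- default_indexes()
  set.seed(10)
  vals <- sample(b$sources$ensembl_gene, 500)
  fc <- classifyField(vals, idx)
  cand <- candidates(fc)
  expect_equal(cand$sourceId[1], "ensembl_gene")
  expect_equal(cand$matchRate[1], 1.0)
  expect_true(isHighConfidence(fc))
  # coverage * elementCount recovers the matched count as an exact integer
  expect_equal(cand$coverage * cand$elementCount,
               round(cand$coverage * cand$elementCount))
  expect_equal(cand$coverage[1] * cand$elementCount[1], 500)
  expect_true(all(unlist(cand$matchedSamples) %in% vals))
  expect_lte(max(lengths(cand$matchedSamples)), 5L)
})

test_that("empty and unmatchable fields behave as specified", {
  idx <- default_indexes()
  expect_error(classifyField(character(), idx), class = "EmptyField")
  fc <- classifyField(c("zzz not an id", "also wrong"), idx)
  expect_equal(nrow(candidates(fc)), 0L)
  expect_false(isHighConfidence(fc))
})

test_that("Bloom match rates stay within FPR slack of the exact oracle", {
  b <- default_bundle()
  idx <- default_indexes()
  set.seed(21)
  for (src in names(b$sources)) {
    vals <- sample(b$sources[[src]], 1000)
    fc <- classifyField(vals, idx)
    cand <- candidates(fc)
    for (i in seq_len(nrow(cand))) {
      oracle <- mean(vals %in% b$sources[[cand$sourceId[i]]])
      diff <- cand$matchRate[i] - oracle
      expect_gte(diff, 0)               # false positives only inflate
      # a value may be probed twice (exact, then version-stripped), so the
      # per-value false-positive chance is at most twice the analytic rate
      fpr <- 2 * analyticFPR(idx[[cand$sourceId[i]]])
      sigma <- sqrt(fpr * (1 - fpr) / length(vals))
      expect_lte(diff, fpr + 3 * sigma + 1e-12)
    }
  }
})

test_that("top-1 recovery is perfect for single-source fields", {
  b <- default_bundle()
  idx <- default_indexes()
  set.seed(33)
  for (src in names(b$sources)) {
    for (rep in 1:3) {
      vals <- sample(b$sources[[src]], 60)
      fc <- classifyField(vals, idx)
      expect_equal(candidates(fc)$sourceId[1], src)
    }
  }
})

test_that("integer fields with competing namespaces are never auto-confirmed", {
  b <- default_bundle()
  idx <- default_indexes()
  ov <- intersect(b$sources$entrez_gene, b$sources$omim_gene)
  fc <- classifyField(head(ov, 200), idx)
  cand <- candidates(fc)
  expect_gte(nrow(cand), 2L)
  expect_gte(sum(cand$matchRate >= 0.95), 2L)
  expect_false(isHighConfidence(fc))
  # ranking is a deterministic total order: source keys never repeat
  expect_false(anyDuplicated(paste(cand$sourceId, cand$subsetId)) > 0)
})

test_that("versioned accessions fall back to a flagged stripped match", {
  b <- default_bundle()
  stripped <- unique(sub("\\.[0-9]+$", "", b$sources$refseq_transcript))
  idx <- list(refseq_nover = buildSourceIndex("refseq_nover", stripped))
  vals <- b$sources$refseq_transcript[1:200]
  fc <- classifyField(vals, idx)
  cand <- candidates(fc)
  expect_equal(cand$sourceId[1], "refseq_nover")
  expect_gte(cand$matchRate[1], 0.99)
  expect_true(cand$versionStripped[1])
})

test_that("classifyTable flags empty fields instead of failing the batch", {
  b <- default_bundle()
  idx <- default_indexes()
  doc <- fixture_doc(b$sources$ensembl_gene[1:60])
  tab <- buildTable(doc)
  res <- classifyTable(tab, idx)
  expect_length(res, 2L)
  expect_equal(candidates(res[[1]])$sourceId[1], "ensembl_gene")
  # the p-value column matches no identifier source meaningfully
  expect_true(res[[2]]@empty || nrow(candidates(res[[2]])) == 0L ||
                max(candidates(res[[2]])$matchRate) < 0.5)
  empties <- new("ParsedTable",
    labels = "x", sampleValues = list(character()),
    records = matrix("", nrow = 3, ncol = 1),
    headerRowsRemoved = 0L, sourceFormat = "TSV")
  res2 <- classifyTable(empties, idx)
  expect_true(res2[[1]]@empty)
})
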