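# In-place translation: previews, policies, accounting, non-interference.

worked_example_mapping <- function() {
  mappingSet("ensembl_gene", "refseq_transcript",
             from = c("ENSG00000168653", "ENSG00000000003",
                      "ENSG00000000005"),
             to = c("NM_004552.3", "NM_003270.4", "NM_015645.5"))
}

simple_table <- function(cells, labels = paste("Column", seq_len(ncol(cells)))) {
  new("ParsedTable",
    labels = labels,
    sampleValues = rep(list(character()), ncol(cells)),
    records = cells, headerRowsRemoved = 0L, sourceFormat = "TSV")
}

test_that("previews expose targets and missingness before committing", {
  m <- worked_example_mapping()
  pv <- previewTranslation(c("ENSG00000168653", "ENSG99999999999"), m, 5)
  expect_equal(nrow(pv), 2L)
  expect_equal(pv$targets[[1]], "NM_004552.3")
  expect_length(pv$targets[[2]], 0L)
  b <- small_bundle()
  vals <- b$sources$ensembl_gene[1:634]
  pv2 <- previewTranslation(vals, b$mappings$ensembl_gene__refseq_transcript, 5)
  expect_equal(nrow(pv2), 5L)
})

test_that("the worked example translates in place", {
  tab <- buildTable(rawDocument("geneId\nENSG00000168653\nENSG00000000003\n"))
  res <- translateTable(tab, 1, worked_example_mapping())
  expect_equal(unname(records(res$table)[, 1]),
               c("NM_004552.3", "NM_003270.4"))
  expect_equal(unname(reportCounts(res$report)[["missing"]]), 0)
  expect_match(fieldLabels(res$table)[1], "refseq_transcript")
})

test_that("ambiguity and missingness policies render as documented", {
  m <- mappingSet("A", "B",
                  from = c("a", "b", "b"), to = c("x", "y1", "y2"))
  cells <- matrix(c("a", "b", "c", "", "1", "2", "3", "4"), ncol = 2)
  tab <- simple_table(cells, c("id", "v"))
  # default: join_all with ";" and keep_empty
  res <- translateTable(tab, 1, m)
  expect_equal(unname(records(res$table)[, 1]), c("x", "y1;y2", "", ""))
  counts <- reportCounts(res$report)
  expect_equal(unname(counts[["matchedUnique"]]), 1)
  expect_equal(unname(counts[["ambiguous"]]), 1)
  expect_equal(unname(counts[["missing"]]), 1)
  expect_equal(unname(counts[["distinctValues"]]), 3)
  # first
  res2 <- translateTable(tab, 1, m,
                         translationPolicy(ambiguousMode = "first"))
  expect_equal(unname(records(res2$table)[2, 1]), "y1")
  # keep_original
  res3 <- translateTable(tab, 1, m,
                         translationPolicy(missingMode = "keep_original"))
  expect_equal(unname(records(res3$table)[3, 1]), "c")
  # drop_row removes exactly the affected rows
  res4 <- translateTable(tab, 1, m,
                         translationPolicy(ambiguousMode = "drop_row",
                                           missingMode = "drop_row"))
  expect_equal(nrow(records(res4$table)), 2L)
  expect_equal(unname(reportCounts(res4$report)[["rowsDropped"]]), 2)
  expect_equal(unname(records(res4$table)[, 2]), c("1", "4"))
})

test_that("empty mappings leave every value missing per policy", {
  m <- mappingSet("A", "B", character(), character())
  tab <- simple_table(matrix(c("a", "b"), ncol = 1), "id")
  res <- translateTable(tab, 1, m)
  expect_equal(unname(records(res$table)[, 1]), c("", ""))
  expect_equal(unname(reportCounts(res$report)[["missing"]]), 2)
})

test_that("non-target columns are byte-identical after translation", {
  b <- small_bundle()
  ids <- b$sources$ensembl_gene[1:100]
  tab <- buildTable(fixture_doc(ids))
  res <- translateTable(tab, 1, b$mappings$ensembl_gene__refseq_transcript)
  expect_identical(records(res$table)[, 2], records(tab)[, 2])
  counts <- reportCounts(res$report)
  expect_equal(unname(counts[["matchedUnique"]] + counts[["ambiguous"]] +
                        counts[["missing"]]),
               unname(counts[["distinctValues"]]))
})

test_that("a bijection and its inverse restore the field exactly", {
  b <- small_bundle()
  src <- b$sources$hgnc_symbol[1:200]
  dst <- b$sources$uniprot_protein[1:200]
  m <- generateMappings(src, dst, c(one_to_one = 1), seed = 9,
                        fromSource = "hgnc_symbol",
                        toSource = "uniprot_protein")
  tab <- simple_table(matrix(src[1:50], ncol = 1), "symbol")
  fwd <- translateTable(tab, 1, m)
  back <- translateTable(fwd$table, 1, invertMapping(m))
  expect_identical(unname(records(back$table)[, 1]),
                   unname(records(tab)[, 1]))
})

test_that("enlarging the mapping never increases the missing count", {
  b <- small_bundle()
  pairs <- mappingPairs(b$mappings$ensembl_gene__hgnc_symbol)
  tab <- simple_table(matrix(b$sources$ensembl_gene[1:150], ncol = 1), "g")
  prevMissing <- Inf
  for (frac in c(0.2, 0.5, 1.0)) {
    k <- floor(nrow(pairs) * frac)
    m <- mappingSet("ensembl_gene", "hgnc_symbol",
                    pairs$from[seq_len(k)], pairs$to[seq_len(k)])
    miss <- reportCounts(translateTable(tab, 1, m)$report)[["missing"]]
    expect_lte(miss, prevMissing)
    prevMissing <- miss
  }
})

test_that("duplicate input values translate consistently across rows", {
  m <- mappingSet("A", "B", "g1", "t1")
  tab <- simple_table(matrix(c("g1", "g1", "g1"), ncol = 1), "id")
  res <- translateTable(tab, 1, m)
  expect_equal(unname(records(res$table)[, 1]), rep("t1", 3))
  expect_equal(unname(reportCounts(res$report)[["distinctValues"]]), 1)
})

test_that("version-stripped matches are counted, never silent", {
  m <- mappingSet("refseq_transcript", "hgnc_symbol",
                  "NM_004552", "NDUFS5")
  tab <- simple_table(matrix("NM_004552.3", ncol = 1), "tx")
  res <- translateTable(tab, 1, m)  # no stripping by default
  expect_equal(unname(reportCounts(res$report)[["missing"]]), 1)
  res2 <- translateTable(tab, 1, m,
                         translationPolicy(versionStrip = TRUE))
  expect_equal(unname(records(res2$table)[, 1]), "NDUFS5")
  expect_equal(unname(reportCounts(res2$report)[["versionStrippedMatches"]]), 1)
})

test_that("keepOriginal appends the translated column instead", {
  m <- worked_example_mapping()
  tab <- simple_table(matrix(c("ENSG00000168653", "0.5"), ncol = 2),
                      c("gene", "p"))
  res <- translateTable(tab, 1, m, keepOriginal = TRUE)
  expect_equal(nFields(res$table), 3L)
  expect_equal(unname(records(res$table)[1, ]),
               c("ENSG00000168653", "NM_004552.3", "0.5"))
})

test_that("a mismatched expected source warns but proceeds", {
  m <- worked_example_mapping()
  tab <- simple_table(matrix("ENSG00000168653", ncol = 1), "gene")
  expect_warning(
    translateTable(tab, 1, m, expectedSource = "entrez_gene"),
    "classified as"
  )
})
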