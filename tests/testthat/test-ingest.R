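# Format sniffing, parsing, header heuristics, table building.

test_that("format detection recognizes TSV, CSV and XLSX", {
  expect_equal(detectFormat(rawDocument("a\tb\nc\td")), "TSV")
  expect_equal(detectFormat(rawDocument("x,\"y,z\"\n1,2", "t.csv")), "CSV")
  zipmagic <- c(as.raw(c(0x50, 0x4B, 0x03, 0x04)), as.raw(0:20))
  expect_equal(detectFormat(rawDocument(zipmagic, "data.xlsx")), "XLSX")
  expect_error(detectFormat(rawDocument("justoneword")),
               class = "UnrecognizedFormat")
  # deterministic: identical bytes, identical verdict
  doc <- rawDocument("g,h\n1,2\n3,4\n")
  expect_equal(detectFormat(doc), detectFormat(doc))
})

test_that("quoted CSV agrees with an RFC-4180 reference parser", {
  txt <- "x,\"y,z\"\n1,2"
  rows <- parseDocument(rawDocument(txt), "CSV")
  oracle <- as.matrix(utils::read.csv(text = txt, header = FALSE,
                                      colClasses = "character"))
  expect_equal(rows[[1]], unname(oracle[1, ]))
  expect_equal(rows[[2]], unname(oracle[2, ]))
  # embedded newline inside quotes is one logical row
  txt2 <- "a,\"line1\nline2\",c\nd,e,f\n"
  rows2 <- parseDocument(rawDocument(txt2), "CSV")
  oracle2 <- utils::read.csv(text = txt2, header = FALSE,
                             colClasses = "character")
  expect_length(rows2, 2L)
  expect_equal(rows2[[1]], unname(unlist(oracle2[1, ])))
  expect_equal(rows2[[1]][2], "line1\nline2")
  # doubled quotes decode to literal quotes
  rows3 <- parseDocument(rawDocument('"he said ""hi""",b\n'), "CSV")
  expect_equal(rows3[[1]][1], 'he said "hi"')
})

test_that("TSV parsing splits on tabs with no quoting dialect", {
  rows <- parseDocument(rawDocument("a\tb\nc\td"), "TSV")
  expect_equal(rows, list(c("a", "b"), c("c", "d")))
  rows <- parseDocument(rawDocument("\"a\tb\n"), "TSV")
  expect_equal(rows[[1]], c("\"a", "b"))
})

test_that("XLSX merged regions propagate the top-left value", {
  cells <- rbind(c("gene", "score"),
                 c("ENSG00000168653", "0.25"),
                 c("", "12"))
  p <- tempfile(fileext = ".xlsx")
  write_test_xlsx(cells, p, merges = "A2:A3")
  rows <- parseDocument(readDocument(p), "XLSX")
  expect_length(rows, 3L)             # merge never changes the record count
  expect_equal(rows[[2]][1], "ENSG00000168653")
  expect_equal(rows[[3]][1], "ENSG00000168653")
  expect_equal(rows[[3]][2], "12")    # integer: no decimal point
  # independent read-back: readxl sees the same top-left value
  ref <- suppressMessages(readxl::read_xlsx(p, col_names = FALSE))
  expect_equal(ref[[1]][2], "ENSG00000168653")
})

test_that("header detection follows the type-class vote", {
  rows <- list(c("geneId", "p"),
               c("ENSG00000168653", "0.01"),
               c("ENSG00000000001", "0.5"))
  h <- detectHeader(rows)
  expect_equal(h$headerRowsRemoved, 1L)
  expect_equal(h$labels, c("geneId", "p"))
  # all-numeric body with no text row: nothing to remove
  h2 <- detectHeader(list(c("1", "2"), c("3", "4"), c("5", "6")))
  expect_equal(h2$headerRowsRemoved, 0L)
  expect_equal(h2$labels, c("Column 1", "Column 2"))
  # two stacked header rows over a numeric body
  rows3 <- c(list(c("study A", "study A"), c("geneId", "p")),
             lapply(1:25, function(i) c(as.character(i), "0.5")))
  h3 <- detectHeader(rows3)
  expect_equal(h3$headerRowsRemoved, 2L)
  expect_equal(h3$labels, c("geneId", "p"))
  # empty label slots are synthesized
  h4 <- detectHeader(list(c("geneId", ""), c("ENSG00000168653", "0.1"),
                          c("ENSG00000000002", "0.2")))
  expect_equal(h4$labels, c("geneId", "Column 2"))
})

test_that("buildTable composes detection, parsing and header removal", {
  tab <- buildTable(rawDocument(
    "geneId\tp\nENSG00000168653\t0.01\nENSG00000000001\t0.5\n"))
  expect_s4_class(tab, "ParsedTable")
  expect_equal(nFields(tab), 2L)
  expect_equal(nRecords(tab), 2L)
  expect_equal(headerRowsRemoved(tab), 1L)
  expect_equal(fieldLabels(tab), c("geneId", "p"))
  # header rows + records account for every raw row
  raw_rows <- parseDocument(rawDocument(
    "geneId\tp\nENSG00000168653\t0.01\nENSG00000000001\t0.5\n"), "TSV")
  expect_equal(headerRowsRemoved(tab) + nRecords(tab), length(raw_rows))
  # sample values: distinct, non-empty, first-come
  expect_equal(sampleValues(tab)[[1]],
               c("ENSG00000168653", "ENSG00000000001"))
})

test_that("ragged rows: short rows pad, long rows fail naming the row", {
  tab <- buildTable(rawDocument("a\tb\nc\td\ne\n x\ty\n"))
  expect_equal(unname(records(tab)[3, ]), c("e", ""))
  err <- expect_error(
    buildTable(rawDocument("a,b\nc,d\ne,f,g\nh,i\nj,k\n", "x.csv")),
    class = "ParseFailure"
  )
  expect_match(conditionMessage(err), "row 3")
})

test_that("empty documents are rejected", {
  expect_error(rawDocument(""), class = "UnrecognizedFormat")
  p <- tempfile()
  file.create(p)
  expect_error(buildTable(p), class = "UnrecognizedFormat")
})

test_that("CSV write/ingest round-trips cells, labels and record count", {
  b <- small_bundle()
  ids <- b$sources$ensembl_gene[1:40]
  tab <- buildTable(fixture_doc(ids))
  p <- tempfile(fileext = ".csv")
  writeTableCSV(tab, p)
  back <- buildTable(p)
  expect_identical(records(back), records(tab))
  expect_identical(fieldLabels(back), fieldLabels(tab))
  # cells with commas, quotes and the join delimiter survive
  tricky <- new("ParsedTable",
    labels = c("geneId", "note"),
    sampleValues = list(character(), character()),
    records = rbind(c("ENSG00000168653", "a,b"),
                    c("NM_004552.3;NM_004552.4", 'say "hi"'),
                    c("4725", "")),
    headerRowsRemoved = 0L, sourceFormat = "CSV")
  p2 <- tempfile(fileext = ".csv")
  writeTableCSV(tricky, p2)
  expect_identical(records(buildTable(p2)), records(tricky))
  raw <- readLines(p2, warn = FALSE)
  expect_true(grepl("NM_004552.3;NM_004552.4", raw[3], fixed = TRUE))
  expect_false(grepl("\"NM_004552", raw[3], fixed = TRUE))
})
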