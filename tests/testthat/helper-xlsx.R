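# Minimal XLSX writer used only to build test fixtures in code (no xlsx
# writer package is a package dependency). Writes one worksheet with
# inline-string or numeric cells and optional merged regions; readable by
# readxl, which serves as the independent read-back check.

.xlsx_col_letter <- function(j) {
  out <- ""
  while (j > 0) {
    r <- (j - 1) %% 26
    out <- paste0(LETTERS[r + 1], out)
    j <- (j - 1) %/% 26
  }
  out
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# cells: character matrix; numeric-looking cells are written as numbers,
# empty cells are omitted. merges: character vector of A1 ranges.
write_test_xlsx <- function(cells, path, merges = character()) {
  rows_xml <- vapply(seq_len(nrow(cells)), function(i) {
    cs <- vapply(seq_len(ncol(cells)), function(j) {
      v <- cells[i, j]
      if (!nzchar(v)) return("")
      ref <- paste0(.xlsx_col_letter(j), i)
      if (grepl("^-?[0-9]+(\\.[0-9]+)?$", v)) {
        sprintf('<c r="%s"><v>%s</v></c>', ref, v)
      } else {
        sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>',
                ref, .xml_escape(v))
      }
    }, "")
    sprintf('<row r="%d">%s</row>', i, paste(cs, collapse = ""))
  }, "")
  merge_xml <- if (length(merges)) {
    sprintf('<mergeCells count="%d">%s</mergeCells>', length(merges),
            paste(sprintf('<mergeCell ref="%s"/>', merges), collapse = ""))
  } else ""
  sheet <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    "<sheetData>", paste(rows_xml, collapse = ""), "</sheetData>",
    merge_xml, "</worksheet>"
  )
  staging <- tempfile("xlsx")
  dir.create(file.path(staging, "_rels"), recursive = TRUE)
  dir.create(file.path(staging, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(staging, "xl", "worksheets"), recursive = TRUE)
  writeChar(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    "</Types>"
  ), file.path(staging, "[Content_Types].xml"), eos = NULL)
  writeChar(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    "</Relationships>"
  ), file.path(staging, "_rels", ".rels"), eos = NULL)
  writeChar(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets><sheet name="Sheet1" sheetId="1" r:id="rId1"/></sheets></workbook>'
  ), file.path(staging, "xl", "workbook.xml"), eos = NULL)
  writeChar(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
    "</Relationships>"
  ), file.path(staging, "xl", "_rels", "workbook.xml.rels"), eos = NULL)
  writeChar(sheet, file.path(staging, "xl", "worksheets", "sheet1.xml"),
            eos = NULL)
  zip::zip(
    file.path(normalizePath(dirname(path), mustWork = FALSE),
              basename(path)),
    files = c("[Content_Types].xml", "_rels/.rels", "xl/workbook.xml",
              "xl/_rels/workbook.xml.rels", "xl/worksheets/sheet1.xml"),
    root = staging, include_directories = FALSE, mode = "mirror"
  )
  unlink(staging, recursive = TRUE)
  invisible(path)
}
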