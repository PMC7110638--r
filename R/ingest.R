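# Ingest: format detection, parsing, and header heuristics for user
# documents of unknown layout. Cells are opaque text throughout; empty cells
# survive as "" so downstream in-place translation preserves row geometry.

#' An uploaded document before parsing
#'
#' @slot content Raw byte content (non-empty).
#' @slot filenameHint Original file name, possibly empty; only its extension
#'   is ever consulted, and only to break delimiter ties.
#' @seealso [rawDocument()], [readDocument()]
#' @exportClass RawDocument
setClass("RawDocument",
  representation(content = "raw", filenameHint = "character")
)

setValidity("RawDocument", function(object) {
  if (length(object@content) == 0L) "content must be non-empty" else TRUE
})

#' Wrap bytes (or text) as a document for ingestion
#'
#' @param content Raw vector, or a character scalar that is converted to
#'   UTF-8 bytes.
#' @param filenameHint Optional original file name.
#' @return A [RawDocument-class].
#' @export
rawDocument <- function(content, filenameHint = "") {
  if (is.character(content)) content <- charToRaw(enc2utf8(content))
  if (!length(content))
    idmStop("UnrecognizedFormat", "document is empty")
  new("RawDocument", content = content, filenameHint = filenameHint)
}

#' Read a file from disk as a document
#'
#' @param path File path.
#' @return A [RawDocument-class] with the file's bytes and name.
#' @export
readDocument <- function(path) {
  if (!file.exists(path))
    idmStop("ParseFailure", "file '%s' does not exist", path)
  rawDocument(readBin(path, "raw", n = file.size(path)), basename(path))
}

# Decode bytes to text: UTF-8 if valid, otherwise latin1. The encoding used
# is recorded on the result so the analysis log can report it.
.decodeText <- function(bytes) {
  txt <- rawToChar(bytes)
  if (isTRUE(validUTF8(txt))) {
    Encoding(txt) <- "UTF-8"
    structure(txt, encoding = "UTF-8")
  } else {
    structure(iconv(txt, from = "latin1", to = "UTF-8"), encoding = "latin1")
  }
}

.ZIP_MAGIC <- as.raw(c(0x50, 0x4B, 0x03, 0x04))

# Column-count consistency of one delimiter over the sniffing window:
# fraction of lines sharing the modal count, plus the modal count itself.
.delimConsistency <- function(lines, delim, quoting) {
  counts <- vapply(
    .tokenize_delimited(paste(lines, collapse = "\n"), delim, quoting),
    length, 0L
  )
  if (!length(counts)) return(c(consistency = 0, modal = 0))
  tab <- table(counts)
  modal <- as.integer(names(tab)[which.max(tab)])
  c(consistency = max(tab) / length(counts), modal = modal)
}

#' Detect the format of a document
#'
#' XLSX is recognized by the ZIP container magic (`PK\\x03\\x04`) before any
#' delimiter logic. Between TSV and CSV, the delimiter that yields the most
#' consistent column count over the first 50 lines wins; the filename
#' extension breaks exact ties, and tab wins a hintless tie (commas occur
#' freely inside prose fields, tabs rarely do). A multi-line file with no
#' delimiter at all is accepted as a single-column TSV — the bare gene list
#' case.
#'
#' @param doc A [RawDocument-class].
#' @return `"TSV"`, `"CSV"`, or `"XLSX"`.
#' @section Errors: `UnrecognizedFormat` when neither the ZIP magic nor any
#'   consistent multi-column delimiter structure is found.
#' @export
detectFormat <- function(doc) {
  stopifnot(is(doc, "RawDocument"))
  validObject(doc)
  if (length(doc@content) >= 4L &&
      identical(doc@content[1:4], .ZIP_MAGIC))
    return("XLSX")
  txt <- .decodeText(doc@content)
  lines <- strsplit(txt, "\r\n|\n|\r")[[1]]
  lines <- utils::head(lines[nzchar(lines) | seq_along(lines) <=
                               max(which(nzchar(lines)), 0L)], 50L)
  if (!length(lines))
    idmStop("UnrecognizedFormat", "document contains no data lines")
  tsv <- .delimConsistency(lines, "\t", quoting = FALSE)
  csv <- .delimConsistency(lines, ",", quoting = TRUE)
  # a delimiter "works" when most lines agree on a multi-column width;
  # short (ragged) rows are tolerated here and padded later
  tsvOk <- tsv[["modal"]] >= 2 && tsv[["consistency"]] >= 0.5
  csvOk <- csv[["modal"]] >= 2 && csv[["consistency"]] >= 0.5
  if (!tsvOk && !csvOk) {
    # multi-line files with no delimiter at all are single-column lists
    # (a bare gene list is the most common upload of all)
    if (length(lines) >= 2 && tsv[["modal"]] == 1 && csv[["modal"]] == 1)
      return("TSV")
    idmStop("UnrecognizedFormat",
            "no consistent delimiter structure found (not TSV, CSV or XLSX)")
  }
  if (tsvOk && !csvOk) return("TSV")
  if (csvOk && !tsvOk) return("CSV")
  if (tsv[["consistency"]] > csv[["consistency"]]) return("TSV")
  if (csv[["consistency"]] > tsv[["consistency"]]) return("CSV")
  ext <- tolower(tools::file_ext(doc@filenameHint))
  if (ext == "csv") return("CSV")
  if (ext %in% c("tsv", "tab", "txt")) return("TSV")
  "TSV"
}

#' Parse a document into raw rows
#'
#' Returns the rows before any header processing, each a character vector of
#' cells. CSV follows RFC 4180 (quoted fields, doubled quotes, embedded
#' newlines); TSV uses no quoting dialect. XLSX reads the requested worksheet,
#' resolves merged regions by propagating the top-left value into every cell
#' of the range, and renders numeric cells without float artifacts (integers
#' carry no decimal point). Formulas are read as their cached values.
#'
#' @param doc A [RawDocument-class].
#' @param fmt Format as returned by [detectFormat()].
#' @param sheet Worksheet number for XLSX (default first).
#' @return List of character vectors, one per row.
#' @section Errors: `ParseFailure` with positional context on malformed
#'   input.
#' @export
parseDocument <- function(doc, fmt, sheet = 1L) {
  stopifnot(is(doc, "RawDocument"))
  fmt <- match.arg(fmt, c("TSV", "CSV", "XLSX"))
  if (fmt == "XLSX") return(.parseXLSX(doc@content, sheet))
  txt <- .decodeText(doc@content)
  rows <- tryCatch(
    .tokenize_delimited(txt, if (fmt == "TSV") "\t" else ",",
                        quoting = fmt == "CSV"),
    error = function(e)
      idmStop("ParseFailure", "%s parse failed: %s", fmt,
              conditionMessage(e))
  )
  # drop trailing all-empty rows (trailing blank lines)
  while (length(rows) && !any(nzchar(rows[[length(rows)]])))
    rows[[length(rows)]] <- NULL
  if (!length(rows))
    idmStop("ParseFailure", "document has no non-empty rows")
  rows
}

# Format a native cell value as text. Identifiers arrive as strings and pass
# through untouched; numerics use R's shortest-roundtrip formatting so
# integral values render with no decimal point.
.cellToText <- function(v) {
  if (is.null(v) || (length(v) == 1L && is.na(v))) return("")
  if (inherits(v, "POSIXt")) return(format(v, "%Y-%m-%d %H:%M:%S"))
  if (is.numeric(v) && length(v) == 1L) {
    if (is.finite(v) && v == round(v) && abs(v) < 1e15)
      return(format(v, scientific = FALSE, trim = TRUE))
    return(as.character(v))
  }
  as.character(v)
}

# A1-style range ("B2:C4") -> list(rows = 2:4, cols = 2:3)
.parseA1Range <- function(ref) {
  corners <- strsplit(ref, ":", fixed = TRUE)[[1]]
  cell <- function(a1) {
    letters_part <- gsub("[0-9]", "", a1)
    digits_part <- as.integer(gsub("[A-Z]", "", a1))
    col <- sum(
      (utf8ToInt(letters_part) - utf8ToInt("A") + 1L) *
        26^rev(seq_along(utf8ToInt(letters_part)) - 1L)
    )
    c(row = digits_part, col = col)
  }
  a <- cell(corners[1])
  b <- cell(corners[length(corners)])
  list(rows = a[["row"]]:b[["row"]], cols = a[["col"]]:b[["col"]])
}

# Merged regions of one worksheet, straight from the sheet XML (readxl does
# not expose them).
.xlsxMergedRanges <- function(xlsxPath, sheet) {
  files <- utils::unzip(xlsxPath, list = TRUE)$Name
  target <- sprintf("xl/worksheets/sheet%d.xml", sheet)
  if (!target %in% files) return(character())
  tmp <- tempfile()
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  utils::unzip(xlsxPath, files = target, exdir = tmp)
  xml <- xml2::read_xml(file.path(tmp, target))
  nodes <- xml2::xml_find_all(
    xml, ".//d1:mergeCell", ns = xml2::xml_ns(xml)
  )
  if (!length(nodes))
    nodes <- xml2::xml_find_all(xml, ".//mergeCell")
  xml2::xml_attr(nodes, "ref")
}

.parseXLSX <- function(bytes, sheet = 1L) {
  tmp <- tempfile(fileext = ".xlsx")
  on.exit(unlink(tmp), add = TRUE)
  writeBin(bytes, tmp)
  cells <- tryCatch(
    suppressMessages(readxl::read_xlsx(
      tmp, sheet = sheet, col_names = FALSE, col_types = "list",
      .name_repair = "minimal"
    )),
    error = function(e)
      idmStop("ParseFailure", "XLSX parse failed: %s", conditionMessage(e))
  )
  nr <- nrow(cells)
  nc <- ncol(cells)
  if (nr == 0L || nc == 0L)
    idmStop("ParseFailure", "XLSX worksheet %d is empty", sheet)
  mat <- matrix("", nrow = nr, ncol = nc)
  for (j in seq_len(nc)) {
    col <- cells[[j]]
    mat[, j] <- vapply(col, .cellToText, "")
  }
  for (ref in .xlsxMergedRanges(tmp, sheet)) {
    rg <- .parseA1Range(ref)
    rows <- rg$rows[rg$rows <= nr]
    cols <- rg$cols[rg$cols <= nc]
    if (!length(rows) || !length(cols)) next
    mat[rows, cols] <- mat[rows[1], cols[1]]
  }
  lapply(seq_len(nr), function(i) mat[i, ])
}

# Type class of one cell for the header heuristic: empty / numeric /
# idlike (mixed letters+digits, accession-shaped) / alpha / text.
.typeClass <- function(x) {
  out <- character(length(x))
  out[!nzchar(x)] <- "empty"
  num <- suppressWarnings(!is.na(as.numeric(x))) & nzchar(x)
  out[num] <- "numeric"
  rest <- !nzchar(out)
  idlike <- rest & grepl("^[A-Za-z][A-Za-z0-9_.:-]*$", x) & grepl("[0-9]", x)
  out[idlike] <- "idlike"
  rest <- !nzchar(out)
  alpha <- rest & grepl("^[A-Za-z]+$", x)
  out[alpha] <- "alpha"
  out[!nzchar(out)] <- "text"
  out
}

.majorityClass <- function(classes) {
  classes <- classes[classes != "empty"]
  if (!length(classes)) return("empty")
  tab <- sort(table(classes), decreasing = TRUE)
  names(tab)[1]
}

#' Detect header rows and derive field labels
#'
#' A leading row is taken as a header when, for a majority of columns, its
#' cell's type class (numeric, accession-shaped, alphabetic, free text)
#' differs from the majority type class of the 20 rows beneath it. At most
#' 3 leading rows are removed. Labels come from the last removed row; empty
#' labels (and the zero-header case) get synthesized `"Column <i>"` names.
#' Zero header rows is a valid outcome, never an error.
#'
#' @param rows List of character-vector rows (ragged allowed; cells beyond a
#'   row's length count as empty).
#' @param maxHeaderRows Cap on removable leading rows.
#' @return List with elements `headerRowsRemoved` (integer) and `labels`
#'   (character).
#' @export
detectHeader <- function(rows, maxHeaderRows = 3L) {
  nf <- max(lengths(rows))
  pad <- function(r) c(r, rep("", nf - length(r)))
  mat <- do.call(rbind, lapply(rows, pad))
  nHeader <- 0L
  while (nHeader < maxHeaderRows && nHeader + 1L < nrow(mat)) {
    cand <- mat[nHeader + 1L, ]
    body <- mat[seq(nHeader + 2L, min(nHeader + 21L, nrow(mat))), ,
                drop = FALSE]
    candClass <- .typeClass(cand)
    votes <- vapply(seq_len(nf), function(j) {
      bodyClass <- .majorityClass(.typeClass(body[, j]))
      if (bodyClass == "empty" || candClass[j] == "empty") return(NA)
      candClass[j] != bodyClass
    }, NA)
    votes <- votes[!is.na(votes)]
    if (!length(votes) || mean(votes) <= 0.5) break
    nHeader <- nHeader + 1L
  }
  if (nHeader > 0L) {
    labels <- mat[nHeader, ]
  } else {
    labels <- rep("", nf)
  }
  blank <- !nzchar(trimws(labels))
  labels[blank] <- sprintf("Column %d", which(blank))
  labels <- make.unique(labels, sep = " ")
  list(headerRowsRemoved = nHeader, labels = as.character(labels))
}

#' Parse a document into a [ParsedTable-class]
#'
#' Composes [detectFormat()], [parseDocument()], and [detectHeader()]. The
#' field count is the modal column count of the raw rows; shorter rows are
#' padded with empty cells, longer rows are a `ParseFailure` naming the row.
#' Per-field sample values hold the first 10 distinct non-empty values.
#'
#' @param doc A [RawDocument-class], or a file path.
#' @param sheet XLSX worksheet number (default first).
#' @param maxHeaderRows Cap on removable header rows; see [detectHeader()].
#' @return A [ParsedTable-class].
#' @examples
#' doc <- rawDocument("gene\tscore\nENSG00000168653\t0.4\n")
#' tab <- buildTable(doc)
#' fieldLabels(tab)
#' @export
buildTable <- function(doc, sheet = 1L, maxHeaderRows = 3L) {
  if (is.character(doc)) doc <- readDocument(doc)
  fmt <- detectFormat(doc)
  rows <- parseDocument(doc, fmt, sheet = sheet)
  widths <- lengths(rows)
  tab <- table(widths)
  modal <- max(as.integer(names(tab)[tab == max(tab)]))
  tooLong <- which(widths > modal)
  if (length(tooLong))
    idmStop("ParseFailure",
            "row %d has %d cells but the table has %d fields",
            tooLong[1], widths[tooLong[1]], modal)
  rows <- lapply(rows, function(r) c(r, rep("", modal - length(r))))
  hdr <- detectHeader(rows, maxHeaderRows = maxHeaderRows)
  body <- rows[seq_along(rows) > hdr$headerRowsRemoved]
  recs <- if (length(body)) {
    matrix(unlist(body, use.names = FALSE), ncol = modal, byrow = TRUE)
  } else {
    matrix(character(), ncol = modal, nrow = 0L)
  }
  samples <- lapply(seq_len(modal), function(j) {
    v <- recs[, j]
    utils::head(unique(v[nzchar(v)]), 10L)
  })
  new("ParsedTable",
    labels = hdr$labels,
    sampleValues = samples,
    records = recs,
    headerRowsRemoved = as.integer(hdr$headerRowsRemoved),
    sourceFormat = fmt
  )
}
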