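# Bloom-filter membership indexes over identifier sources.
# Sizing follows the standard closed forms:
#   m = ceil(-n * ln(p) / (ln 2)^2),  k = max(1, round((m/n) * ln 2))
# Probing uses Kirsch-Mitzenmacher double hashing (see src/bloom.cpp).

#' Signal a classed error
#'
#' All package errors carry a condition class (`UnrecognizedFormat`,
#' `ParseFailure`, `VersionMismatch`, `ChecksumMismatch`, `MalformedPair`,
#' `EmptyMapping`, `EmptyField`, `IncompleteMetadata`) so callers can handle
#' them with `tryCatch(..., <class> = )`.
#' @noRd
idmStop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "idmapperError", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

#' Create an empty Bloom filter sized for a target false-positive rate
#'
#' Sizes the bit array and probe count with the standard closed forms
#' `m = ceil(-capacity * ln(fpr) / (ln 2)^2)` and
#' `k = max(1, round((m / capacity) * ln 2))`.
#'
#' @param capacity Expected number of distinct elements (positive integer).
#' @param targetFpr Desired false-positive rate at design capacity, in (0, 1).
#'   Default 0.001: classification error must stay far below typical
#'   match-rate gaps between the true source and impostors.
#' @param seed Integer hash salt; the fixed default makes indexes reproducible
#'   across runs and machines. Recorded in the serialized index file.
#' @return An empty [BloomFilter-class].
#' @examples
#' f <- bloomCreate(1000, 0.01)
#' f <- bloomAdd(f, c("ENSG00000168653", "NDUFS5"))
#' bloomContains(f, c("ENSG00000168653", "absent"))
#' @export
bloomCreate <- function(capacity, targetFpr = 0.001, seed = 104729L) {
  if (length(capacity) != 1L || is.na(capacity) || capacity < 1)
    idmStop("InvalidArgument", "capacity must be a positive integer")
  if (length(targetFpr) != 1L || is.na(targetFpr) ||
      targetFpr <= 0 || targetFpr >= 1)
    idmStop("InvalidArgument", "targetFpr must be strictly between 0 and 1")
  capacity <- as.numeric(capacity)
  m <- ceiling(-capacity * log(targetFpr) / (log(2)^2))
  k <- max(1L, as.integer(round((m / capacity) * log(2))))
  k <- min(k, 32L)
  new("BloomFilter",
    bits = raw(ceiling(m / 8)),
    m = m,
    k = k,
    nInserted = 0,
    seed = as.integer(seed)
  )
}

#' Add values to a Bloom filter
#'
#' Values are hashed as their exact bytes; no normalization happens here
#' (trimming and deduplication are the classifier's job). Adding the same
#' value twice advances `nInserted` twice — distinctness accounting belongs
#' to the caller. The empty string is a legal, queryable member.
#'
#' @param f A [BloomFilter-class].
#' @param values Character vector of values to add.
#' @return The updated filter (functional update; the input is not modified).
#' @export
bloomAdd <- function(f, values) {
  stopifnot(is(f, "BloomFilter"))
  values <- as.character(values)
  if (anyNA(values))
    idmStop("InvalidArgument", "NA values cannot be added to a Bloom filter")
  f@bits <- .bloom_insert(f@bits, f@m, f@k, as.numeric(f@seed), values)
  f@nInserted <- f@nInserted + length(values)
  f
}

#' Test Bloom-filter membership
#'
#' Returns `TRUE` for every value ever added (no false negatives).
#' Non-members test `TRUE` at approximately the analytic rate
#' `(1 - exp(-k*n/m))^k`; see [analyticFPR()].
#'
#' @param f A [BloomFilter-class].
#' @param values Character vector of values to query.
#' @return Logical vector, one element per query value.
#' @export
bloomContains <- function(f, values) {
  stopifnot(is(f, "BloomFilter"))
  .bloom_query(f@bits, f@m, f@k, as.numeric(f@seed), as.character(values))
}

#' Analytic false-positive rate of a Bloom filter
#'
#' @param x A [BloomFilter-class] or [SourceIndex-class].
#' @param n Number of inserted elements; defaults to the filter's own count.
#' @return The analytic rate `(1 - exp(-k*n/m))^k`.
#' @export
analyticFPR <- function(x, n = NULL) {
  if (is(x, "SourceIndex")) x <- x@filter
  stopifnot(is(x, "BloomFilter"))
  if (is.null(n)) n <- x@nInserted
  (1 - exp(-x@k * n / x@m))^x@k
}

#' Build a membership index for one identifier source
#'
#' Deduplicates the identifiers, sizes a Bloom filter for the distinct count,
#' and inserts every distinct identifier. `elementCount` records the exact
#' distinct count, used later as the denominator of coverage.
#'
#' @param sourceId Source key, e.g. `"ensembl_gene"`.
#' @param identifiers Character vector of identifiers (deduplicated here).
#' @param subsetId Optional subset tag (species/assembly).
#' @param targetFpr Bloom sizing target; see [bloomCreate()].
#' @param metadataRef Key into the source-metadata registry; defaults to
#'   `sourceId`.
#' @param seed Hash salt passed to [bloomCreate()].
#' @return A [SourceIndex-class].
#' @export
buildSourceIndex <- function(sourceId, identifiers, subsetId = "",
                             targetFpr = 0.001, metadataRef = sourceId,
                             seed = 104729L) {
  ids <- unique(as.character(identifiers))
  ids <- ids[!is.na(ids) & nzchar(ids)]
  if (!length(ids))
    idmStop("InvalidArgument", "source '%s' has no identifiers", sourceId)
  f <- bloomCreate(length(ids), targetFpr, seed = seed)
  f <- bloomAdd(f, ids)
  new("SourceIndex",
    sourceId = sourceId, subsetId = subsetId, filter = f,
    elementCount = as.numeric(length(ids)), metadataRef = metadataRef
  )
}

# On-disk index format (little-endian):
#   magic "IDXBLM" (6 bytes) | version 0x01 (1 byte)
#   sourceId, subsetId, metadataRef: uint32 length + UTF-8 bytes each
#   elementCount: float64 | m: float64 | k: uint8 | seed: int32
#   analytic FPR at save time: float64
#   nInserted: float64 | bit array: uint64ish float64 length + bytes
#   CRC-32 of everything above (4 bytes)
.IDX_MAGIC <- charToRaw("IDXBLM")
.IDX_VERSION <- as.raw(1L)

# digest() drops leading zeros from crc32 hex; keep a fixed 8-char form
.crc32hex <- function(bytes) {
  h <- digest::digest(bytes, algo = "crc32", serialize = FALSE)
  paste0(strrep("0", 8L - nchar(h)), h)
}

.putStr <- function(con, s) {
  b <- charToRaw(enc2utf8(s))
  writeBin(length(b), con, size = 4L, endian = "little")
  if (length(b)) writeBin(b, con)
}

.getStr <- function(con) {
  n <- readBin(con, "integer", size = 4L, endian = "little")
  if (n == 0L) return("")
  rawToChar(readBin(con, "raw", n = n))
}

#' Save a source index to a binary file
#'
#' The on-disk layout (documented in the package source) carries magic bytes,
#' a format version, both source keys, exact element count, the filter
#' geometry and seed, the analytic FPR at save time, the bit array, and a
#' trailing CRC-32. [indexLoad()] verifies all of these.
#'
#' @param idx A [SourceIndex-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
indexSave <- function(idx, path) {
  stopifnot(is(idx, "SourceIndex"))
  validObject(idx)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(.IDX_MAGIC, con)
  writeBin(.IDX_VERSION, con)
  .putStr(con, idx@sourceId)
  .putStr(con, idx@subsetId)
  .putStr(con, idx@metadataRef)
  f <- idx@filter
  writeBin(as.numeric(idx@elementCount), con, endian = "little")
  writeBin(as.numeric(f@m), con, endian = "little")
  writeBin(as.raw(f@k), con)
  writeBin(as.integer(f@seed), con, size = 4L, endian = "little")
  writeBin(analyticFPR(f), con, endian = "little")
  writeBin(as.numeric(f@nInserted), con, endian = "little")
  writeBin(as.numeric(length(f@bits)), con, endian = "little")
  writeBin(f@bits, con)
  body <- rawConnectionValue(con)
  crc <- .crc32hex(body)
  payload <- c(body, as.raw(strtoi(
    substring(crc, c(1, 3, 5, 7), c(2, 4, 6, 8)), 16L
  )))
  writeBin(payload, path)
  invisible(path)
}

#' Load a source index saved by [indexSave()]
#'
#' @param path Path to an index file.
#' @return A [SourceIndex-class], bit-identical to the one saved.
#' @section Errors: `VersionMismatch` for an unknown format version,
#'   `ChecksumMismatch` for truncation or corruption.
#' @export
indexLoad <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < length(.IDX_MAGIC) + 1L + 4L)
    idmStop("ChecksumMismatch", "index file '%s' is truncated", path)
  if (!identical(bytes[seq_along(.IDX_MAGIC)], .IDX_MAGIC))
    idmStop("VersionMismatch", "'%s' is not an identifier index file", path)
  if (bytes[length(.IDX_MAGIC) + 1L] != .IDX_VERSION)
    idmStop("VersionMismatch", "unsupported index format version %d",
            as.integer(bytes[length(.IDX_MAGIC) + 1L]))
  body <- bytes[seq_len(length(bytes) - 4L)]
  stored <- paste(sprintf("%02x", as.integer(utils::tail(bytes, 4L))),
                  collapse = "")
  if (!identical(tolower(stored), tolower(.crc32hex(body))))
    idmStop("ChecksumMismatch", "index file '%s' failed its CRC check", path)
  con <- rawConnection(body, "rb")
  on.exit(close(con), add = TRUE)
  ok <- tryCatch({
    readBin(con, "raw", n = length(.IDX_MAGIC) + 1L)
    sourceId <- .getStr(con)
    subsetId <- .getStr(con)
    metadataRef <- .getStr(con)
    elementCount <- readBin(con, "numeric", endian = "little")
    m <- readBin(con, "numeric", endian = "little")
    k <- as.integer(readBin(con, "raw", n = 1L))
    seed <- readBin(con, "integer", size = 4L, endian = "little")
    fpr <- readBin(con, "numeric", endian = "little")
    nInserted <- readBin(con, "numeric", endian = "little")
    nBits <- readBin(con, "numeric", endian = "little")
    bits <- readBin(con, "raw", n = nBits)
    if (length(bits) != nBits) stop("short read")
    f <- new("BloomFilter", bits = bits, m = m, k = k,
             nInserted = nInserted, seed = seed)
    new("SourceIndex", sourceId = sourceId, subsetId = subsetId,
        filter = f, elementCount = elementCount, metadataRef = metadataRef)
  }, error = function(e) {
    if (inherits(e, "idmapperError")) stop(e)
    idmStop("ChecksumMismatch", "index file '%s' could not be decoded: %s",
            path, conditionMessage(e))
  })
  ok
}

#' Load every index file in a directory
#'
#' Reads all `*.idx` files (as written by [indexSave()]).
#'
#' @param dir Directory containing index files.
#' @return Named list of [SourceIndex-class] objects keyed by source id.
#' @export
loadIndexDir <- function(dir) {
  paths <- sort(list.files(dir, pattern = "\\.idx$", full.names = TRUE))
  idx <- lapply(paths, indexLoad)
  names(idx) <- vapply(idx, sourceId, "")
  idx
}
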