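# Mapping store: 2-column TSV files on disk are the source of truth, an
# in-memory hash multimap serves lookups. Mappings are directional; the
# reverse direction is its own MappingSet (see invertMapping). No chaining:
# reachable targets are exactly the one-hop neighbours.

#' Load a mapping set from a 2-column TSV file
#'
#' One `source<TAB>target` pair per line. Duplicate pairs are collapsed;
#' lines with the wrong column count abort the load naming the offending
#' line numbers.
#'
#' @param path Path to the TSV file.
#' @param fromSource,toSource Source keys recorded on the mapping.
#' @return A [MappingSet-class].
#' @section Errors: `MalformedPair` (wrong column count, with line numbers),
#'   `EmptyMapping` (no valid pairs).
#' @export
loadMapping <- function(path, fromSource, toSource) {
  if (!file.exists(path))
    idmStop("EmptyMapping", "mapping file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(lines)
  lines <- lines[keep]
  if (!length(lines))
    idmStop("EmptyMapping", "mapping file '%s' contains no pairs", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    idmStop("MalformedPair",
            "mapping file '%s': line(s) %s do not have exactly 2 columns",
            path, paste(utils::head(which(keep)[bad], 10L), collapse = ", "))
  m <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
  mappingSet(fromSource, toSource, m[, 1], m[, 2])
}

#' Look up the targets of identifier values
#'
#' An empty result means the value is *missing* from the mapping; a result
#' of length two or more means it is *ambiguous* — the two data-quality
#' categories tracked throughout translation. Targets come back sorted, so
#' lookups are deterministic.
#'
#' @param m A [MappingSet-class].
#' @param values Character vector of left-side values.
#' @return For a single value, a character vector of targets; for several
#'   values, a named list of such vectors.
#' @export
lookupTargets <- function(m, values) {
  stopifnot(is(m, "MappingSet"))
  values <- as.character(values)
  res <- lapply(values, function(v) {
    if (exists(v, envir = m@index, inherits = FALSE))
      get(v, envir = m@index) else character(0)
  })
  if (length(values) == 1L) return(res[[1]])
  names(res) <- values
  res
}

#' Invert a mapping set
#'
#' Swaps the direction: 1:many relations become many:1, with the
#' correspondingly different ambiguity semantics.
#'
#' @param m A [MappingSet-class].
#' @return A [MappingSet-class] from `toSource` to `fromSource`.
#' @export
invertMapping <- function(m) {
  stopifnot(is(m, "MappingSet"))
  mappingSet(m@toSource, m@fromSource, m@pairs$to, m@pairs$from)
}

#' Target sources reachable in exactly one mapping hop
#'
#' Chained conversions are out of scope by design: translating A to X with
#' no direct A-to-X mapping requires an explicit intermediate run.
#'
#' @param registry List of [MappingSet-class] objects.
#' @param fromSource Source key to start from.
#' @return Sorted character vector of directly reachable source keys.
#' @export
reachableTargets <- function(registry, fromSource) {
  hits <- vapply(registry, function(m) m@fromSource == fromSource, NA)
  sort(unique(vapply(registry[hits], function(m) m@toSource, "")))
}

#' Load the per-source metadata registry
#'
#' A YAML file keyed by source id; every entry must provide `display_name`,
#' `citation`, `fetch_date`, `access_date`, and `version_label`
#' (`reference_key` and `license_note` are optional). Validation happens at
#' load so exports never discover missing provenance late.
#'
#' @param path Path to the YAML registry.
#' @return Named list of [SourceMetadata-class] objects.
#' @section Errors: `IncompleteMetadata` naming the source and missing key.
#' @export
loadSourceRegistry <- function(path) {
  reg <- yaml::read_yaml(path)
  required <- c("display_name", "citation", "fetch_date", "access_date",
                "version_label")
  out <- lapply(names(reg), function(nm) {
    entry <- reg[[nm]]
    for (key in required) {
      v <- entry[[key]]
      if (is.null(v) || !nzchar(as.character(v)))
        idmStop("IncompleteMetadata",
                "source '%s': required metadata key '%s' is missing", nm, key)
    }
    new("SourceMetadata",
      sourceId = nm,
      displayName = as.character(entry$display_name),
      citation = as.character(entry$citation),
      referenceKey = as.character(entry$reference_key %||% nm),
      fetchDate = as.character(entry$fetch_date),
      accessDate = as.character(entry$access_date),
      versionLabel = as.character(entry$version_label),
      licenseNote = as.character(entry$license_note %||% "")
    )
  })
  names(out) <- names(reg)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
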