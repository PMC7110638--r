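# Synthetic identifier sources and mapping sets. The generator emulates the
# surface grammars of common gene identifier namespaces (Ensembl-style
# accessions, versioned RefSeq-style accessions, bare integers, gene
# symbols, UniProt-style accessions) so classification and translation are
# fully exercisable without downloading any warehouse snapshot.

# Run code under a fixed, fully specified RNG state and restore the caller's
# state afterwards, so generation is deterministic across processes.
.withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Construct an identifier grammar
#'
#' @param name Grammar name, used as the fixture source key.
#' @param prefix Literal prefix (`""` for bare integers and symbols).
#' @param digitCount Digits after the prefix (0 for symbol grammars).
#' @param zeroPadded Left-pad the digit run with zeros (so `ENSG` + 11
#'   digits always has exactly 11 digits).
#' @param versionSuffix Append a `.digit` version (1--9), RefSeq style.
#' @param alphabet Symbol alphabet as one string; non-empty switches the
#'   grammar to symbol mode.
#' @param lengthRange Min/max total length for symbol-mode identifiers.
#' @return An [IdentifierGrammar-class].
#' @examples
#' g <- identifierGrammar("ensembl_gene", prefix = "ENSG", digitCount = 11,
#'                        zeroPadded = TRUE)
#' generateSource(g, 3, seed = 1)
#' @export
identifierGrammar <- function(name, prefix = "", digitCount = 0L,
                              zeroPadded = FALSE, versionSuffix = FALSE,
                              alphabet = "", lengthRange = c(3L, 8L)) {
  new("IdentifierGrammar",
    name = name, prefix = prefix, digitCount = as.integer(digitCount),
    zeroPadded = zeroPadded, versionSuffix = versionSuffix,
    alphabet = alphabet, lengthRange = as.integer(lengthRange)
  )
}

#' Regular expression matched by every identifier a grammar generates
#'
#' @param grammar An [IdentifierGrammar-class].
#' @return A single anchored regex string.
#' @export
grammarPattern <- function(grammar) {
  if (nzchar(grammar@alphabet)) {
    cls <- sprintf("[%s]", grammar@alphabet)
    return(sprintf("^[A-Za-z]%s{%d,%d}$", cls,
                   grammar@lengthRange[1] - 1L, grammar@lengthRange[2] - 1L))
  }
  digits <- if (grammar@zeroPadded) {
    sprintf("\\d{%d}", grammar@digitCount)
  } else {
    sprintf("[1-9]\\d{0,%d}", grammar@digitCount - 1L)
  }
  version <- if (grammar@versionSuffix) "\\.\\d" else ""
  # regex-escape every non-alphanumeric character of the literal prefix
  prefix <- gsub("([^A-Za-z0-9_])", "\\\\\\1", grammar@prefix)
  sprintf("^%s%s%s$", prefix, digits, version)
}

# Combinatorial capacity of a grammar (distinct base identifiers; versions
# do not add capacity because bases are kept distinct).
.grammarCapacity <- function(grammar) {
  if (nzchar(grammar@alphabet)) {
    sizes <- nchar(grammar@alphabet)
    lens <- grammar@lengthRange[1]:grammar@lengthRange[2]
    # first two characters are letters (symbols like NDUFS5 never lead with
    # a digit, and a two-letter head keeps symbols out of accession space)
    return(sum(26 * 26 * sizes^(pmax(lens - 2L, 0L))))
  }
  if (grammar@zeroPadded) 10^grammar@digitCount else 10^grammar@digitCount - 1
}

#' Generate distinct identifiers from a grammar
#'
#' Deterministic in `(grammar, n, seed)` — the same triple reproduces the
#' identical identifier list across sessions and machines.
#'
#' @param grammar An [IdentifierGrammar-class].
#' @param n Number of distinct identifiers (must not exceed the grammar's
#'   combinatorial capacity).
#' @param seed Integer seed.
#' @return Character vector of `n` distinct identifiers, each matching
#'   [grammarPattern()].
#' @export
generateSource <- function(grammar, n, seed) {
  stopifnot(is(grammar, "IdentifierGrammar"))
  validObject(grammar)
  if (n < 1) idmStop("InvalidArgument", "n must be >= 1")
  cap <- .grammarCapacity(grammar)
  if (n > cap)
    idmStop("InvalidArgument",
            "grammar '%s' can produce only %d distinct identifiers (%d requested)",
            grammar@name, cap, n)
  .withSeed(seed, {
    if (nzchar(grammar@alphabet)) {
      ids <- .generateSymbols(grammar, n)
    } else {
      # zero-padded grammars span 0..10^d - 1, bare integers 1..10^d - 1
      nums <- if (grammar@zeroPadded) {
        sample.int(10^grammar@digitCount, n) - 1
      } else {
        sample.int(10^grammar@digitCount - 1, n)
      }
      # format = "f", digits = 0 keeps exactness for values beyond 2^31
      digits <- if (grammar@zeroPadded) {
        formatC(nums, width = grammar@digitCount, flag = "0",
                format = "f", digits = 0)
      } else {
        formatC(nums, format = "f", digits = 0)
      }
      ids <- paste0(grammar@prefix, digits)
      if (grammar@versionSuffix)
        ids <- paste0(ids, ".", sample(1:9, n, replace = TRUE))
    }
    ids
  })
}

.generateSymbols <- function(grammar, n) {
  letters26 <- strsplit("ABCDEFGHIJKLMNOPQRSTUVWXYZ", "")[[1]]
  alpha <- strsplit(grammar@alphabet, "")[[1]]
  out <- character(0)
  guard <- 0L
  while (length(out) < n && guard < 1000L) {
    need <- (n - length(out)) * 2L
    lens <- sample(grammar@lengthRange[1]:grammar@lengthRange[2], need,
                   replace = TRUE)
    batch <- vapply(lens, function(L) {
      paste0(
        paste(sample(letters26, min(2L, L), replace = TRUE), collapse = ""),
        if (L > 2L)
          paste(sample(alpha, L - 2L, replace = TRUE), collapse = "")
        else ""
      )
    }, "")
    out <- unique(c(out, batch))
    guard <- guard + 1L
  }
  if (length(out) < n)
    idmStop("InvalidArgument",
            "could not generate %d distinct symbols for grammar '%s'",
            n, grammar@name)
  out[seq_len(n)]
}

#' The default grammar set
#'
#' Six grammars emulating common identifier namespaces:
#' `ensembl_gene` (`ENSG` + 11 zero-padded digits), `refseq_transcript`
#' (`NM_` + 6 zero-padded digits + `.version`), `entrez_gene` (bare
#' integers), `omim_gene` (bare integers — deliberately inside the
#' entrez-like integer space, providing the integer-ambiguity scenario),
#' `hgnc_symbol` (3--8 uppercase alphanumerics, two-letter head), and
#' `uniprot_protein` (letter + 5 alphanumerics, accession style).
#'
#' @return Named list of [IdentifierGrammar-class] objects.
#' @export
defaultGrammars <- function() {
  g <- list(
    identifierGrammar("ensembl_gene", prefix = "ENSG", digitCount = 11L,
                      zeroPadded = TRUE),
    identifierGrammar("refseq_transcript", prefix = "NM_", digitCount = 6L,
                      zeroPadded = TRUE, versionSuffix = TRUE),
    identifierGrammar("entrez_gene", digitCount = 7L),
    identifierGrammar("omim_gene", digitCount = 6L),
    identifierGrammar("hgnc_symbol", alphabet = "ABCDEFGHIJKLMNOPQRSTUVWXYZ0123456789",
                      lengthRange = c(3L, 8L)),
    identifierGrammar("uniprot_protein", prefix = "P", digitCount = 5L,
                      zeroPadded = TRUE)
  )
  names(g) <- vapply(g, function(x) x@name, "")
  g
}

#' Construct a directed mapping set from explicit pairs
#'
#' Duplicate pairs are collapsed; the forward-lookup hash index is built
#' here once.
#'
#' @param fromSource,toSource Source keys.
#' @param from,to Equal-length character vectors of pair endpoints.
#' @return A [MappingSet-class].
#' @export
mappingSet <- function(fromSource, toSource, from, to) {
  stopifnot(length(from) == length(to))
  from <- as.character(from)
  to <- as.character(to)
  keep <- !duplicated(paste0(from, "\r", to))
  pairs <- data.frame(from = from[keep], to = to[keep],
                      stringsAsFactors = FALSE)
  idx <- new.env(parent = emptyenv(), hash = TRUE,
                 size = max(29L, nrow(pairs)))
  if (nrow(pairs)) {
    sp <- split(pairs$to, pairs$from)
    for (key in names(sp)) assign(key, sort(sp[[key]]), envir = idx)
  }
  new("MappingSet", fromSource = fromSource, toSource = toSource,
      pairs = pairs, index = idx)
}

#' Generate a many-to-many mapping set with a target cardinality profile
#'
#' Source identifiers are partitioned into one-to-one, one-to-many (2--3
#' targets), many-to-one (groups of 2--3 sources sharing a target), and
#' unmapped groups according to `profile`. At `n >= 1000` the realized
#' fractions land within 2 percentage points of the profile (allocation is
#' exact up to rounding). Deterministic in `seed`.
#'
#' @param srcIds,dstIds Non-empty identifier vectors for the two ends.
#' @param profile Named numeric vector with entries among `one_to_one`,
#'   `one_to_many`, `many_to_one`, `unmapped`, summing to 1 (±1e-9).
#' @param seed Integer seed.
#' @param fromSource,toSource Source keys recorded on the mapping.
#' @return A [MappingSet-class].
#' @export
generateMappings <- function(srcIds, dstIds, profile, seed,
                             fromSource = "src", toSource = "dst") {
  if (!length(srcIds) || !length(dstIds))
    idmStop("InvalidArgument", "srcIds and dstIds must be non-empty")
  full <- c(one_to_one = 0, one_to_many = 0, many_to_one = 0, unmapped = 0)
  if (is.null(names(profile)) ||
      !all(names(profile) %in% names(full)))
    idmStop("InvalidArgument",
            "profile names must be among: %s",
            paste(names(full), collapse = ", "))
  full[names(profile)] <- profile
  if (abs(sum(full) - 1) > 1e-9)
    idmStop("InvalidArgument", "profile fractions must sum to 1 (got %.12f)",
            sum(full))
  n <- length(srcIds)
  counts <- round(full * n)
  # make the allocation total exactly n; put the remainder in the largest bin
  counts[which.max(counts)] <- counts[which.max(counts)] + (n - sum(counts))
  .withSeed(seed, {
    src <- sample(srcIds)
    dstPool <- sample(dstIds)
    take <- function(k) {
      if (k > length(dstPool))
        idmStop("InvalidArgument",
                "not enough target identifiers for the requested profile")
      out <- dstPool[seq_len(k)]
      dstPool <<- dstPool[-seq_len(k)]
      out
    }
    pos <- 0L
    nextSrc <- function(k) {
      out <- src[pos + seq_len(k)]
      pos <<- pos + k
      out
    }
    fromV <- character(0)
    toV <- character(0)
    # one-to-one
    s <- nextSrc(counts[["one_to_one"]])
    fromV <- c(fromV, s)
    toV <- c(toV, take(length(s)))
    # one-to-many: 2-3 distinct targets each
    s <- nextSrc(counts[["one_to_many"]])
    if (length(s)) {
      kPer <- sample(2:3, length(s), replace = TRUE)
      fromV <- c(fromV, rep(s, kPer))
      toV <- c(toV, take(sum(kPer)))
    }
    # many-to-one: groups of 2-3 sources share one target
    s <- nextSrc(counts[["many_to_one"]])
    while (length(s)) {
      g <- min(sample(2:3, 1L), length(s))
      fromV <- c(fromV, s[seq_len(g)])
      toV <- c(toV, rep(take(1L), g))
      s <- s[-seq_len(g)]
    }
    # remaining sources are unmapped by construction
    mappingSet(fromSource, toSource, fromV, toV)
  })
}

#' Generate the default fixture bundle
#'
#' Six sources of `nPerSource` identifiers from [defaultGrammars()], plus
#' five mapping sets connecting them. The omim-like integer source is built
#' with half of its identifiers drawn from the entrez-like set, so the two
#' integer namespaces genuinely collide — the ambiguity scenario that makes
#' integer fields unsafe to auto-confirm. Regenerating with the same seed
#' reproduces the bundle exactly; the manifest records all parameters.
#'
#' @param seed Integer seed.
#' @param nPerSource Identifiers per source (default 5000).
#' @param profile Cardinality profile for the generated mappings; see
#'   [generateMappings()].
#' @return List with elements `sources` (named list of identifier vectors),
#'   `mappings` (named list of [MappingSet-class]), and `manifest`.
#' @export
generateFixtureBundle <- function(seed, nPerSource = 5000L,
                                  profile = c(one_to_one = 0.8,
                                              one_to_many = 0.05,
                                              many_to_one = 0.05,
                                              unmapped = 0.1)) {
  grammars <- defaultGrammars()
  sources <- list()
  for (nm in names(grammars)) {
    if (nm == "omim_gene") next
    sources[[nm]] <- generateSource(grammars[[nm]], nPerSource,
                                    seed = seed + match(nm, names(grammars)))
  }
  # omim-like integers: half shared with the entrez-like set (namespace
  # collision), half fresh 6-digit integers not already entrez members
  nShared <- floor(nPerSource / 2)
  omimSeed <- seed + match("omim_gene", names(grammars))
  sources[["omim_gene"]] <- .withSeed(omimSeed, {
    entrez <- sources[["entrez_gene"]]
    shared <- sample(entrez, nShared)
    fresh <- character(0)
    guard <- 0L
    while (length(fresh) < nPerSource - length(shared) && guard < 100L) {
      cand <- format(sample(100000:999999, nPerSource), trim = TRUE)
      fresh <- utils::head(
        unique(c(fresh, setdiff(cand, c(entrez, shared)))),
        nPerSource - length(shared)
      )
      guard <- guard + 1L
    }
    c(shared, fresh)
  })
  sources <- sources[names(grammars)]
  mapSpecs <- list(
    c("ensembl_gene", "refseq_transcript"),
    c("ensembl_gene", "hgnc_symbol"),
    c("ensembl_gene", "entrez_gene"),
    c("entrez_gene", "hgnc_symbol"),
    c("refseq_transcript", "uniprot_protein")
  )
  mappings <- list()
  for (i in seq_along(mapSpecs)) {
    sp <- mapSpecs[[i]]
    mappings[[paste(sp, collapse = "__")]] <- generateMappings(
      sources[[sp[1]]], sources[[sp[2]]], profile,
      seed = seed + 100L + i, fromSource = sp[1], toSource = sp[2]
    )
  }
  manifest <- list(
    generator = "IdMapper fixture bundle",
    seed = seed,
    n_per_source = nPerSource,
    cardinality_profile = as.list(profile),
    sources = names(sources),
    mappings = names(mappings)
  )
  list(sources = sources, mappings = mappings, manifest = manifest)
}

#' Write a fixture bundle to disk
#'
#' One plain-text identifier file per source (one identifier per line),
#' each mapping set as 2-column TSV, the generation manifest as JSON, and a
#' minimal source-metadata registry (YAML) so exports from fixture data
#' carry complete provenance.
#'
#' @param bundle A bundle from [generateFixtureBundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeFixtureBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle$sources))
    writeLines(bundle$sources[[nm]], file.path(dir, paste0(nm, ".ids.txt")))
  for (nm in names(bundle$mappings)) {
    p <- bundle$mappings[[nm]]@pairs
    writeLines(paste(p$from, p$to, sep = "\t"),
               file.path(dir, paste0(nm, ".map.tsv")))
  }
  jsonlite::write_json(bundle$manifest,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  reg <- lapply(names(bundle$sources), function(nm) {
    list(
      display_name = gsub("_", " ", nm),
      citation = sprintf(
        "Synthetic fixture source '%s', IdMapper fixture generator (seed %d).",
        nm, bundle$manifest$seed
      ),
      reference_key = nm,
      fetch_date = "2026-01-01",
      access_date = "2026-01-01",
      version_label = sprintf("fixture-seed-%d", bundle$manifest$seed),
      license_note = "synthetic data; no usage restrictions"
    )
  })
  names(reg) <- names(bundle$sources)
  yaml::write_yaml(reg, file.path(dir, "sources.yaml"))
  invisible(dir)
}

#' Build Bloom indexes for every source in a bundle
#'
#' @param bundle A bundle from [generateFixtureBundle()].
#' @param targetFpr Bloom sizing target; see [bloomCreate()].
#' @return Named list of [SourceIndex-class] objects.
#' @export
buildFixtureIndexes <- function(bundle, targetFpr = 0.001) {
  out <- lapply(names(bundle$sources), function(nm)
    buildSourceIndex(nm, bundle$sources[[nm]], targetFpr = targetFpr))
  names(out) <- names(bundle$sources)
  out
}
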