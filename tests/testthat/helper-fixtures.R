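# Shared fixture builders. The default bundle (6 sources x 5000 ids) is
# built once per test session and reused; small bundles are cheap enough to
# rebuild per test.

.fixture_cache <- new.env(parent = emptyenv())

default_bundle <- function(seed = 20260101) {
  key <- paste0("bundle_", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generateFixtureBundle(seed = seed)
  .fixture_cache[[key]]
}

default_indexes <- function(seed = 20260101) {
  key <- paste0("indexes_", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- buildFixtureIndexes(default_bundle(seed))
  .fixture_cache[[key]]
}

small_bundle <- function(seed = 11, n = 400) {
  key <- sprintf("small_%d_%d", seed, n)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generateFixtureBundle(seed = seed,
                                                   nPerSource = n)
  .fixture_cache[[key]]
}

# random non-identifier strings for false-positive probing
random_strings <- function(n, width = 12) {
  chars <- c(letters, LETTERS, 0:9)
  vapply(seq_len(n), function(i)
    paste(sample(chars, width, replace = TRUE), collapse = ""), "")
}

# registry with complete metadata for the fixture sources
fixture_registry <- function(bundle) {
  dir <- tempfile("reg")
  writeFixtureBundle(bundle, dir)
  loadSourceRegistry(file.path(dir, "sources.yaml"))
}

# a TSV document over a fixture source plus a numeric column
fixture_doc <- function(ids, label = "geneId") {
  txt <- paste0(
    label, "\tscore\n",
    paste(ids, seq_along(ids) / (length(ids) + 1), sep = "\t",
          collapse = "\n"), "\n"
  )
  rawDocument(txt, "fixture.tsv")
}
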