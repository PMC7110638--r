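Package: IdMapper
Title: Automated Gene Identifier Detection and In-Place Translation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ingests tabular gene-oriented data files (TSV, CSV, XLSX) with
    unknown layout, classifies which identifier source each column comes from
    using Bloom-filter membership indexes, translates identifiers in place to a
    chosen target source, and exports the remapped data together with
    statistics, methods text, a bibliography, and analysis logs as a single
    ZIP archive. Includes a synthetic fixture generator that emulates common
    identifier grammars (Ensembl-style accessions, versioned RefSeq-style
    accessions, bare integer IDs, gene symbols) and many-to-many mapping sets,
    so the full pipeline is testable without any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    utils,
    stats,
    Rcpp,
    digest,
    jsonlite,
    yaml,
    readxl,
    xml2,
    zip
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
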