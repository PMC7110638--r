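---
title: "Automated identifier detection and in-place translation"
author: "IdMapper authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated identifier detection and in-place translation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IdMapper)
```

## The problem

A large share of useful genomics results lives in supplementary tables:
gene lists with Ensembl accessions, RefSeq transcripts, Entrez integers, or
bare symbols, in whatever layout the authors' spreadsheet produced.
Reusing such a table means answering three questions that have nothing to
do with the science itself: *what format is this file*, *which identifier
namespace is that column*, and *how do I swap those identifiers for the
ones my own tools accept without wrecking the rest of the table*.

IdMapper automates that chain. A document of unknown layout (TSV, CSV, or
XLSX) is parsed into records and fields; each field's values are tested
against Bloom-filter membership indexes of candidate identifier sources;
the chosen field is translated in place through a directed cross-reference
mapping; and the remapped table ships inside a ZIP archive together with
statistics, methods text, a bibliography, and the analysis log, so the
provenance travels with the data.

## Ingestion

Format detection is deliberate about order. The XLSX container magic
(`PK\x03\x04`) is checked before any delimiter logic, because an XLSX file
is a ZIP and any byte-level delimiter heuristic on it is noise. Between
tab and comma, the winner is the delimiter whose column counts are most
consistent over the first 50 lines (a bounded window, so huge files cost
nothing to sniff); the filename extension only breaks exact ties, and a
multi-line file with no delimiter at all is accepted as a single-column
list — the bare gene list is the most common upload there is.

Cells are opaque text end to end. No locale number parsing, no case
folding, no trimming beyond the classifier's own whitespace handling:
identifiers must survive byte-exact, because a "cleaned" identifier is a
different identifier. Decoding tries UTF-8 first and falls back to latin1,
and the encoding used is recorded rather than silently guessed. XLSX
merged regions are resolved by propagating the top-left value into every
cell of the range, so merged label blocks behave like the repeated values
they visually represent; numeric cells render without float artifacts
(integral values carry no decimal point); formulas are read as their
cached values.

Header rows are not declared anywhere in these files, so they are
inferred: a leading row is taken as a header when, for a majority of
columns, its cell's *type class* (numeric, accession-shaped, alphabetic,
free text) differs from the majority class of the 20 rows beneath it. At
most three leading rows can be removed — stacked header blocks deeper than
that are vanishingly rare in practice and a cap keeps the heuristic from
eating data rows in pathological files. Labels come from the last removed
row; missing labels are synthesized as `Column <i>`. Zero removed rows is
a valid outcome, not an error.

## Bloom-filter indexes

Classification must test a column against every known identifier source,
so the per-source membership structure has to be compact and fast. A Bloom
filter gives exactly the right trade: zero false negatives (a genuine
member is never missed) and a tunable false-positive rate.

Sizing uses the standard closed forms

$$m = \left\lceil \frac{-n \ln p}{(\ln 2)^2} \right\rceil, \qquad
  k = \max\!\left(1, \operatorname{round}\!\big(\tfrac{m}{n}\ln 2\big)\right)$$

for capacity $n$ and target false-positive rate $p$, and membership
probing uses Kirsch–Mitzenmacher double hashing: two 64-bit values derived
from one seeded FNV-1a pass over the value's exact bytes, probed as
$h_1 + i\,h_2 \bmod m$ for $i = 0,\dots,k-1$. The default target rate is
$p = 0.001$: the quantity that matters downstream is the *gap* between the
true source's match rate (near 1) and an impostor's (near the FPR), and
three orders of magnitude of slack keeps that gap unambiguous even for
fields of modest size. The hash seed is fixed and recorded in the
serialized index, so an index built twice — or on another machine — is
bit-identical.

The on-disk index format carries magic bytes, a format version, the source
keys, exact element count, filter geometry, seed, the analytic FPR at save
time, the bit array, and a trailing CRC-32. Loads verify magic, version,
and checksum in that order, so a version bump is reported as a version
mismatch rather than masquerading as corruption.

## Classification

For one field, the distinct, trimmed, non-empty values are tested against
every index. Each candidate source gets a **match rate** (fraction of the
field's distinct values found in the index) and a **coverage** (matched
values divided by the source's total size). The two answer different
questions: match rate says "does this column look like source X", coverage
distinguishes "a tiny sample of X" from "nearly all of X". Candidates are
ranked by match rate, then coverage, then smaller source size, then source
key — a total order, so ranking never depends on input order.

All distinct values are used, not a sample: at desk scale a full scan is
sub-second, and accuracy is the point (a `--sample` escape hatch exists in
the CLI for very large files). Matching is exact-case — symbols are
case-meaningful in several nomenclatures, and folding is a lossy guess.
The one tolerated variation is version suffixes: when a source matches
poorly and the values carry trailing `.digit` versions, a second pass
retries with the suffix stripped, and any such match is flagged
`versionStripped` rather than silently absorbed. Because a value may then
be probed twice, the worst-case false-positive inflation of a match rate
is twice the analytic rate — the property tests bound it at
$2\,\mathrm{FPR} + 3\sigma$.

A field is *high confidence* when its top match rate reaches the threshold
(default 0.95 — the cut is a design choice; anything clearly above typical
FPR noise and clearly below sloppy-partial-match territory works, and 0.95
tolerates a few stale identifiers in an otherwise clean column). The
exception is integer-looking fields: when two or more sources clear the
threshold simultaneously — which is precisely what happens when integer
namespaces collide — the field is never auto-confirmed, and the user must
choose. An empty field raises a classed `EmptyField` condition:
classification of nothing is undefined, not "zero match everywhere".

## Mappings and translation

Cross-references are directed many-to-many pair sets, stored as 2-column
TSV (the source of truth) and served from an in-memory hash multimap. A
lookup returning nothing means **missing**; two or more targets means
**ambiguous** — the two data-quality categories tracked everywhere.
Mappings are directional because inversion changes the semantics (1:many
becomes many:1); `invertMapping()` makes the reverse set explicit rather
than implicit. Reachability is exactly one hop: chained conversions
(A→B→C) are out of scope by design, and `reachableTargets()` only ever
reports direct neighbours.

Translation is in place: only the chosen column changes, row order and
every other cell survive byte-identical, and the field label is annotated
with the target source. The default policy joins ambiguous targets with
`";"` and leaves missing values empty — lossless and visible, because the
package's stance is to surface quality issues, not resolve them silently.
`first` and `drop_row` modes exist for pipelines that need single values
or complete rows; dropped rows are counted in the report. The report
satisfies

```
matchedUnique + ambiguous + missing == distinctValues
```

as a validity invariant of the report object itself, not merely a
documented intention — a report violating it cannot be constructed.
Duplicate values in different rows translate identically and are counted
once in the distinct-value accounting.

## Provenance

Every run carries an append-only log (ingest, classify, translate, export
— an archive whose log is missing a stage is refused), the input file's
SHA-256, and the package version. The methods text is templated from the
source metadata registry — display name, citation, version label, fetch
and access dates are mandatory, and an export fails early with
`IncompleteMetadata` naming the offending key, because unciteable data is
precisely the failure mode this machinery exists to prevent. The
statistics files (JSON and plain text) are renderings of the single
`TranslationReport` object; no number is recomputed on the way out.

The archive is a standard ZIP with six members: the remapped CSV, both
statistics renderings, the methods text with bibliography, the analysis
log, and a manifest listing the other five with SHA-256 digests.
Timestamps are injected by the caller, never read from the clock inside
writers, so identical inputs with a pinned timestamp produce byte-identical
archives — which is also what makes the archive writer testable.

## The synthetic fixture generator

No real warehouse snapshot ships with the package; the fixture generator
stands in for it. Six default sources of 5,000 identifiers each emulate
the *surface grammars* of common namespaces: `ENSG` + 11 zero-padded
digits, `NM_` + 6 digits + `.version`, bare integers (twice), 3–8
character uppercase symbols with a two-letter head, and letter-plus-5
alphanumerics. 5,000 per source keeps a full bundle build plus six index
constructions comfortably in CI while leaving coverage values far from the
degenerate 0/1 ends. Mapping sets are generated against a cardinality
profile (fractions of 1:1, 1:many, many:1, and unmapped sources; the
default 0.8/0.05/0.05/0.1 reflects that real cross-references are mostly
clean with a visible minority of fan-outs and gaps), realized exactly up
to rounding, so accounting tests have sharp expectations.

Two deliberate design points. First, the non-integer grammars are mutually
exclusive by construction (prefixes, lengths, and a two-letter symbol head
guarantee disjoint string sets), which is what makes 100% top-1 recovery a
meaningful expectation rather than luck. Second, the two integer sources
deliberately collide: half of the omim-like identifiers are drawn from the
entrez-like set, reproducing the real-world situation where a bare integer
is claimable by several namespaces — this is the scenario behind the
integer no-auto-confirm rule. Generation is deterministic in
`(grammar, n, seed)` with a fully pinned RNG configuration, and the
manifest written next to every bundle records all parameters.

What the fixtures do *not* emulate: real identifier populations (retired
accessions, skewed integer densities), cross-species subsets, curation
noise, or warehouse scale. Passing tests therefore demonstrate the
correctness of the machinery — detection, ranking, accounting,
serialization — on clean grammars, not classification robustness against
dirty real-world columns.

## Numerical and degenerate-input choices

* Delimiter sniffing accepts a delimiter when most (>50%) of the sniffed
  lines agree on a multi-column width; ragged *short* rows are padded with
  empty cells, while rows *longer* than the modal width are an error named
  by row number — silent truncation would corrupt data invisibly.
* The field count of a parsed document is the modal raw-row width, robust
  against a stray trailing cell in one row deciding the geometry.
* Bloom `k` is clamped to [1, 32]; capacity 0 and FPR outside (0, 1) are
  rejected rather than coerced.
* Empty cells never participate in classification or translation
  accounting, but they are preserved in the table — row geometry is
  sacrosanct.
* The empty string is a legal Bloom member (total function) even though
  aggregation never produces it.
* Ties in candidate ranking cannot occur: the final tie-break key is the
  source key itself.

## Problem sizes

The test suite and the acceptance script regenerate everything they
measure: Bloom calibration at capacity 10,000 with 200,000 probes, oracle
comparisons and recovery over the 6 × 5,000 default bundle with 60
single-source fields, translation accounting on a 1,000-row profiled
fixture, and a full export run. These sizes were chosen so the entire
suite completes in well under a minute while keeping Monte-Carlo
estimates (FPR, category fractions) tight enough for the stated bounds.

## Limitations

* Detection assumes columns of identifiers; free text and clinical prose
  will classify as nothing (by design) but are not actively recognized.
* No chained conversions — translating A→X without a direct mapping
  requires an explicit intermediate run.
* Search cost is linear in the number of loaded indexes.
* First-worksheet-only XLSX by default (a `sheet` argument exists);
  formulas are cached values; formatting carries no meaning.
* The fixture generator's clean grammars overstate real-world separability
  (see above).
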