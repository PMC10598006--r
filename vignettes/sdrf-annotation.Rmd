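---
title: "Annotating proteomics experiments in SDRF with sdrfkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating proteomics experiments in SDRF with sdrfkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdrfkit)
```

## The problem

Public mass-spectrometry proteomics data is only reusable to the extent
that its sample and acquisition metadata are machine-readable. The
SDRF-Proteomics standard addresses this with a tab-delimited table that
maps every raw data file to its sample characteristics, technical
parameters and studied variables, all expressed as controlled-vocabulary
terms. In practice most repository submissions carry no SDRF at all, and
hand-edited spreadsheets drift in term spelling, column naming and row
structure. `sdrfkit` is a headless annotation engine for this format: it
turns ontology releases into fast lookup artifacts, generates per-species
templates of required columns, maps a lab's local metadata table into SDRF
columns while canonicalizing terms, expands rows over multiplex label
channels, validates the result, and stamps a reproducible submission hash.

## Ontology handling

Controlled vocabularies enter as OBO term stanzas (`parse_obo()`) or as a
flat term-list JSON (`import_term_list_json()`), the generic shape we use
for vocabularies published in other serializations. A graph is validated
at construction: unique CURIEs, no dangling `is_a` targets, acyclicity
(via igraph). Each graph is rendered into three derived artifacts,
persisted as gzipped JSON:

* a flat **element list** of all non-obsolete labels, sorted
  case-insensitively — the autocomplete source;
* a **nested label tree**, a recursive dictionary mirroring the ontology
  hierarchy; a term with several parents appears once under each parent
  (a DAG rendered as a tree), with recursion truncated at a configurable
  depth (default 50) purely as a guard against pathological inputs;
* a **nodes tree** carrying `{label, value = CURIE, children}` records for
  tree-select widgets.

Obsolete terms stay in the graph but are excluded from every artifact:
they must never be offered for annotation. Alongside the three shapes,
`export_ontology_artifacts()` writes a fourth file, `<name>_terms.json.gz`
(the flat term-list export), so a search index can be rebuilt from the
artifact directory without the original release file — the three display
artifacts do not all carry ids and synonyms.

Artifacts are written through a fixed-header gzip stream, so identical
content produces byte-identical files; round trips through
`write_artifact()`/`read_artifact()` are exact structural identities, and
a file lacking the `1f 8b` magic or with a truncated stream is rejected
with a typed error.

The term index (`build_term_index()`) maps normalized labels and synonyms
(trimmed, whitespace-collapsed, lowercased) to CURIEs. When two terms
share a normalized key, the lexicographically smallest CURIE wins and the
collision is recorded as an index warning — deterministic resolution
without guessing curator intent. `search_terms()` ranks matches by class
(exact label, label prefix, label substring, then the same three over
synonyms), breaking ties by shorter label and then case-insensitive label
order; each term appears once, under its best class.

## The table model

An SDRF table is an ordered set of column headers plus a character cell
matrix with value semantics. Six column categories exist; headers render
lowercase (`characteristics[organism]`, `comment[data file]`, ...), parse
case-insensitively, and may not repeat verbatim. Canonical order is:
source name, characteristics columns (stable by insertion), technology
type, assay name, comment columns, factor value columns last.
`write_sdrf()` emits that order with LF endings and a single trailing
newline; cells may not contain tabs or newlines, since SDRF has no quoting
dialect.

Templates are data: `inst/extdata/registry/templates.json` maps species
keys (`default`, `human`, `vertebrates`, `invertebrates`, `plants`,
`cell-lines`) to required-column lists. The shipped sets are a frozen,
desk-scale registry patterned on the community template collection —
configuration, not a normative claim about the standard; drop in another
JSON file to use the official sets. The same pattern covers label schemes
(TMT 6/10/11/16-plex with PSI-MS channel names, SILAC, iTRAQ 4/8-plex,
label-free), column presets (a metaproteomics set), and
column-to-ontology bindings.

`set_raw_files()` appends one row per file, auto-naming samples
(`sample <i>`) and runs (`run <i>`), and enforces a limit of 250 distinct
files per table — beyond that, the intended route is a partial SDRF merged
later via `merge_partial()`, which takes the union of columns, keys rows
by data file, lets annotated cells win over template defaults, and treats
two different non-default values for one cell as a hard conflict.

## Mapping, expansion, validation

`map_metadata()` writes a local metadata table into SDRF columns. Values
on ontology-bound columns are canonicalized: exact label matches take the
vocabulary's casing, synonyms are rewritten to the canonical label
(inconsistent synonym use is precisely what breaks machine readability),
and anything unresolvable is left in place and reported. The report is a
partition — exact + synonym + unresolved counts sum to the mapped cells —
so nothing is silently dropped. Alignment is positional when row counts
match and no file-name column is present; otherwise the local `file`
column joins on `comment[data file]`, and any unmatched file is an error
rather than a truncation.

`expand_labels()` multiplies each row by the scheme's channels, setting
`comment[label]` and suffixing source names with ` ch<j>` so each channel
is a distinct sample; re-expanding a table whose files already carry every
channel of the scheme is refused. `fill_column()` is all-or-nothing when
an index is bound: a single unresolvable value aborts the whole write, so
a failed broadcast never leaves a half-written column.

`validate_table()` accumulates findings (severity, machine code, row,
column, message) from required-column presence, empty hard-required cells
(source name, data file, organism — placeholder tokens count as empty
there, though they pass term checks everywhere else), per-cell term
resolution on bound columns, the `KEY=value;...` grammar of modification
and cleavage cells (recognized keys NT, AC, MT, PP, TA, TS, CS, MM;
unknown keys warn, since the standard evolves), the 250-file limit, and
orphaned factor-value columns. Unresolved terms are errors on template
columns and warnings on extra columns; synonym use is always a warning
with the canonical suggestion. Findings sort by row, column, code, so
reports are reproducible; a report passes iff it has no error.

## Hashing

`stamp_hash()` computes SHA-256 over a canonical serialization: columns in
a *total* order (category rank, then header — deliberately stronger than
the insertion-stable display order, so that permuting columns or re-casing
headers cannot change the digest), lowercase headers, LF endings, one
trailing newline. The digest is written as a `<digest>  <filename>`
sidecar, the common checksum-file convention, because the tab-delimited
format has no comment syntax to embed it in-band. What any downstream
submission system does with the hash is its contract, not ours; we
guarantee only determinism and sensitivity (any cell edit changes it).

## Fixture generators

`generate_toy_ontology()` emits a deterministic OBO file: a fixed
mini-taxonomy (root `organism`, `Homo sapiens` with synonym `human`, one
subspecies) plus randomly parented terms forming a DAG of bounded depth,
with a chain guaranteeing the requested depth, occasional second parents
to exercise multi-parent rendering, and obsolete flags assigned only to
childless terms so the live hierarchy stays fully reachable from the
roots. `generate_toy_metadata()` emits a small TSV with organism values
mixing canonical and synonym spellings and, from five samples up, exactly
one planted unresolvable value, giving mapping reports a known shape.
These fixtures emulate the *formats* and failure modes of real releases
at desk scale; they do not emulate real ontologies' size (millions of
taxa), label ambiguity rates, or curation quirks, so green tests certify
the engine's laws, not the quality of any particular vocabulary release.

## Numerical and design choices

* Percentages (`adoption_percentage()`) round half-up to one decimal on
  the 0–100 scale; this is the convention that reproduces both published
  adoption figures (1.6 from 156/9671, 3.9 from 376/9671) and is applied
  uniformly.
* The suite and the acceptance script run on 40–50-term ontologies, 1–8
  row random tables, 2–4 file workflows and 100 fuzzed corruptions per
  defect class — sizes at which every property is exercised (multi-parent
  duplication, synonym collisions, all label schemes, the 250/251
  boundary) while the whole suite stays interactive.
* Missing values use `"not available"` (unknown) and `"not applicable"`
  (semantically void); both pass term checks, both are "empty" for the
  three hard-required columns.
* Exit codes of the CLI: 0 success, 1 validation failure, 2 usage/input
  error, so shells can distinguish "invalid SDRF" from "wrong invocation".

## Limitations

The validator covers structural and term-compliance rules, not the full
recommended-column catalogue of the official SDRF validator, and performs
no cross-file checks or raw-file content inspection. OWL ontologies are
not parsed natively; vocabularies published that way are ingested through
the flat term-list JSON shape. The shipped registries are deliberately
small and replaceable; real deployments should point them at current
community template and ontology releases.
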