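# sdrfkit

A headless R engine for annotating mass-spectrometry proteomics
experiments in **SDRF-Proteomics**, the tab-delimited standard that maps
every raw data file to its sample characteristics, technical metadata and
studied variables, with values drawn from controlled vocabularies.

Most public proteomics datasets ship without such structured metadata, and
hand-edited spreadsheets drift in term spelling and table structure, which
makes large-scale reuse of repository data painful. `sdrfkit` implements
the full annotation workflow as composable, scriptable functions:

1. **Species template** — `create_template("human")` starts a table with
   that species' required columns; `set_raw_files()` registers up to 250
   raw files per table, auto-naming samples and assay runs.
2. **Metadata mapping** — `map_metadata()` writes a local TSV/CSV into
   SDRF columns, resolving each value against the ontology bound to the
   target column: exact matches keep canonical casing, synonyms are
   rewritten to the canonical label, the rest is reported unresolved.
3. **Label expansion** — `expand_labels()` turns each row into one row per
   label channel (TMT 6/10/11/16-plex, iTRAQ 4/8-plex, SILAC, label-free).
4. **Column entry** — `fill_column()` (atomic, ontology-checked),
   `add_column()`, `apply_preset()` (e.g. the metaproteomics column set).
5. **Validation and hashing** — `validate_table()` reports findings with
   machine-readable codes (`REQUIRED_MISSING`, `TERM_UNRESOLVED`,
   `KV_MALFORMED`, `FILE_LIMIT`, ...); `stamp_hash()` computes a SHA-256
   over a canonical serialization so a submission digest is reproducible
   no matter how columns were ordered or headers cased.

Underneath sits an ontology store: OBO releases (or flat term-list JSON)
are parsed into validated DAGs and rendered into three gzipped JSON
artifacts — a sorted element list, a nested label tree and a
select-widget nodes tree — plus a term index supporting ranked
autocomplete (`search_terms()`) and ancestor queries. Oversized studies
are handled by annotating in batches and recombining with
`merge_partial()`, which keys rows on the data file and refuses
conflicting annotations.

## Worked example

```r
library(sdrfkit)

# toy taxonomy + metadata stand in for real releases (same formats)
graph    <- parse_obo(generate_toy_ontology(n_terms = 50, depth = 4, seed = 1))
registry <- ontology_bindings(indices = list(taxonomy = build_term_index(graph)))
meta     <- read.delim(text = generate_toy_metadata(4, seed = 1),
                       check.names = FALSE)

t   <- create_template("human")
t   <- set_raw_files(t, meta$file)
res <- map_metadata(t, meta, c(organism = "characteristics[organism]"), registry)
res$report
#>      local                    target resolved synonym_resolved unresolved
#> 1 organism characteristics[organism]        2                2          0
```

Two cells matched the canonical label `Homo sapiens` exactly and two used
the synonym `human`, which mapping rewrote to the canonical label; nothing
was left unresolved. Expand over TMT channels and finish the annotation:

```r
t <- expand_labels(res$table, "TMT10plex")
t <- fill_column(t, "comment[cleavage agent details]", "NT=Trypsin;AC=MS:1001251")
t <- fill_column(t, "comment[modification parameters]",
                 "NT=Oxidation;AC=UNIMOD:35;MT=Variable;TA=M")
t <- fill_column(t, "comment[fraction identifier]", "1")
t <- fill_column(t, "technology type", "proteomic profiling by mass spectrometry")
t <- fill_column(t, "characteristics[ancestry category]", "not available")
t
#> <sdrf_table: 16 column(s) x 40 row(s)>
```

4 files × 10 TMT channels gives 40 rows, each channel a distinct sample
(`sample 1 ch1`, ...). Validate and stamp:

```r
validate_table(t, "human", registry)
#> PASSED: 0 error(s), 0 warning(s)
stamp_hash(write_sdrf(t))
#> <sdrf_hash SHA-256 bce64d18ef23c7eef1263c7b18f140d922dbb370c975a955daef1b136d18a3ad (sdrf-canonical-v1)>
```

Autocomplete over the indexed vocabulary:

```r
search_terms(build_term_index(graph), "homo", limit = 3)
#>                           label              id   match_kind
#> 1                  Homo sapiens  NCBITaxon:9606 label_prefix
#> 2 Homo sapiens neanderthalensis NCBITaxon:63221 label_prefix
```

The same workflow is available from a shell through the CLI launcher
(`inst/cli/sdrfkit.R`): `template`, `convert-ontology`, `search`, `map`,
`expand`, `fill`, `preset`, `merge`, `validate`, `hash`, `fixtures`; exit
codes are 0 (success), 1 (validation failure), 2 (usage error).

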