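# Shared fixtures and independent oracles for the suite. Everything is
# generated in code at test time; no binary fixtures.

toy_graph <- function(n = 50L, depth = 4L, seed = 1L, obsolete_rate = 0) {
  parse_obo(generate_toy_ontology(n_terms = n, depth = depth, seed = seed,
                                  obsolete_rate = obsolete_rate))
}

taxonomy_index <- function() build_term_index(toy_graph())

instrument_graph <- function() {
  import_term_list_json('[
    {"id": "MS:1000031", "label": "instrument model"},
    {"id": "MS:1002732", "label": "Orbitrap Fusion Lumos",
     "parents": ["MS:1000031"]},
    {"id": "MS:1002523", "label": "Q Exactive HF", "parents": ["MS:1000031"],
     "synonyms": ["QE-HF"]},
    {"id": "MS:1001045", "label": "cleavage agent name"},
    {"id": "MS:1001251", "label": "Trypsin", "parents": ["MS:1001045"]},
    {"id": "MS:1001309", "label": "Lys-C", "parents": ["MS:1001045"]}
  ]', name = "instrument")
}

unimod_csv_text <- function() {
  paste("Name,Accession,Site,Position,Mono_mass",
        "Oxidation,35,M,Anywhere,15.994915",
        "Carbamidomethyl,4,C,Anywhere,57.021464",
        sep = "\n")
}

fixture_registry <- function() {
  ontology_bindings(
    indices = list(taxonomy = taxonomy_index(),
                   instrument = build_term_index(instrument_graph())),
    catalog = load_unimod_csv(unimod_csv_text())
  )
}

# A fully annotated table produced by the whole workflow (the happy path).
happy_table <- function(n_files = 2L, scheme = "TMT10plex", seed = 1L) {
  reg <- fixture_registry()
  t <- create_template("human")
  files <- sprintf("file_%02d.raw", seq_len(n_files))
  t <- set_raw_files(t, files)
  meta <- utils::read.delim(
    text = generate_toy_metadata(n_files, seed = seed), check.names = FALSE)
  meta$organism[meta$organism == "unobtainium"] <- "human"
  t <- map_metadata(t, meta,
                    c(organism = "characteristics[organism]",
                      "organism part" = "characteristics[organism part]",
                      instrument = "comment[instrument]"),
                    registry = reg)$table
  t <- expand_labels(t, scheme)
  t <- fill_column(t, "comment[cleavage agent details]",
                   "NT=Trypsin;AC=MS:1001251")
  t <- fill_column(t, "comment[modification parameters]",
                   "NT=Oxidation;AC=UNIMOD:35;MT=Variable;TA=M")
  t <- fill_column(t, "comment[fraction identifier]", "1")
  t <- fill_column(t, "technology type", "proteomic profiling by mass spectrometry")
  t <- fill_column(t, "characteristics[ancestry category]", "not available")
  t
}

# Independent search oracle: case-insensitive substring scan straight over
# the graph's term records (never touches the index).
brute_search_ids <- function(graph, query) {
  q <- tolower(gsub("[[:space:]]+", " ", trimws(query)))
  hit <- vapply(graph$terms, function(t) {
    if (t$obsolete) return(FALSE)
    keys <- tolower(gsub("[[:space:]]+", " ", trimws(c(t$label, t$synonyms))))
    any(grepl(q, keys, fixed = TRUE))
  }, logical(1))
  sort(names(graph$terms)[hit])
}

# Independent DFS enumeration of root-to-leaf label paths over parent links.
dfs_label_paths <- function(graph) {
  live <- Filter(function(t) !t$obsolete, graph$terms)
  kids <- lapply(live, function(t) character())
  for (t in live) for (p in t$parents) {
    if (p %in% names(live)) kids[[p]] <- c(kids[[p]], t$id)
  }
  out <- character()
  walk <- function(id, path) {
    path <- c(path, live[[id]]$label)
    ch <- kids[[id]]
    if (!length(ch)) {
      out[[length(out) + 1L]] <<- paste(path, collapse = " / ")
    } else {
      for (c_ in ch) walk(c_, path)
    }
  }
  roots <- names(live)[vapply(live, function(t) length(t$parents) == 0L, logical(1))]
  for (r in roots) walk(r, character())
  sort(out)
}

# Root-to-leaf paths of a nested-tree artifact.
nested_tree_paths <- function(tree) {
  out <- character()
  walk <- function(node, path) {
    if (!length(node)) {
      out[[length(out) + 1L]] <<- paste(path, collapse = " / ")
      return()
    }
    for (nm in names(node)) walk(node[[nm]], c(path, nm))
  }
  for (nm in names(tree$tree)) walk(tree$tree[[nm]], nm)
  sort(out)
}

# Random valid SDRF table for round-trip / rectangularity properties.
random_sdrf_table <- function(seed) {
  set.seed(seed)
  extra_pool <- c("characteristics[age]", "characteristics[sex]",
                  "comment[fraction identifier]", "comment[instrument]",
                  "factor value[disease]", "factor value[dose]")
  cols <- c("source name", "characteristics[organism]", "assay name",
            "comment[data file]", "technology type",
            sample(extra_pool, sample(0:4, 1)))
  cols <- canonical_order(cols)
  n <- sample(1:8, 1)
  vocab <- c("Homo sapiens", "liver", "not available", "42", "a b c",
             "x,y;z", "T: cell", "value [bracketed]")
  cells <- matrix(sample(vocab, n * length(cols), replace = TRUE),
                  nrow = n)
  cells[, match("comment[data file]", cols)] <- sprintf("f%03d.raw", seq_len(n))
  t <- create_template("default")
  t$columns <- cols
  t$cells <- cells
  t$provenance <- list()
  parse_sdrf(write_sdrf(t))  # normalize through the public surface
}

# Seeded corruption generators; each returns list(table, code).
corrupt_table <- function(class, base, seed) {
  set.seed(seed)
  if (class == "drop_required") {
    victim <- sample(c("characteristics[organism]", "comment[data file]",
                       "assay name", "technology type"), 1)
    return(list(table = remove_column(base, victim), code = "REQUIRED_MISSING"))
  }
  if (class == "blank_required") {
    col <- sample(c("source name", "comment[data file]",
                    "characteristics[organism]"), 1)
    r <- sample(sdrf_nrow(base), 1)
    base$cells[r, match(col, base$columns)] <- sample(c("", "not available"), 1)
    return(list(table = base, code = "REQUIRED_EMPTY"))
  }
  if (class == "bogus_term") {
    r <- sample(sdrf_nrow(base), 1)
    junk <- paste0("bogus-", paste(sample(letters, 8, TRUE), collapse = ""))
    base$cells[r, match("characteristics[organism]", base$columns)] <- junk
    return(list(table = base, code = "TERM_UNRESOLVED"))
  }
  if (class == "broken_kv") {
    r <- sample(sdrf_nrow(base), 1)
    pick <- sample(3, 1)
    cell <- c("Oxidation",                       # token without "="
              "NT=Oxidation;NT=Oxidation",       # duplicate key
              "AC=UNIMOD:35;MT=Variable")[pick]  # no NT
    code <- c("KV_MALFORMED", "KV_DUPLICATE", "KV_NO_NAME")[pick]
    base$cells[r, match("comment[modification parameters]", base$columns)] <- cell
    return(list(table = base, code = code))
  }
  if (class == "file_limit") {
    # direct row injection past set_raw_files' guard
    tmpl <- sample(sdrf_nrow(base), 1)
    n_extra <- 251L - length(unique(sdrf_column(base, "comment[data file]")))
    extra <- base$cells[rep(tmpl, n_extra), , drop = FALSE]
    extra[, match("comment[data file]", base$columns)] <-
      sprintf("inject_%03d.raw", seq_len(n_extra))
    base$cells <- rbind(base$cells, extra)
    return(list(table = base, code = "FILE_LIMIT"))
  }
  stop("unknown corruption class: ", class)
}

capture_cli <- function(argv) {
  stdout <- capture.output(status <- suppressMessages(cli_dispatch(argv)))
  list(status = status, stdout = stdout)
}
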