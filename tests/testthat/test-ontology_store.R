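test_that("parse_obo builds graphs from term stanzas", {
  obo <- paste(
    "[Term]\nid: X:1\nname: A",
    "[Term]\nid: X:2\nname: B\nis_a: X:1 ! A",
    "[Term]\nid: X:3\nname: C\nis_a: X:1",
    sep = "\n\n")
  g <- parse_obo(obo)
  expect_length(g$terms, 3L)
  expect_identical(g$roots, "X:1")
  expect_identical(g$terms[["X:2"]]$parents, "X:1")

  empty <- parse_obo("")
  expect_length(empty$terms, 0L)
  expect_length(empty$roots, 0L)

  expect_error(parse_obo("[Term]\nid: X:1"), "stanza 1",
               class = "sdrf_obo_parse_error")
  expect_error(
    parse_obo("[Term]\nid: X:1\nname: A\nis_a: X:2\n\n[Term]\nid: X:2\nname: B\nis_a: X:1"),
    "cyclic", class = "sdrf_cycle_error")
  expect_error(parse_obo("[Term]\nid: X:1\nname: A\nis_a: X:9"),
               "dangling", class = "sdrf_dangling_parent_error")
})

test_that("parse_obo agrees with an independent stanza line scan", {
  obo <- generate_toy_ontology(n_terms = 50L, depth = 4L, seed = 1L)
  lines <- strsplit(obo, "\n")[[1]]
  n_stanzas <- sum(lines == "[Term]")
  n_obsolete <- sum(lines == "is_obsolete: true")
  g <- parse_obo(obo)
  expect_identical(length(g$terms), n_stanzas)
  expect_identical(length(sdrfkit:::graph_term_ids(g)), n_stanzas - n_obsolete)
  expect_identical(length(g$terms), 50L)
})

test_that("term-list JSON import mirrors OBO parsing and round-trips", {
  expect_length(import_term_list_json("[]")$terms, 0L)
  g2 <- import_term_list_json(
    '[{"id": "X:1", "label": "A"}, {"id": "X:2", "label": "B", "parents": ["X:1"]}]')
  expect_length(g2$terms, 2L)
  expect_identical(g2$roots, "X:1")
  expect_error(import_term_list_json('{"id": "X:1"}'), class = "sdrf_import_error")
  expect_error(import_term_list_json('[{"id": "X:1"}]'), "record 1",
               class = "sdrf_import_error")

  g <- toy_graph()
  back <- import_term_list_json(export_term_list_json(g), name = g$name)
  expect_true(sdrfkit:::graph_equal(g, back))
})

test_that("element list excludes obsolete terms and conserves the multiset", {
  g <- import_term_list_json(
    '[{"id": "X:1", "label": "A"}, {"id": "X:2", "label": "b"},
      {"id": "X:3", "label": "C", "obsolete": true}]')
  expect_identical(build_element_list(g)$elements, c("A", "b"))
  expect_identical(build_element_list(parse_obo(""))$elements, character())

  g50 <- toy_graph(n = 50L, obsolete_rate = 0)
  el <- build_element_list(g50)
  expect_length(el$elements, 50L)
  all_labels <- vapply(g50$terms, function(t) t$label, character(1))
  expect_identical(sort(el$elements), sort(unname(all_labels)))
  expect_identical(el$elements, el$elements[order(tolower(el$elements),
                                                  method = "radix")])
})

test_that("nested tree duplicates multi-parent terms under each parent", {
  g <- import_term_list_json(
    '[{"id": "X:1", "label": "A"},
      {"id": "X:2", "label": "B", "parents": ["X:1"]},
      {"id": "X:3", "label": "C", "parents": ["X:1"]}]')
  nt <- build_nested_tree(g)
  expect_identical(names(nt$tree), "A")
  expect_identical(names(nt$tree$A), c("B", "C"))
  expect_length(nt$tree$A$B, 0L)

  diamond <- import_term_list_json(
    '[{"id": "X:1", "label": "A"},
      {"id": "X:2", "label": "B", "parents": ["X:1"]},
      {"id": "X:3", "label": "C", "parents": ["X:1"]},
      {"id": "X:4", "label": "D", "parents": ["X:2", "X:3"]}]')
  dt <- build_nested_tree(diamond)
  expect_identical(names(dt$tree$A$B), "D")
  expect_identical(names(dt$tree$A$C), "D")
})

test_that("nested-tree paths equal an independent DFS over parent links", {
  g <- toy_graph(n = 50L, seed = 2L, obsolete_rate = 0.05)
  expect_identical(nested_tree_paths(build_nested_tree(g)), dfs_label_paths(g))
})

test_that("select nodes mirror the nested tree with CURIE values", {
  g1 <- import_term_list_json('[{"id": "X:1", "label": "A"}]')
  sn <- build_select_nodes(g1)
  expect_identical(sn$nodes,
                   list(list(label = "A", value = "X:1", children = list())))
  expect_identical(build_select_nodes(parse_obo(""))$nodes, list())

  g <- toy_graph(n = 40L, seed = 3L)
  expect_identical(
    sdrfkit:::select_nodes_preorder(build_select_nodes(g)),
    sdrfkit:::nested_tree_preorder(build_nested_tree(g)))
  root_values <- vapply(build_select_nodes(g)$nodes, `[[`, character(1), "value")
  expect_setequal(root_values, g$roots)
})

test_that("gzipped artifacts round-trip, carry the gzip magic and are byte-stable", {
  g <- toy_graph(n = 30L, seed = 4L)
  dir <- withr::local_tempdir()
  for (artifact in list(build_element_list(g), build_nested_tree(g),
                        build_select_nodes(g))) {
    p <- file.path(dir, paste0(class(artifact)[1], ".json.gz"))
    write_artifact(artifact, p)
    magic <- readBin(p, "raw", n = 2)
    expect_identical(magic, as.raw(c(0x1f, 0x8b)))
    expect_identical(read_artifact(p), artifact)
    p2 <- file.path(dir, "again.json.gz")
    write_artifact(artifact, p2)
    expect_identical(readBin(p, "raw", file.size(p)),
                     readBin(p2, "raw", file.size(p2)))
  }

  plain <- file.path(dir, "plain.json")
  writeLines('{"type": "element_list"}', plain)
  expect_error(read_artifact(plain), class = "sdrf_format_error")

  gz <- file.path(dir, "trunc.json.gz")
  write_artifact(build_element_list(g), gz)
  full <- readBin(gz, "raw", file.size(gz))
  writeBin(full[1:20], gz)
  expect_error(read_artifact(gz), class = "sdrf_integrity_error")

  tiny <- file.path(dir, "tiny.json.gz")
  write_artifact(structure(list(ontology = "t", elements = character()),
                           class = "sdrf_element_list"), tiny)
  expect_lt(file.size(tiny), 200)
  expect_identical(read_artifact(tiny)$elements, character())
})

test_that("term index resolves labels and synonyms case-insensitively", {
  g <- import_term_list_json(
    '[{"id": "NCBITaxon:1", "label": "organism"},
      {"id": "NCBITaxon:9606", "label": "Homo sapiens",
       "parents": ["NCBITaxon:1"], "synonyms": ["human"]}]')
  idx <- build_term_index(g)
  expect_identical(lookup_term(idx, "human")$id, "NCBITaxon:9606")
  expect_identical(lookup_term(idx, "HOMO  SAPIENS")$id, "NCBITaxon:9606")
  expect_null(lookup_term(idx, "klingon"))

  g50 <- toy_graph(n = 50L, obsolete_rate = 0)
  idx50 <- build_term_index(g50)
  for (id in names(g50$terms)) {
    expect_identical(lookup_term(idx50, g50$terms[[id]]$label)$id, id)
  }
})

test_that("ambiguous labels resolve to the smallest CURIE with a warning record", {
  g <- import_term_list_json(
    '[{"id": "X:2", "label": "shared"}, {"id": "X:1", "label": "shared"}]')
  idx <- build_term_index(g)
  expect_identical(lookup_term(idx, "shared")$id, "X:1")
  expect_length(idx$warnings, 1L)
  expect_match(idx$warnings, "shared")
})

test_that("search ranks exact > prefix > substring and label > synonym", {
  idx <- taxonomy_index()
  hits <- search_terms(idx, "homo sap", limit = 10L)
  expect_identical(hits$label[1:2],
                   c("Homo sapiens", "Homo sapiens neanderthalensis"))
  expect_identical(hits$match_kind[1], "label_prefix")

  exact <- search_terms(idx, "Homo sapiens", limit = 10L)
  expect_identical(exact$label[1], "Homo sapiens")
  expect_identical(exact$match_kind[1], "label_exact")

  syn <- search_terms(idx, "human", limit = 10L)
  expect_identical(syn$id[1], "NCBITaxon:9606")
  expect_identical(syn$match_kind[1], "synonym_exact")

  expect_identical(nrow(search_terms(idx, "zzz-no-such-term")), 0L)
  expect_error(search_terms(idx, "   "), class = "sdrf_query_error")
})

test_that("search equals a brute-force scan of labels and synonyms", {
  g <- toy_graph(n = 50L, seed = 5L, obsolete_rate = 0.1)
  idx <- build_term_index(g)
  set.seed(99)
  labels <- vapply(g$terms, function(t) t$label, character(1))
  for (i in 1:40) {
    src <- sample(labels, 1)
    start <- sample(nchar(src), 1)
    q <- substr(src, start, min(nchar(src), start + sample(1:6, 1)))
    if (!nzchar(trimws(q))) next
    got <- search_terms(idx, q, limit = 10000L)
    expect_setequal(got$id, brute_search_ids(g, q))
  }
})

test_that("ancestors is the transitive closure over parents", {
  diamond <- import_term_list_json(
    '[{"id": "X:1", "label": "A"},
      {"id": "X:2", "label": "B", "parents": ["X:1"]},
      {"id": "X:3", "label": "C", "parents": ["X:1"]},
      {"id": "X:4", "label": "D", "parents": ["X:2", "X:3"]}]')
  expect_identical(ancestors(diamond, "X:1"), character())
  expect_identical(ancestors(diamond, "X:4"), c("X:1", "X:2", "X:3"))
  expect_error(ancestors(diamond, "X:9"), class = "sdrf_lookup_error")

  # fixed-point oracle + monotonicity over every parent link
  g <- toy_graph(n = 40L, seed = 6L)
  for (id in names(g$terms)) {
    anc <- character(); frontier <- id
    repeat {
      nxt <- unique(unlist(lapply(frontier, function(i) g$terms[[i]]$parents)))
      nxt <- setdiff(nxt, anc)
      if (!length(nxt)) break
      anc <- c(anc, nxt); frontier <- nxt
    }
    expect_identical(ancestors(g, id), sort(anc))
    for (p in g$terms[[id]]$parents) {
      expect_true(all(c(p, ancestors(g, p)) %in% ancestors(g, id)))
    }
  }
})

test_that("Unimod CSV loads, normalizes accessions and rejects bad input", {
  cat_ <- load_unimod_csv(unimod_csv_text())
  expect_identical(nrow(cat_$records), 2L)
  expect_setequal(cat_$records$accession, c("UNIMOD:35", "UNIMOD:4"))
  expect_identical(cat_$records$sites[[1]], "M")

  empty <- load_unimod_csv("Name,Accession\n")
  expect_identical(nrow(empty$records), 0L)

  norm <- load_unimod_csv("Name,Accession\nOxidation,35\n")
  expect_identical(norm$records$accession, "UNIMOD:35")

  expect_error(load_unimod_csv("Name,Foo\nOxidation,35\n"),
               class = "sdrf_schema_error")
  expect_error(load_unimod_csv("Name,Accession\nA,35\nB,35\n"),
               class = "sdrf_duplicate_error")
})
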