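test_that("map_metadata canonicalizes terms and reports a partition", {
  reg <- fixture_registry()
  t <- set_raw_files(create_template("default"), c("a.raw", "b.raw"))
  local_rows <- data.frame(organism = c("human", "Homo sapiens"),
                           check.names = FALSE)
  res <- map_metadata(t, local_rows, c(organism = "characteristics[organism]"),
                      registry = reg)
  expect_identical(sdrf_column(res$table, "characteristics[organism]"),
                   c("Homo sapiens", "Homo sapiens"))
  expect_identical(res$report$resolved, 1L)
  expect_identical(res$report$synonym_resolved, 1L)
  expect_identical(res$report$unresolved, 0L)

  local_bad <- data.frame(organism = c("unobtainium", "human"),
                          check.names = FALSE)
  res2 <- map_metadata(t, local_bad, c(organism = "characteristics[organism]"),
                       registry = reg)
  expect_identical(sdrf_column(res2$table, "characteristics[organism]")[1],
                   "unobtainium")  # left in place
  expect_identical(res2$report$unresolved_values[[1]], "unobtainium")
  # partition: counts sum to mapped cells
  expect_identical(res2$report$resolved + res2$report$synonym_resolved +
                     res2$report$unresolved, 2L)

  res3 <- map_metadata(t, local_rows, character(), registry = reg)
  expect_identical(res3$table$cells, t$cells)
  expect_identical(nrow(res3$report), 0L)

  expect_error(
    map_metadata(t, local_rows, c(nope = "characteristics[organism]"), reg),
    class = "sdrf_mapping_error")
  expect_error(
    map_metadata(t, data.frame(organism = "human"),
                 c(organism = "characteristics[organism]"), reg),
    class = "sdrf_alignment_error")

  # row/column counts never change for pre-existing targets
  expect_identical(sdrf_nrow(res$table), sdrf_nrow(t))
  expect_identical(res$table$columns, t$columns)
})

test_that("map_metadata joins on a local file-name column when present", {
  reg <- fixture_registry()
  t <- set_raw_files(create_template("default"), c("b.raw", "a.raw"))
  local_rows <- data.frame(file = c("a.raw", "b.raw"),
                           organism = c("human", "unobtainium"),
                           check.names = FALSE)
  res <- map_metadata(t, local_rows, c(organism = "characteristics[organism]"),
                      registry = reg)
  expect_identical(sdrf_column(res$table, "characteristics[organism]"),
                   c("unobtainium", "Homo sapiens"))

  local_missing <- data.frame(file = "a.raw", organism = "human",
                              check.names = FALSE)
  expect_error(map_metadata(t, local_missing,
                            c(organism = "characteristics[organism]"), reg),
               "b.raw", class = "sdrf_alignment_error")
})

test_that("expand_labels multiplies rows by channels and keeps other cells", {
  t <- set_raw_files(create_template("default"), c("a.raw", "b.raw"))
  tmt <- expand_labels(t, "TMT10plex")
  expect_identical(sdrf_nrow(tmt), 20L)
  expect_identical(sdrf_column(tmt, "comment[label]")[1:3],
                   c("TMT126", "TMT127N", "TMT127C"))

  lf <- expand_labels(set_raw_files(create_template("default"),
                                    c("a.raw", "b.raw", "c.raw")),
                      "label free sample")
  expect_identical(sdrf_nrow(lf), 3L)
  expect_identical(unique(sdrf_column(lf, "comment[label]")),
                   "label free sample")
  # single channel: source names unchanged
  expect_identical(sdrf_column(lf, "source name"),
                   c("sample 1", "sample 2", "sample 3"))

  one <- set_raw_files(create_template("default"), "a.raw")
  silac <- expand_labels(one, "SILAC light/heavy")
  expect_identical(sdrf_nrow(silac), 2L)
  expect_identical(sdrf_column(silac, "source name"),
                   c("sample 1 ch1", "sample 1 ch2"))
  same <- setdiff(silac$columns, c("comment[label]", "source name"))
  for (h in same) {
    expect_identical(sdrf_column(silac, h)[1], sdrf_column(silac, h)[2])
  }

  expect_error(expand_labels(silac, "SILAC light/heavy"),
               class = "sdrf_double_expansion_error")
  expect_error(expand_labels(create_template("default"), "TMT10plex"),
               class = "sdrf_input_error")
  expect_error(label_scheme("TMT99plex"), class = "sdrf_scheme_error")
})

test_that("expand_labels conserves per-column multisets", {
  t <- happy_table(n_files = 3L, scheme = "label free sample")
  for (name in names(label_schemes())) {
    scheme <- label_scheme(name)
    base <- t
    base$cells[, match("comment[label]", base$columns)] <- "not available"
    out <- expand_labels(base, scheme)
    k <- length(scheme$channels)
    expect_identical(sdrf_nrow(out), sdrf_nrow(base) * k)
    for (h in setdiff(base$columns, c("comment[label]", "source name"))) {
      expect_identical(sort(sdrf_column(out, h)),
                       sort(rep(sdrf_column(base, h), k)))
    }
  }
})

test_that("fill_column broadcasts, canonicalizes and fails atomically", {
  reg <- fixture_registry()
  idx <- reg$indices$instrument
  t <- set_raw_files(create_template("default"), c("a.raw", "b.raw"))

  ok <- fill_column(t, "comment[instrument]", "Orbitrap Fusion Lumos", idx)
  expect_identical(unique(sdrf_column(ok, "comment[instrument]")),
                   "Orbitrap Fusion Lumos")
  syn <- fill_column(t, "comment[instrument]", "QE-HF", idx)
  expect_identical(unique(sdrf_column(syn, "comment[instrument]")),
                   "Q Exactive HF")  # synonym rewritten

  before <- t$cells
  expect_error(fill_column(t, "comment[instrument]", "banana", idx),
               "banana", class = "sdrf_term_error")
  expect_identical(t$cells, before)  # untouched

  expect_error(fill_column(t, "comment[instrument]", c("a", "b", "c"), idx),
               class = "sdrf_alignment_error")
  per_row <- fill_column(t, "comment[instrument]",
                         c("Orbitrap Fusion Lumos", "Q Exactive HF"), idx)
  expect_identical(sdrf_column(per_row, "comment[instrument]"),
                   c("Orbitrap Fusion Lumos", "Q Exactive HF"))
})

test_that("presets add their columns once, idempotently", {
  t <- create_template("default")
  preset_cols <- presets()$metaproteomics
  out <- apply_preset(t, "metaproteomics")
  expect_identical(sdrf_ncol(out), sdrf_ncol(t) + length(preset_cols))
  expect_true(all(preset_cols %in% out$columns))
  again <- apply_preset(out, "metaproteomics")
  expect_identical(again$columns, out$columns)
  expect_identical(again$cells, out$cells)
  expect_error(apply_preset(t, "astrology"), class = "sdrf_preset_error")
})

test_that("merge_partial keeps annotated cells and enforces the file limit", {
  reg <- fixture_registry()
  tmpl <- set_raw_files(create_template("default"), c("a.raw", "b.raw"))
  partial <- fill_column(tmpl, "characteristics[organism]", "Homo sapiens")
  merged <- merge_partial(partial, tmpl)
  expect_identical(sdrf_nrow(merged), 2L)
  expect_identical(unique(sdrf_column(merged, "characteristics[organism]")),
                   "Homo sapiens")

  # idempotent on its own output
  twice <- merge_partial(merged, merged)
  expect_identical(twice$columns, merged$columns)
  expect_identical(twice$cells, merged$cells)

  # disjoint file sets union
  p1 <- set_raw_files(create_template("default"), "a.raw")
  p2 <- set_raw_files(create_template("default"), "b.raw")
  expect_identical(sdrf_nrow(merge_partial(p1, p2)), 2L)

  big <- set_raw_files(create_template("default"), sprintf("f%03d.raw", 1:250))
  extra <- set_raw_files(create_template("default"), "g.raw")
  expect_error(merge_partial(extra, big), "250",
               class = "sdrf_file_limit_error")

  confl_a <- fill_column(tmpl, "characteristics[organism]", "Homo sapiens")
  confl_b <- fill_column(tmpl, "characteristics[organism]", "Mus musculus")
  expect_error(merge_partial(confl_a, confl_b), class = "sdrf_conflict_error")
})

test_that("the submission hash is canonical-content pure", {
  t <- happy_table(n_files = 2L)
  txt <- write_sdrf(t)
  h1 <- stamp_hash(txt)
  expect_match(h1$digest, "^[0-9a-f]{64}$")
  expect_identical(h1$algorithm, "SHA-256")

  # permute columns and re-case a header: same digest
  perm <- sample(seq_along(t$columns))
  lines <- strsplit(txt, "\n")[[1]]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  permuted <- vapply(fields, function(f) paste(f[perm], collapse = "\t"),
                     character(1))
  permuted[1] <- sub("source name", "Source Name", permuted[1], fixed = TRUE)
  h2 <- stamp_hash(paste0(paste(permuted, collapse = "\n"), "\n"))
  expect_identical(h2$digest, h1$digest)

  # any cell edit changes it; 1000 random single-edits never collide
  set.seed(21)
  digests <- vapply(1:1000, function(i) {
    mod <- t
    r <- sample(sdrf_nrow(mod), 1); c_ <- sample(sdrf_ncol(mod), 1)
    mod$cells[r, c_] <- sprintf("edit %d", i)
    stamp_hash(write_sdrf(mod))$digest
  }, character(1))
  expect_false(h1$digest %in% digests)
  expect_identical(anyDuplicated(digests), 0L)

  expect_error(stamp_hash(""), class = "sdrf_parse_error")

  dir <- withr::local_tempdir()
  p <- file.path(dir, "out.sdrf.tsv")
  write_sdrf_file(t, p)
  side <- write_hash_sidecar(h1, p)
  expect_identical(readLines(side), sprintf("%s  %s", h1$digest, "out.sdrf.tsv"))
})

test_that("the composed workflow yields a valid SDRF", {
  t <- happy_table(n_files = 3L, scheme = "TMT6plex")
  report <- validate_table(t, "human", fixture_registry())
  expect_true(report$passed)
  expect_identical(sum(report$findings$severity == "error"), 0L)
})
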