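# Annotation workflow ----------------------------------------------------
#
# The five-step annotation path as composable operations: map a local
# metadata table into SDRF columns with ontology canonicalization, expand
# rows over label channels, fill columns (broadcast or per row), apply
# column presets, merge a partially annotated file back into a template,
# and stamp a canonical SHA-256 hash for submission.

#' Shipped label schemes
#'
#' Named lists of channel names: TMT 6/10/11/16-plex (PSI-MS channel
#' naming), SILAC light/heavy, iTRAQ 4/8-plex and the single-channel
#' `"label free sample"`.
#'
#' @param path Registry JSON (defaults to the shipped file).
#' @return Named list of character vectors.
#' @export
label_schemes <- function(path = registry_file("label_schemes.json")) {
  reg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lapply(reg, as.character)
}

#' Look up one label scheme
#'
#' @param name Scheme name (case-insensitive).
#' @param schemes Registry from [label_schemes()].
#' @return A list of class `sdrf_label_scheme` with `name` and `channels`.
#' @export
label_scheme <- function(name, schemes = label_schemes()) {
  i <- match(tolower(trimws(name)), tolower(names(schemes)))
  if (is.na(i)) {
    sdrf_abort(sprintf("unknown label scheme '%s'; available: %s",
                       name, paste(names(schemes), collapse = ", ")),
               "sdrf_scheme_error")
  }
  channels <- schemes[[i]]
  if (anyDuplicated(channels) || !length(channels)) {
    sdrf_abort(sprintf("label scheme '%s' has empty or duplicated channels",
                       names(schemes)[i]), "sdrf_scheme_error")
  }
  structure(list(name = names(schemes)[i], channels = channels),
            class = "sdrf_label_scheme")
}

#' Shipped column presets
#'
#' Currently a metaproteomics set (environmental material, biome,
#' metagenome accession, assembly strategy); data-driven, so domain
#' communities can ship their own sets without code changes.
#'
#' @param path Registry JSON (defaults to the shipped file).
#' @return Named list of character vectors of column headers.
#' @export
presets <- function(path = registry_file("presets.json")) {
  reg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lapply(reg, as.character)
}

#' Map local metadata into SDRF columns with ontology compliance
#'
#' Each mapped cell is resolved against the ontology bound to its target
#' column: an exact label match is kept with the vocabulary's canonical
#' casing, a synonym match is rewritten to the canonical label, anything
#' else is written verbatim and reported as unresolved. Alignment is
#' positional when the local table has exactly one row per SDRF row;
#' otherwise a local file-name column (named `file`, `data file` or
#' `comment[data file]`) is joined on `comment[data file]`.
#'
#' @param table An `sdrf_table` with rows (files already registered).
#' @param local_rows Data frame of the user's local metadata (header row
#'   becomes column names).
#' @param mapping Named character vector or list: local column name ->
#'   target SDRF header.
#' @param registry An [ontology_bindings()] registry (may be empty: all
#'   targets then count as resolved verbatim).
#' @return List with `table` (new `sdrf_table`) and `report` (data frame
#'   with one row per mapping pair: `local`, `target`, `resolved`,
#'   `synonym_resolved`, `unresolved` counts, and an `unresolved_values`
#'   list column of distinct offending strings).
#' @export
map_metadata <- function(table, local_rows, mapping,
                         registry = ontology_bindings()) {
  mapping <- unlist(mapping)
  report0 <- data.frame(local = character(), target = character(),
                        resolved = integer(), synonym_resolved = integer(),
                        unresolved = integer(), stringsAsFactors = FALSE)
  report0$unresolved_values <- list()
  if (!length(mapping)) {
    return(list(table = table, report = report0))
  }
  if (is.null(names(mapping)) || any(!nzchar(names(mapping)))) {
    sdrf_abort("mapping must be named: local column -> target header",
               "sdrf_mapping_error")
  }
  if (anyDuplicated(names(mapping)) || anyDuplicated(unlist(mapping))) {
    sdrf_abort("mapping local names and targets must be unique",
               "sdrf_mapping_error")
  }
  absent <- setdiff(names(mapping), names(local_rows))
  if (length(absent)) {
    sdrf_abort(sprintf("mapping references absent local column(s): %s",
                       paste(absent, collapse = ", ")),
               "sdrf_mapping_error")
  }
  # row alignment: positional, or joined on a local file-name column
  n <- sdrf_nrow(table)
  file_col <- intersect(c("file", "data file", "comment[data file]"),
                        tolower(names(local_rows)))
  if (length(file_col)) {
    local_files <- as.character(local_rows[[match(file_col[1], tolower(names(local_rows)))]])
    row_of <- match(sdrf_column(table, "comment[data file]"), local_files)
    if (anyNA(row_of)) {
      sdrf_abort(sprintf("local metadata has no row for file(s): %s",
                         paste(sdrf_column(table, "comment[data file]")[is.na(row_of)],
                               collapse = ", ")),
                 "sdrf_alignment_error")
    }
  } else if (nrow(local_rows) == n) {
    row_of <- seq_len(n)
  } else {
    sdrf_abort(sprintf("local metadata has %d row(s) but the table has %d and no file-name column to join on",
                       nrow(local_rows), n),
               "sdrf_alignment_error")
  }

  out <- table
  report <- report0
  for (local in names(mapping)) {
    target <- parse_column_header(mapping[[local]])$header
    if (is.na(column_index(out, target, required = FALSE))) {
      out <- add_column(out, target)
    }
    values <- as.character(local_rows[[local]])[row_of]
    index <- binding_index(registry, target)
    n_exact <- n_syn <- 0L
    bad <- character()
    resolved <- vapply(values, function(v) {
      if (is.null(index) || is_missing_token(v) || !nzchar(trimws(v))) {
        n_exact <<- n_exact + 1L
        return(trimws(v))
      }
      hit <- lookup_term(index, v)
      if (is.null(hit)) {
        bad <<- c(bad, trimws(v))
        trimws(v)
      } else if (hit$kind == "label") {
        n_exact <<- n_exact + 1L
        hit$label
      } else {
        n_syn <<- n_syn + 1L
        hit$label
      }
    }, character(1), USE.NAMES = FALSE)
    out$cells[, column_index(out, target)] <- resolved
    rep_row <- data.frame(local = local, target = target,
                          resolved = n_exact, synonym_resolved = n_syn,
                          unresolved = length(bad), stringsAsFactors = FALSE)
    rep_row$unresolved_values <- list(unique(bad))
    report <- rbind(report, rep_row)
  }
  rownames(report) <- NULL
  list(table = out, report = report)
}

#' Expand SDRF rows over label channels
#'
#' Each row is replaced by one row per channel, identical except
#' `comment[label]` (set to the channel name) and `source name` (suffixed
#' `" ch<j>"`, 1-based), so every channel of every raw file names a
#' distinct sample. Channel order is preserved within each file block.
#'
#' @param table An `sdrf_table` with at least one row.
#' @param scheme An [label_scheme()] (or a scheme name).
#' @return A new `sdrf_table` with `nrow * length(channels)` rows.
#' @export
expand_labels <- function(table, scheme) {
  if (is.character(scheme)) scheme <- label_scheme(scheme)
  stopifnot(inherits(scheme, "sdrf_label_scheme"))
  if (!sdrf_nrow(table)) {
    sdrf_abort("cannot expand labels on a table with no rows",
               "sdrf_input_error")
  }
  if (is.na(column_index(table, "comment[label]", required = FALSE))) {
    table <- add_column(table, "comment[label]")
  }
  label_i <- column_index(table, "comment[label]")
  file_i <- column_index(table, "comment[data file]", required = FALSE)
  if (!is.na(file_i) && length(scheme$channels) > 1L) {
    per_file <- split(table$cells[, label_i], table$cells[, file_i])
    if (any(vapply(per_file, function(l) all(scheme$channels %in% l), logical(1)))) {
      sdrf_abort(sprintf("table already expanded with scheme '%s'", scheme$name),
                 "sdrf_double_expansion_error")
    }
  }
  k <- length(scheme$channels)
  src_i <- column_index(table, "source name")
  rows <- rep(seq_len(nrow(table$cells)), each = k)
  cells <- table$cells[rows, , drop = FALSE]
  cells[, label_i] <- rep(scheme$channels, times = nrow(table$cells))
  if (k > 1L) {
    cells[, src_i] <- paste0(cells[, src_i], " ch",
                             rep(seq_len(k), times = nrow(table$cells)))
  }
  new_sdrf_table(table$columns, cells, table$provenance)
}

#' Fill an SDRF column, optionally enforcing ontology terms
#'
#' With a bound index, every value must resolve exactly or by synonym
#' (synonyms are rewritten to the canonical label) or the whole operation
#' fails and the table is returned unchanged — a failed broadcast never
#' leaves a half-written column. Missing-value tokens always pass.
#'
#' @param table An `sdrf_table`.
#' @param header Target column (must be present).
#' @param values Single string (broadcast) or one value per row.
#' @param index Optional [build_term_index()] bound to the column.
#' @return A new `sdrf_table`.
#' @export
fill_column <- function(table, header, values, index = NULL) {
  i <- column_index(table, header)
  n <- sdrf_nrow(table)
  values <- as.character(values)
  if (length(values) == 1L) values <- rep(values, n)
  if (length(values) != n) {
    sdrf_abort(sprintf("%d value(s) for %d row(s)", length(values), n),
               "sdrf_alignment_error")
  }
  values <- trimws(values)
  if (!is.null(index)) {
    out_vals <- character(n)
    bad <- character()
    for (r in seq_len(n)) {
      v <- values[r]
      if (is_missing_token(v) || !nzchar(v)) { out_vals[r] <- v; next }
      hit <- lookup_term(index, v)
      if (is.null(hit)) bad <- c(bad, v) else out_vals[r] <- hit$label
    }
    if (length(bad)) {
      sdrf_abort(sprintf("value(s) not in the bound vocabulary for %s: %s",
                         table$columns[i], paste(unique(bad), collapse = ", ")),
                 "sdrf_term_error")
    }
    values <- out_vals
  }
  table$cells[, i] <- values
  new_sdrf_table(table$columns, table$cells, table$provenance)
}

#' Apply a column preset
#'
#' Adds every preset column not already present (cells default to
#' `"not available"`) at its canonical position. Idempotent.
#'
#' @param table An `sdrf_table`.
#' @param name Preset name.
#' @param registry Registry from [presets()].
#' @return A new `sdrf_table`.
#' @export
apply_preset <- function(table, name, registry = presets()) {
  i <- match(tolower(trimws(name)), tolower(names(registry)))
  if (is.na(i)) {
    sdrf_abort(sprintf("unknown preset '%s'; available: %s",
                       name, paste(names(registry), collapse = ", ")),
               "sdrf_preset_error")
  }
  for (h in registry[[i]]) {
    if (is.na(column_index(table, h, required = FALSE))) {
      table <- add_column(table, h)
    }
  }
  table
}

#' Merge a partially annotated SDRF back into a template table
#'
#' Rows are keyed by `comment[data file]`; the merged table takes the union
#' of columns in canonical order. Annotated (non-default) cells from the
#' partial file win over template defaults; two different non-default
#' values for the same cell are a conflict. The merged table may not hold
#' more than 250 distinct data files.
#'
#' @param partial An `sdrf_table` carrying prior annotation.
#' @param template An `sdrf_table` (typically a fresh template with files).
#' @return A new merged `sdrf_table`.
#' @export
merge_partial <- function(partial, template) {
  for (t in list(partial, template)) {
    if (is.na(column_index(t, "comment[data file]", required = FALSE))) {
      sdrf_abort("both tables need a comment[data file] column to merge on",
                 "sdrf_merge_error")
    }
  }
  is_default <- function(v) !nzchar(v) | is_missing_token(v) |
    grepl("^(sample|run) [0-9]+( ch[0-9]+)?$", v)
  cols <- canonical_order(union(template$columns, partial$columns))
  keys_t <- sdrf_column(template, "comment[data file]")
  keys_p <- sdrf_column(partial, "comment[data file]")
  if (anyDuplicated(keys_t) || anyDuplicated(keys_p)) {
    sdrf_abort("merge requires one row per data file on each side (expand labels after merging)",
               "sdrf_merge_error")
  }
  all_keys <- c(keys_t, setdiff(keys_p, keys_t))
  if (length(unique(all_keys)) > MAX_RAW_FILES) {
    sdrf_abort(sprintf("merged table would hold %d distinct files; the limit is %d",
                       length(unique(all_keys)), MAX_RAW_FILES),
               "sdrf_file_limit_error")
  }
  cell_of <- function(tab, keys, key, col) {
    j <- match(col, tab$columns)
    r <- match(key, keys)
    if (is.na(j) || is.na(r)) NA_character_ else tab$cells[r, j]
  }
  cells <- matrix("not available", nrow = length(all_keys), ncol = length(cols))
  for (r in seq_along(all_keys)) {
    key <- all_keys[r]
    for (j in seq_along(cols)) {
      vt <- cell_of(template, keys_t, key, cols[j])
      vp <- cell_of(partial, keys_p, key, cols[j])
      has_t <- !is.na(vt) && !is_default(vt)
      has_p <- !is.na(vp) && !is_default(vp)
      if (has_t && has_p && vt != vp) {
        if (cols[j] == "source name") {
          sdrf_abort(sprintf("data file '%s' has different source names ('%s' vs '%s')",
                             key, vp, vt), "sdrf_key_error")
        }
        sdrf_abort(sprintf("conflicting values for file '%s', column %s: '%s' vs '%s'",
                           key, cols[j], vp, vt), "sdrf_conflict_error")
      }
      cells[r, j] <- if (has_p) vp else if (has_t) vt
        else if (!is.na(vp) && nzchar(vp)) vp
        else if (!is.na(vt) && nzchar(vt)) vt
        else "not available"
    }
  }
  new_sdrf_table(cols, cells, template$provenance)
}

# Submission hash ---------------------------------------------------------

HASH_CANONICALIZATION <- "sdrf-canonical-v1"

#' Stamp a submission hash on SDRF content
#'
#' The digest is SHA-256 over the canonical serialization (canonical column
#' order, lowercase headers, LF endings, single trailing newline), so
#' permuting columns or re-casing headers never changes it while any cell
#' edit does. Invalid SDRF content is refused.
#'
#' @param sdrf_text Tab-delimited SDRF content.
#' @return A list of class `sdrf_hash`: `algorithm` (`"SHA-256"`), `digest`
#'   (64 lowercase hex chars) and `canonicalization` tag.
#' @export
stamp_hash <- function(sdrf_text) {
  table <- parse_sdrf(sdrf_text)
  # a total column order (category rank, then header), unlike the
  # insertion-stable canonical_order, so column permutations hash alike
  rank <- vapply(table$columns,
                 function(h) COLUMN_CATEGORIES[[column_category(h)]],
                 integer(1))
  ord <- order(rank, table$columns, method = "radix")
  table$columns <- table$columns[ord]
  table$cells <- table$cells[, ord, drop = FALSE]
  canonical <- write_sdrf(table)
  structure(
    list(algorithm = "SHA-256",
         digest = digest::digest(charToRaw(enc2utf8(canonical)),
                                 algo = "sha256", serialize = FALSE),
         canonicalization = HASH_CANONICALIZATION),
    class = "sdrf_hash"
  )
}

#' @export
print.sdrf_hash <- function(x, ...) {
  cat(sprintf("<sdrf_hash %s %s (%s)>\n", x$algorithm, x$digest,
              x$canonicalization))
  invisible(x)
}

#' Write a checksum sidecar for an SDRF file
#'
#' Single line `"<digest>  <filename>"`, the common checksum-file layout.
#'
#' @param hash An [stamp_hash()] result.
#' @param sdrf_path Path of the SDRF file the hash stamps.
#' @param path Sidecar path (default `<sdrf_path>.sha256`).
#' @return Sidecar path, invisibly.
#' @export
write_hash_sidecar <- function(hash, sdrf_path,
                               path = paste0(sdrf_path, ".sha256")) {
  writeLines(sprintf("%s  %s", hash$digest, basename(sdrf_path)), path)
  invisible(path)
}
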