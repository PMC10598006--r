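# Validation -------------------------------------------------------------
#
# Structural and ontology-compliance checks over an SDRF table, reported as
# findings with a machine-readable code drawn from a closed registry:
#
#   REQUIRED_MISSING  error    template column absent
#   REQUIRED_EMPTY    error    blank / placeholder cell in a hard-required
#                              column (source name, data file, organism)
#   TERM_UNRESOLVED   error*   value not in the bound vocabulary
#                              (*warning on non-template columns)
#   TERM_SYNONYM      warning  synonym used; canonical label suggested
#   KV_MALFORMED      error    key=value token without "="
#   KV_DUPLICATE      error    repeated key within one cell
#   KV_NO_NAME        error    key=value cell without NT
#   KV_UNKNOWN_KEY    warning  key outside the recognized set
#   RAGGED_ROW        error    row length differs from header
#   FILE_LIMIT        error    more than 250 distinct data files
#   FACTOR_ORPHAN     warning  factor value[x] without characteristics[x]
#
# Rows are 1-based data rows; 0 marks the header, NA marks table-level
# findings.

FINDING_CODES <- c("REQUIRED_MISSING", "REQUIRED_EMPTY", "TERM_UNRESOLVED",
                   "TERM_SYNONYM", "KV_MALFORMED", "KV_DUPLICATE",
                   "KV_NO_NAME", "KV_UNKNOWN_KEY", "RAGGED_ROW",
                   "FILE_LIMIT", "FACTOR_ORPHAN")

KV_KEYS <- c("NT", "AC", "MT", "PP", "TA", "TS", "CS", "MM")

KV_COLUMNS <- c("comment[modification parameters]",
                "comment[cleavage agent details]")

finding <- function(severity, code, message, row = NA_integer_,
                    column = NA_character_) {
  stopifnot(code %in% FINDING_CODES, severity %in% c("error", "warning"))
  data.frame(severity = severity, code = code, row = as.integer(row),
             column = column, message = message, stringsAsFactors = FALSE)
}

no_findings <- function() {
  data.frame(severity = character(), code = character(), row = integer(),
             column = character(), message = character(),
             stringsAsFactors = FALSE)
}

#' Parse an SDRF key=value cell
#'
#' The grammar used by modification-parameter and cleavage-agent cells:
#' `;`-separated tokens, each `KEY=value` (split on the first `=`), keys
#' upper-cased and whitespace-trimmed. Recognized keys: NT, AC, MT, PP, TA,
#' TS, CS, MM; unknown keys are kept and flagged. A valid cell always
#' carries NT.
#'
#' @param text Non-empty cell content.
#' @return A list of class `sdrf_kv_cell`: `entries` (named character
#'   vector, insertion order) and `unknown_keys`.
#' @export
parse_key_value_cell <- function(text) {
  if (!is_string(text) || !nzchar(trimws(text))) {
    sdrf_abort("empty key=value cell", "sdrf_kv_malformed_error")
  }
  tokens <- trimws(strsplit(text, ";", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  keys <- character(length(tokens))
  vals <- character(length(tokens))
  for (i in seq_along(tokens)) {
    eq <- regexpr("=", tokens[i], fixed = TRUE)
    if (eq < 0L) {
      sdrf_abort(sprintf("token without '=': %s", tokens[i]),
                 "sdrf_kv_malformed_error")
    }
    keys[i] <- toupper(trimws(substr(tokens[i], 1L, eq - 1L)))
    vals[i] <- trimws(substr(tokens[i], eq + 1L, nchar(tokens[i])))
  }
  if (anyDuplicated(keys)) {
    sdrf_abort(sprintf("duplicate key(s): %s",
                       paste(unique(keys[duplicated(keys)]), collapse = ", ")),
               "sdrf_kv_duplicate_error")
  }
  if (!"NT" %in% keys) {
    sdrf_abort("key=value cell lacks NT (name)", "sdrf_kv_no_name_error")
  }
  structure(list(entries = stats::setNames(vals, keys),
                 unknown_keys = setdiff(keys, KV_KEYS)),
            class = "sdrf_kv_cell")
}

# Ontology-binding registry ----------------------------------------------

#' Bundle ontology indexes, column bindings and a modification catalog
#'
#' `bindings` maps column headers to ontology keys; `indices` maps those
#' keys to [build_term_index()] indexes. A column whose ontology key has no
#' index behaves as unbound (free text). The shipped default bindings tie
#' organism to a taxonomy, organism part / cell type to an anatomy
#' vocabulary, instrument and cleavage agents to an instrument vocabulary
#' and the label column to the label-scheme vocabulary.
#'
#' @param indices Named list of term indexes, keyed by ontology key.
#' @param bindings Named character vector: header -> ontology key.
#' @param catalog Optional [load_unimod_csv()] catalog for modification
#'   cells.
#' @return A list of class `sdrf_bindings`.
#' @export
ontology_bindings <- function(indices = list(),
                              bindings = default_bindings(),
                              catalog = NULL) {
  structure(list(indices = indices, bindings = unlist(bindings),
                 catalog = catalog),
            class = "sdrf_bindings")
}

#' Shipped column-to-ontology bindings
#' @param path Registry JSON (defaults to the shipped file).
#' @return Named character vector: header -> ontology key.
#' @export
default_bindings <- function(path = registry_file("bindings.json")) {
  unlist(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

binding_index <- function(registry, header) {
  if (!inherits(registry, "sdrf_bindings")) return(NULL)
  key <- registry$bindings[header]
  if (is.na(key)) return(NULL)
  registry$indices[[key]]
}

#' Resolve one value against the vocabulary bound to a column
#'
#' @param value Cell value.
#' @param header Rendered column header.
#' @param registry An [ontology_bindings()] registry.
#' @return A list: `status` one of `"exact"`, `"synonym"`, `"unresolved"`,
#'   `"unbound"`; `canonical` (canonical label for exact/synonym hits);
#'   `id` (CURIE or NA). Missing-value tokens on bound columns are
#'   `"exact"`. Statuses, never exceptions.
#' @export
resolve_term <- function(value, header, registry) {
  header <- parse_column_header(header)$header
  index <- binding_index(registry, header)
  if (is.null(index)) {
    return(list(status = "unbound", canonical = value, id = NA_character_))
  }
  if (is_missing_token(value) || !nzchar(trimws(value))) {
    return(list(status = "exact", canonical = value, id = NA_character_))
  }
  hit <- lookup_term(index, value)
  if (is.null(hit)) {
    return(list(status = "unresolved", canonical = value, id = NA_character_))
  }
  list(status = if (hit$kind == "label") "exact" else "synonym",
       canonical = hit$label, id = hit$id)
}

#' Check required columns and hard-required cells against a template
#'
#' @param table An `sdrf_table`.
#' @param template Character vector of required headers, or a species key
#'   resolved through [species_templates()].
#' @return Findings data frame (`REQUIRED_MISSING` / `REQUIRED_EMPTY`).
#' @export
validate_required <- function(table, template = "default") {
  required <- template_columns(template)
  findings <- no_findings()
  for (h in setdiff(required, table$columns)) {
    findings <- rbind(findings,
      finding("error", "REQUIRED_MISSING",
              sprintf("required column %s is missing", h), column = h))
  }
  hard <- c("source name", "comment[data file]", "characteristics[organism]")
  for (h in intersect(hard, table$columns)) {
    vals <- sdrf_column(table, h)
    empty <- which(!nzchar(vals) | is_missing_token(vals))
    for (r in empty) {
      findings <- rbind(findings,
        finding("error", "REQUIRED_EMPTY",
                sprintf("%s is empty in row %d", h, r), row = r, column = h))
    }
  }
  findings
}

template_columns <- function(template) {
  if (is.character(template) && length(template) == 1L &&
      !grepl("\\[", template) && !template %in% names(BARE_HEADERS)) {
    template <- species_templates()[[tolower(template)]] %||%
      sdrf_abort(sprintf("unknown species template '%s'", template),
                 "sdrf_template_error")
  }
  vapply(template, function(h) parse_column_header(h)$header, character(1),
         USE.NAMES = FALSE)
}

#' Validate an SDRF table
#'
#' Accumulates findings from required-column presence, rectangularity,
#' per-cell term resolution on bound columns, key=value grammar on
#' modification-parameter and cleavage-agent cells, the 250-distinct-file
#' limit, empty hard-required cells, and orphaned factor value columns.
#' Findings are ordered by row, then column, then code; the report passes
#' iff no error-severity finding exists.
#'
#' @param table An `sdrf_table`.
#' @param template Required-column template (header vector or species key).
#' @param registry An [ontology_bindings()] registry.
#' @return A list of class `sdrf_validation_report`: `findings` data frame
#'   and `passed` flag.
#' @export
validate_table <- function(table, template = "default",
                           registry = ontology_bindings()) {
  findings <- validate_required(table, template)
  required <- template_columns(template)

  # rectangularity (defensive: the class maintains it, hand-built cell
  # matrices can still be malformed)
  if (!is.matrix(table$cells) || ncol(table$cells) != length(table$columns)) {
    findings <- rbind(findings,
      finding("error", "RAGGED_ROW", "cell matrix does not match the header"))
  }

  for (j in seq_along(table$columns)) {
    h <- table$columns[j]
    vals <- table$cells[, j]
    sev <- if (h %in% required) "error" else "warning"
    if (h %in% KV_COLUMNS) {
      findings <- rbind(findings, validate_kv_column(vals, h, registry, sev))
      next
    }
    if (is.null(binding_index(registry, h))) next
    for (r in seq_along(vals)) {
      res <- resolve_term(vals[r], h, registry)
      if (res$status == "unresolved") {
        findings <- rbind(findings,
          finding(sev, "TERM_UNRESOLVED",
                  sprintf("'%s' is not in the vocabulary bound to %s",
                          vals[r], h), row = r, column = h))
      } else if (res$status == "synonym") {
        findings <- rbind(findings,
          finding("warning", "TERM_SYNONYM",
                  sprintf("'%s' is a synonym; use '%s'", vals[r], res$canonical),
                  row = r, column = h))
      }
    }
  }

  file_i <- column_index(table, "comment[data file]", required = FALSE)
  if (!is.na(file_i)) {
    files <- unique(table$cells[, file_i])
    files <- files[nzchar(files) & !is_missing_token(files)]
    if (length(files) > MAX_RAW_FILES) {
      findings <- rbind(findings,
        finding("error", "FILE_LIMIT",
                sprintf("%d distinct data files exceed the %d-file limit",
                        length(files), MAX_RAW_FILES),
                column = "comment[data file]"))
    }
  }

  for (h in table$columns) {
    if (column_category(h) == "factor_value") {
      attr_ <- column_attribute(h)
      if (!sprintf("characteristics[%s]", attr_) %in% table$columns) {
        findings <- rbind(findings,
          finding("warning", "FACTOR_ORPHAN",
                  sprintf("%s has no matching characteristics[%s] column",
                          h, attr_), column = h))
      }
    }
  }

  findings <- sort_findings(findings)
  structure(list(findings = findings,
                 passed = !any(findings$severity == "error")),
            class = "sdrf_validation_report")
}

validate_kv_column <- function(vals, header, registry, severity) {
  findings <- no_findings()
  for (r in seq_along(vals)) {
    v <- vals[r]
    if (!nzchar(trimws(v)) || is_missing_token(v)) next
    cell <- tryCatch(parse_key_value_cell(v), sdrfkit_error = identity)
    if (inherits(cell, "condition")) {
      code <- if (inherits(cell, "sdrf_kv_duplicate_error")) "KV_DUPLICATE"
              else if (inherits(cell, "sdrf_kv_no_name_error")) "KV_NO_NAME"
              else "KV_MALFORMED"
      findings <- rbind(findings,
        finding(severity, code, conditionMessage(cell), row = r, column = header))
      next
    }
    for (k in cell$unknown_keys) {
      findings <- rbind(findings,
        finding("warning", "KV_UNKNOWN_KEY",
                sprintf("unrecognized key '%s'", k), row = r, column = header))
    }
    findings <- rbind(findings,
                      validate_kv_terms(cell, header, registry, severity, r))
  }
  findings
}

# NT/AC of modification cells check against the modification catalog; the
# NT of cleavage cells checks against the bound (instrument) vocabulary.
validate_kv_terms <- function(cell, header, registry, severity, row) {
  findings <- no_findings()
  nt <- cell$entries[["NT"]]
  if (header == "comment[modification parameters]" &&
      inherits(registry, "sdrf_bindings") && !is.null(registry$catalog)) {
    hit <- lookup_modification(registry$catalog, name = nt,
                               accession = cell$entries["AC"][[1]])
    if (is.null(hit)) {
      findings <- rbind(findings,
        finding(severity, "TERM_UNRESOLVED",
                sprintf("modification '%s' is not in the catalog", nt),
                row = row, column = header))
    }
  }
  if (header == "comment[cleavage agent details]") {
    index <- binding_index(registry, header)
    if (!is.null(index) && is.null(lookup_term(index, nt))) {
      findings <- rbind(findings,
        finding(severity, "TERM_UNRESOLVED",
                sprintf("cleavage agent '%s' is not in the bound vocabulary", nt),
                row = row, column = header))
    }
  }
  findings
}

sort_findings <- function(findings) {
  if (!nrow(findings)) return(findings)
  row_key <- ifelse(is.na(findings$row), -1L, findings$row)
  col_key <- ifelse(is.na(findings$column), "", findings$column)
  out <- findings[order(row_key, col_key, findings$code, method = "radix"), ,
                  drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.sdrf_validation_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Render a validation report as text lines
#' @param report An [validate_table()] report.
#' @return Character vector of lines.
#' @export
format_report <- function(report) {
  f <- report$findings
  header <- sprintf("%s: %d error(s), %d warning(s)",
                    if (report$passed) "PASSED" else "FAILED",
                    sum(f$severity == "error"), sum(f$severity == "warning"))
  if (!nrow(f)) return(header)
  loc <- ifelse(is.na(f$row), "", sprintf(" row %d", f$row))
  col <- ifelse(is.na(f$column), "", sprintf(" [%s]", f$column))
  c(header, sprintf("  %-7s %-16s%s%s %s", f$severity, f$code, loc, col,
                    f$message))
}

#' Render a validation report as JSON
#' @param report An [validate_table()] report.
#' @return JSON string with `passed` and a `findings` array.
#' @export
report_json <- function(report) {
  as.character(jsonlite::toJSON(
    list(passed = report$passed, findings = report$findings),
    auto_unbox = TRUE, na = "null", digits = NA))
}
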