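# The SDRF table ---------------------------------------------------------
#
# An sdrf_table is an ordered set of column headers plus a character cell
# matrix (value semantics: every operation returns a new table). Cells may
# not contain tabs or newlines; every row has exactly one cell per column.

MAX_RAW_FILES <- 250L

new_sdrf_table <- function(columns, cells = NULL, provenance = list()) {
  columns <- vapply(columns, function(h) parse_column_header(h)$header,
                    character(1), USE.NAMES = FALSE)
  if (anyDuplicated(columns)) {
    sdrf_abort(sprintf("duplicate column(s): %s",
                       paste(unique(columns[duplicated(columns)]), collapse = ", ")),
               "sdrf_duplicate_column_error")
  }
  if (is.null(cells)) cells <- matrix(character(), nrow = 0L, ncol = length(columns))
  stopifnot(is.matrix(cells), ncol(cells) == length(columns))
  mode(cells) <- "character"
  bad <- grepl("[\t\n\r]", cells)
  if (any(bad)) {
    sdrf_abort("cells may not contain tabs or newlines", "sdrf_cell_error")
  }
  dimnames(cells) <- NULL
  structure(list(columns = columns, cells = cells, provenance = provenance),
            class = "sdrf_table")
}

#' @export
print.sdrf_table <- function(x, ...) {
  cat(sprintf("<sdrf_table: %d column(s) x %d row(s)>\n",
              length(x$columns), nrow(x$cells)))
  cat(paste0("  ", x$columns, collapse = "\n"), "\n")
  invisible(x)
}

#' Number of rows / columns of an SDRF table
#' @param table An `sdrf_table`.
#' @return Integer count.
#' @export
sdrf_nrow <- function(table) nrow(table$cells)

#' @rdname sdrf_nrow
#' @export
sdrf_ncol <- function(table) length(table$columns)

column_index <- function(table, header, required = TRUE) {
  h <- parse_column_header(header)$header
  i <- match(h, table$columns)
  if (is.na(i) && required) {
    sdrf_abort(sprintf("column not present: %s", h), "sdrf_column_error")
  }
  i
}

#' Get one column's cells
#' @param table An `sdrf_table`.
#' @param header Rendered column header.
#' @return Character vector of cells.
#' @export
sdrf_column <- function(table, header) {
  table$cells[, column_index(table, header)]
}

# Species-template registry ---------------------------------------------

registry_file <- function(name) {
  path <- system.file("extdata", "registry", name, package = "sdrfkit")
  if (!nzchar(path)) {
    sdrf_abort(sprintf("registry file missing from installation: %s", name),
               "sdrf_registry_error")
  }
  path
}

#' Species templates of required SDRF columns
#'
#' The shipped registry is a JSON file mapping species keys (`default`,
#' `human`, `vertebrates`, `invertebrates`, `plants`, `cell-lines`) to the
#' ordered list of required column headers; it can be replaced wholesale by
#' pointing `path` at another file of the same shape.
#'
#' @param path Registry JSON (defaults to the shipped file).
#' @return Named list of character vectors (one per species key).
#' @export
species_templates <- function(path = registry_file("templates.json")) {
  reg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lapply(reg, as.character)
}

UNIVERSAL_REQUIRED <- c("source name", "characteristics[organism]",
                        "assay name", "comment[data file]", "technology type")

#' Create an empty SDRF table from a species template
#'
#' @param species_key Template key, matched case-insensitively.
#' @param templates Registry from [species_templates()].
#' @return An `sdrf_table` with the template's columns in canonical order
#'   and zero rows; provenance records the species.
#' @export
create_template <- function(species_key, templates = species_templates()) {
  key <- tolower(trimws(species_key))
  i <- match(key, tolower(names(templates)))
  if (is.na(i)) {
    sdrf_abort(sprintf("unknown species template '%s'; available: %s",
                       species_key, paste(sort(names(templates)), collapse = ", ")),
               "sdrf_template_error")
  }
  cols <- canonical_order(templates[[i]])
  if (!all(UNIVERSAL_REQUIRED %in% cols)) {
    sdrf_abort(sprintf("template '%s' lacks universal required column(s): %s",
                       names(templates)[i],
                       paste(setdiff(UNIVERSAL_REQUIRED, cols), collapse = ", ")),
               "sdrf_registry_error")
  }
  new_sdrf_table(cols, provenance = list(species = names(templates)[i]))
}

# Parsing and serialization ----------------------------------------------

#' Parse a tab-delimited SDRF file
#'
#' Headers are matched case-insensitively; cells are trimmed at both ends;
#' ragged rows are rejected with their line number. SDRF has no quoting
#' dialect: tabs always separate fields.
#'
#' @param text SDRF content as one string, or a character vector of lines.
#' @return An `sdrf_table` (column order as in the file).
#' @export
parse_sdrf <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\r?\n")[[1]] else text
  while (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (!length(lines)) {
    sdrf_abort("empty SDRF input (no header line)", "sdrf_parse_error")
  }
  hdr_tokens <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  columns <- vapply(seq_along(hdr_tokens), function(j) {
    tryCatch(parse_column_header(hdr_tokens[j])$header,
             sdrfkit_error = function(e) {
               sdrf_abort(sprintf("column %d: %s", j, conditionMessage(e)),
                          "sdrf_header_error")
             })
  }, character(1))
  rows <- lapply(seq_along(lines)[-1], function(ln) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    # strsplit drops a trailing empty field when the line ends in a tab
    if (length(f) == length(columns) - 1L && grepl("\t$", lines[ln])) {
      f <- c(f, "")
    }
    if (length(f) != length(columns)) {
      sdrf_abort(sprintf("line %d has %d field(s), expected %d",
                         ln, length(f), length(columns)),
                 "sdrf_row_error")
    }
    trimws(f)
  })
  cells <- if (length(rows)) do.call(rbind, rows)
           else matrix(character(), 0L, length(columns))
  new_sdrf_table(columns, cells)
}

#' Read an SDRF file from disk
#' @param path File path.
#' @return An `sdrf_table`.
#' @export
read_sdrf <- function(path) {
  parse_sdrf(readLines(path, encoding = "UTF-8", warn = FALSE))
}

#' Serialize an SDRF table to tab-delimited text
#'
#' Emits lowercase headers in canonical order, LF line endings and a single
#' trailing newline; cells containing tabs or newlines are refused.
#'
#' @param table An `sdrf_table`.
#' @return A single string.
#' @export
write_sdrf <- function(table) {
  stopifnot(inherits(table, "sdrf_table"))
  ord <- match(canonical_order(table$columns), table$columns)
  cols <- table$columns[ord]
  cells <- table$cells[, ord, drop = FALSE]
  if (any(grepl("[\t\n\r]", cells))) {
    sdrf_abort("cells may not contain tabs or newlines", "sdrf_cell_error")
  }
  body <- apply(cells, 1L, paste, collapse = "\t")
  paste0(paste(c(paste(cols, collapse = "\t"), body), collapse = "\n"), "\n")
}

#' Write an SDRF table to disk
#' @param table An `sdrf_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sdrf_file <- function(table, path) {
  writeLines(sub("\n$", "", write_sdrf(table)), path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# Column and row operations ----------------------------------------------

#' Add a column to an SDRF table
#'
#' The column is inserted at its canonical position and all existing rows
#' receive `default_cell`.
#'
#' @param table An `sdrf_table`.
#' @param header Rendered column header to add.
#' @param default_cell Cell value given to existing rows.
#' @return A new `sdrf_table`.
#' @export
add_column <- function(table, header, default_cell = "not available") {
  h <- parse_column_header(header)$header
  if (h %in% table$columns) {
    sdrf_abort(sprintf("column already present: %s", h),
               "sdrf_duplicate_column_error")
  }
  cols <- canonical_order(c(table$columns, h))
  new_cells <- matrix(default_cell, nrow = nrow(table$cells), ncol = 1L)
  cells <- cbind(table$cells, new_cells)[, match(cols, c(table$columns, h)),
                                         drop = FALSE]
  new_sdrf_table(cols, cells, table$provenance)
}

#' Remove a column from an SDRF table
#' @inheritParams add_column
#' @return A new `sdrf_table` without the column.
#' @export
remove_column <- function(table, header) {
  i <- column_index(table, header)
  new_sdrf_table(table$columns[-i], table$cells[, -i, drop = FALSE],
                 table$provenance)
}

#' Register raw data files on an SDRF table
#'
#' Appends one row per file: `comment[data file]` holds the file name,
#' `source name` is auto-filled `"sample <i>"` and `assay name` `"run <i>"`
#' (1-based over the table); other cells default to `"not available"`.
#' At most 250 distinct files may be registered per table.
#'
#' @param table An `sdrf_table` (a freshly created template, typically).
#' @param filenames Character vector of raw file names (non-empty, unique).
#' @return A new `sdrf_table` with the rows added.
#' @export
set_raw_files <- function(table, filenames) {
  if (!length(filenames)) {
    sdrf_abort("no file names supplied", "sdrf_input_error")
  }
  filenames <- as.character(filenames)
  if (any(!nzchar(trimws(filenames)))) {
    sdrf_abort("file names must be non-empty strings", "sdrf_input_error")
  }
  if (anyDuplicated(filenames)) {
    sdrf_abort(sprintf("duplicate file name(s): %s",
                       paste(unique(filenames[duplicated(filenames)]), collapse = ", ")),
               "sdrf_duplicate_error")
  }
  if (length(filenames) > MAX_RAW_FILES) {
    sdrf_abort(sprintf("%d files exceed the %d-file limit per table",
                       length(filenames), MAX_RAW_FILES),
               "sdrf_file_limit_error")
  }
  if (is.na(column_index(table, "comment[data file]", required = FALSE))) {
    table <- add_column(table, "comment[data file]")
  }
  existing <- sdrf_column(table, "comment[data file]")
  existing <- existing[nzchar(existing) & !is_missing_token(existing)]
  clash <- intersect(filenames, existing)
  if (length(clash)) {
    sdrf_abort(sprintf("file(s) already registered: %s",
                       paste(clash, collapse = ", ")),
               "sdrf_duplicate_error")
  }
  if (length(unique(existing)) + length(filenames) > MAX_RAW_FILES) {
    sdrf_abort(sprintf("table would hold %d distinct files; the limit is %d",
                       length(unique(existing)) + length(filenames), MAX_RAW_FILES),
               "sdrf_file_limit_error")
  }
  n0 <- nrow(table$cells)
  new_rows <- matrix("not available", nrow = length(filenames),
                     ncol = length(table$columns))
  idx <- n0 + seq_along(filenames)
  new_rows[, column_index(table, "source name")] <- sprintf("sample %d", idx)
  assay_i <- column_index(table, "assay name", required = FALSE)
  if (!is.na(assay_i)) new_rows[, assay_i] <- sprintf("run %d", idx)
  new_rows[, column_index(table, "comment[data file]")] <- filenames
  new_sdrf_table(table$columns, rbind(table$cells, new_rows), table$provenance)
}
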