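# Term index and autocomplete search ------------------------------------

#' Build a lookup index over an ontology
#'
#' Maps every non-obsolete label and synonym (case-insensitive,
#' whitespace-normalized) to its CURIE. When two terms share a normalized
#' label the lexicographically smallest CURIE wins and the collision is
#' recorded in `warnings`.
#'
#' @param graph An [ontology_graph()].
#' @return A list of class `sdrf_term_index` with a `entries` data frame
#'   (`key`, `kind`, `id`, `label`) and a `warnings` character vector.
#' @export
build_term_index <- function(graph) {
  ids <- graph_term_ids(graph)
  rows <- lapply(ids, function(id) {
    t <- graph$terms[[id]]
    keys <- c(norm_label(t$label), vapply(t$synonyms, norm_label, character(1)))
    kinds <- c("label", rep("synonym", length(t$synonyms)))
    keep <- nzchar(keys)
    data.frame(key = unname(keys[keep]), kind = kinds[keep],
               id = id, label = t$label, stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, c(rows, list(data.frame(
    key = character(), kind = character(),
    id = character(), label = character(), stringsAsFactors = FALSE))))
  warnings <- character()
  if (nrow(entries)) {
    # deterministic ambiguity resolution: first writer by sorted CURIE
    entries <- entries[order(entries$key, entries$kind, entries$id,
                             method = "radix"), , drop = FALSE]
    dup <- duplicated(entries[, c("key", "kind")])
    if (any(dup)) {
      clash <- entries[dup, , drop = FALSE]
      warnings <- sprintf("ambiguous %s '%s' also maps to %s (kept first CURIE)",
                          clash$kind, clash$key, clash$id)
      entries <- entries[!dup, , drop = FALSE]
    }
    rownames(entries) <- NULL
  }
  structure(list(ontology = graph$name, entries = entries, warnings = warnings),
            class = "sdrf_term_index")
}

#' Resolve a value through a term index
#'
#' Labels take precedence over synonyms when both match.
#'
#' @param index An [build_term_index()] index.
#' @param value String to resolve.
#' @return `NULL` if unresolved, else a list with `id`, `label` (canonical)
#'   and `kind` (`"label"` or `"synonym"`).
#' @export
lookup_term <- function(index, value) {
  key <- norm_label(value)
  e <- index$entries
  hit <- e[e$key == key & e$kind == "label", , drop = FALSE]
  if (!nrow(hit)) hit <- e[e$key == key & e$kind == "synonym", , drop = FALSE]
  if (!nrow(hit)) return(NULL)
  list(id = hit$id[1], label = hit$label[1], kind = hit$kind[1])
}

MATCH_KINDS <- c("label_exact", "label_prefix", "label_substring",
                 "synonym_exact", "synonym_prefix", "synonym_substring")

#' Ranked autocomplete search over an index
#'
#' Match classes, best first: exact label, label prefix, label substring,
#' exact synonym, synonym prefix, synonym substring. Each term is reported
#' once under its best class; ties break by shorter label, then
#' case-insensitive label order. Matching is case-insensitive.
#'
#' @param index An [build_term_index()] index.
#' @param query Non-empty search string.
#' @param limit Maximum number of results (default 10).
#' @return Data frame with columns `label`, `id`, `match_kind`.
#' @export
search_terms <- function(index, query, limit = 10L) {
  q <- norm_label(query)
  if (!nzchar(q)) sdrf_abort("empty search query", "sdrf_query_error")
  if (!is.numeric(limit) || limit < 1) {
    sdrf_abort("limit must be a positive integer", "sdrf_query_error")
  }
  e <- index$entries
  empty <- data.frame(label = character(), id = character(),
                      match_kind = character(), stringsAsFactors = FALSE)
  if (!nrow(e)) return(empty)
  cls <- ifelse(e$key == q, 1L,
         ifelse(startsWith(e$key, q), 2L,
         ifelse(grepl(q, e$key, fixed = TRUE), 3L, NA_integer_)))
  cls <- cls + ifelse(e$kind == "label", 0L, 3L)
  hit <- !is.na(cls)
  if (!any(hit)) return(empty)
  res <- data.frame(id = e$id[hit], label = e$label[hit], rank = cls[hit],
                    stringsAsFactors = FALSE)
  # best class per term id
  res <- res[order(res$rank, method = "radix"), , drop = FALSE]
  res <- res[!duplicated(res$id), , drop = FALSE]
  res <- res[order(res$rank, nchar(res$label), tolower(res$label), res$id,
                   method = "radix"), , drop = FALSE]
  res <- utils::head(res, limit)
  data.frame(label = res$label, id = res$id,
             match_kind = MATCH_KINDS[res$rank],
             stringsAsFactors = FALSE, row.names = NULL)
}

# Protein-modification catalog ------------------------------------------

#' Load a Unimod-style modification catalog from CSV
#'
#' Expects a comma-separated, UTF-8 table whose header names (matched
#' case-insensitively) include a name and an accession column; optional
#' site, position and monoisotopic-mass columns are captured when present.
#' Accessions are normalized to `UNIMOD:<n>`.
#'
#' @param text CSV content as a string, or a path to a CSV file.
#' @return A list of class `sdrf_modification_catalog` with a `records`
#'   data frame (`name`, `accession`, `sites`, `position`, `mono_mass`).
#' @export
load_unimod_csv <- function(text) {
  df <- if (is_string(text) && file.exists(text) && !grepl("\n", text)) {
    utils::read.csv(text, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    utils::read.csv(text = text, stringsAsFactors = FALSE, check.names = FALSE)
  }
  cols <- tolower(trimws(names(df)))
  pick <- function(cands) {
    i <- which(cols %in% cands)
    if (length(i)) df[[i[1]]] else NULL
  }
  name <- pick(c("name", "title", "modification"))
  acc <- pick(c("accession", "record id", "record_id", "unimod accession", "id"))
  if (is.null(name) || is.null(acc)) {
    sdrf_abort("Unimod CSV must have name and accession columns",
               "sdrf_schema_error")
  }
  acc <- trimws(as.character(acc))
  bare <- grepl("^[0-9]+$", acc)
  acc[bare] <- paste0("UNIMOD:", acc[bare])
  pref <- grepl("^unimod:[0-9]+$", tolower(acc))
  acc[pref] <- paste0("UNIMOD:", sub("^[Uu][Nn][Ii][Mm][Oo][Dd]:", "", acc[pref]))
  bad <- !grepl("^UNIMOD:[0-9]+$", acc)
  if (any(bad)) {
    sdrf_abort(sprintf("invalid Unimod accession(s): %s",
                       paste(unique(acc[bad]), collapse = ", ")),
               "sdrf_schema_error")
  }
  if (anyDuplicated(acc)) {
    sdrf_abort(sprintf("duplicate Unimod accession(s): %s",
                       paste(unique(acc[duplicated(acc)]), collapse = ", ")),
               "sdrf_duplicate_error")
  }
  sites <- pick(c("site", "sites", "ta"))
  sites <- if (is.null(sites)) replicate(length(acc), character(), simplify = FALSE)
           else lapply(strsplit(as.character(sites), "[,; ]+"),
                       function(s) s[nzchar(s)])
  position <- pick(c("position", "pp"))
  mono <- pick(c("mono_mass", "monoisotopic mass", "mono mass", "monoisotopic"))
  n <- length(acc)
  records <- data.frame(name = trimws(as.character(name)), accession = acc,
                        position = if (is.null(position)) rep(NA_character_, n)
                                   else as.character(position),
                        mono_mass = if (is.null(mono)) rep(NA_real_, n)
                                    else suppressWarnings(as.numeric(mono)),
                        stringsAsFactors = FALSE)
  records$sites <- sites
  structure(list(records = records), class = "sdrf_modification_catalog")
}

# Look a modification up by name (case-insensitive) or UNIMOD accession.
lookup_modification <- function(catalog, name = NULL, accession = NULL) {
  r <- catalog$records
  if (!is.null(accession) && !is.na(accession)) {
    acc <- trimws(accession)
    if (grepl("^[0-9]+$", acc)) acc <- paste0("UNIMOD:", acc)
    i <- which(toupper(r$accession) == toupper(acc))
    if (length(i)) return(r[i[1], , drop = FALSE])
  }
  if (!is.null(name)) {
    i <- which(norm_label(r$name) == norm_label(name))
    if (length(i)) return(r[i[1], , drop = FALSE])
  }
  NULL
}
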