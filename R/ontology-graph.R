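# Controlled-vocabulary graphs ------------------------------------------
#
# An ontology is held as a DAG of terms: each term has a CURIE id, a label,
# optional synonyms, is_a parent links, and an obsolete flag. Construction
# validates id uniqueness, dangling parents and acyclicity; obsolete terms
# stay in the graph but are excluded from every derived artifact.

#' Construct an ontology term record
#'
#' @param id CURIE string (`prefix:local`, e.g. `"NCBITaxon:9606"`).
#' @param label Non-empty human-readable name.
#' @param synonyms Character vector of synonyms (may be empty).
#' @param parents Character vector of parent CURIEs (`is_a` targets).
#' @param definition Optional definition string.
#' @param obsolete Logical; obsolete terms are never offered for annotation.
#' @return A list of class `ontology_term`.
#' @export
ontology_term <- function(id, label, synonyms = character(),
                          parents = character(), definition = NULL,
                          obsolete = FALSE) {
  if (!is_string(id) || !grepl("^[^:[:space:]]+:[^:[:space:]]+$", id)) {
    sdrf_abort(sprintf("invalid CURIE id: %s", deparse(id)), "sdrf_curie_error")
  }
  if (!is_string(label) || !nzchar(trimws(label))) {
    sdrf_abort(sprintf("term %s has an empty label", id), "sdrf_term_error")
  }
  structure(
    list(id = id, label = label,
         synonyms = as.character(synonyms),
         parents = as.character(parents),
         definition = definition,
         obsolete = isTRUE(obsolete)),
    class = "ontology_term"
  )
}

#' Construct an ontology graph from term records
#'
#' Validates that ids are unique, every parent link points at a term in the
#' graph, and the `is_a` relation is acyclic. Roots are the non-obsolete
#' terms with no parents.
#'
#' @param terms List of [ontology_term()] records.
#' @param name Ontology key (e.g. `"psi-ms"`).
#' @param version Version string.
#' @return A list of class `ontology_graph` with fields `name`, `version`,
#'   `terms` (named by id) and `roots`.
#' @export
ontology_graph <- function(terms, name = "ontology", version = "0") {
  ids <- vapply(terms, function(t) t$id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    sdrf_abort(sprintf("duplicate term id(s): %s",
                       paste(unique(dup), collapse = ", ")),
               "sdrf_duplicate_id_error")
  }
  names(terms) <- ids
  for (t in terms) {
    missing <- setdiff(t$parents, ids)
    if (length(missing)) {
      sdrf_abort(sprintf("term %s has dangling parent(s): %s",
                         t$id, paste(missing, collapse = ", ")),
                 "sdrf_dangling_parent_error")
    }
  }
  check_acyclic(terms)
  obsolete <- vapply(terms, function(t) t$obsolete, logical(1))
  n_par <- vapply(terms, function(t) length(t$parents), integer(1))
  roots <- ids[!obsolete & n_par == 0L]
  structure(
    list(name = name, version = version, terms = terms,
         roots = unname(roots)),
    class = "ontology_graph"
  )
}

# Cycle detection over is_a links via igraph; reports one cycle on failure.
check_acyclic <- function(terms) {
  edges <- do.call(rbind, lapply(terms, function(t) {
    if (length(t$parents)) cbind(t$id, t$parents) else NULL
  }))
  if (is.null(edges) || nrow(edges) == 0L) return(invisible(TRUE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]),
    directed = TRUE,
    vertices = data.frame(name = names(terms))
  )
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    bad <- which(comp$csize > 1L)[1]
    cyc <- names(comp$membership)[comp$membership == bad]
    sdrf_abort(sprintf("cyclic is_a chain involving: %s",
                       paste(sort(cyc), collapse = " -> ")),
               "sdrf_cycle_error")
  }
  invisible(TRUE)
}

#' @export
print.ontology_graph <- function(x, ...) {
  n_obs <- sum(vapply(x$terms, function(t) t$obsolete, logical(1)))
  cat(sprintf("<ontology_graph '%s' v%s: %d terms (%d obsolete), %d roots>\n",
              x$name, x$version, length(x$terms), n_obs, length(x$roots)))
  invisible(x)
}

graph_term_ids <- function(graph, include_obsolete = FALSE) {
  ids <- names(graph$terms)
  if (include_obsolete) return(ids)
  ids[!vapply(graph$terms, function(t) t$obsolete, logical(1))]
}

#' Parse an OBO-format controlled vocabulary
#'
#' Handles `[Term]` stanzas with `id`, `name`, `is_a`, `synonym`, `def` and
#' `is_obsolete` tags (OBO 1.2/1.4 flat file). Other stanza types
#' (`[Typedef]` etc.) are skipped. Stanza order is irrelevant to the result.
#'
#' @param text OBO file content as a single string, or a character vector of
#'   lines.
#' @param name,version Ontology key and version recorded on the graph;
#'   `name`/`version` default to the `ontology:`/`data-version:` header tags
#'   when present.
#' @return An [ontology_graph()].
#' @export
parse_obo <- function(text, name = NULL, version = NULL) {
  lines <- if (length(text) == 1L) strsplit(text, "\r?\n")[[1]] else text
  hdr_name <- hdr_version <- NULL
  stanzas <- list()
  current <- NULL        # NULL outside stanzas; list of lines inside [Term]
  in_term <- FALSE
  flush <- function() {
    if (in_term && length(current)) stanzas[[length(stanzas) + 1L]] <<- current
    current <<- NULL
  }
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (grepl("^\\[", ln)) {
      flush()
      in_term <- identical(ln, "[Term]")
      current <- character()
      next
    }
    if (!nzchar(ln)) next
    if (is.null(current)) {            # header block
      if (grepl("^ontology:", ln)) hdr_name <- trimws(sub("^ontology:", "", ln))
      if (grepl("^data-version:", ln)) hdr_version <- trimws(sub("^data-version:", "", ln))
      next
    }
    if (in_term) current <- c(current, ln)
  }
  flush()

  terms <- lapply(seq_along(stanzas), function(i) parse_term_stanza(stanzas[[i]], i))
  ontology_graph(terms,
                 name = name %||% hdr_name %||% "ontology",
                 version = version %||% hdr_version %||% "0")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_term_stanza <- function(stanza, ordinal) {
  tag_val <- function(tag) {
    hits <- grep(paste0("^", tag, ":"), stanza, value = TRUE)
    trimws(sub(paste0("^", tag, ":"), "", hits))
  }
  id <- tag_val("id")
  nm <- tag_val("name")
  if (length(id) != 1L || !nzchar(id) || length(nm) != 1L || !nzchar(nm)) {
    sdrf_abort(sprintf("malformed [Term] stanza %d: missing id or name", ordinal),
               "sdrf_obo_parse_error")
  }
  # is_a lines may carry a trailing "! label" comment
  parents <- trimws(sub("!.*$", "", tag_val("is_a")))
  parents <- parents[nzchar(parents)]
  # synonym: "text" SCOPE [] -- keep the quoted portion
  syn_lines <- tag_val("synonym")
  synonyms <- regmatches(syn_lines, regexpr('"[^"]*"', syn_lines))
  synonyms <- gsub('"', "", synonyms)
  def_line <- tag_val("def")
  definition <- if (length(def_line)) {
    d <- regmatches(def_line[1], regexpr('"[^"]*"', def_line[1]))
    if (length(d)) gsub('"', "", d) else NULL
  } else NULL
  obsolete <- any(tolower(tag_val("is_obsolete")) == "true")
  ontology_term(id, nm, synonyms = synonyms, parents = parents,
                definition = definition, obsolete = obsolete)
}

#' Import an ontology from a flat term-list JSON
#'
#' Generic importer for vocabularies available as a JSON array of
#' `{id, label, parents?, synonyms?, obsolete?, definition?}` records;
#' produces a graph equivalent to [parse_obo()] on the same content.
#'
#' @param text JSON string.
#' @param name,version Recorded on the graph.
#' @return An [ontology_graph()].
#' @export
import_term_list_json <- function(text, name = "ontology", version = "0") {
  recs <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                   error = function(e) {
                     sdrf_abort(paste("invalid JSON:", conditionMessage(e)),
                                "sdrf_import_error")
                   })
  if (!is.list(recs) || (length(recs) && !is.null(names(recs)))) {
    sdrf_abort("term-list JSON must be an array of records", "sdrf_import_error")
  }
  terms <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    if (!is.list(r) || is.null(r$id) || is.null(r$label)) {
      sdrf_abort(sprintf("term-list record %d is missing id or label", i),
                 "sdrf_import_error")
    }
    ontology_term(r$id, r$label,
                  synonyms = unlist(r$synonyms) %||% character(),
                  parents = unlist(r$parents) %||% character(),
                  definition = r$definition %||% NULL,
                  obsolete = isTRUE(r$obsolete))
  })
  ontology_graph(terms, name = name, version = version)
}

#' Export an ontology graph to the flat term-list JSON shape
#'
#' Inverse of [import_term_list_json()]: the round trip is graph equality.
#'
#' @param graph An [ontology_graph()].
#' @return JSON string.
#' @export
export_term_list_json <- function(graph) {
  recs <- lapply(graph$terms[order(names(graph$terms))], function(t) {
    list(id = jsonlite::unbox(t$id),
         label = jsonlite::unbox(t$label),
         parents = as.list(t$parents),
         synonyms = as.list(t$synonyms),
         obsolete = jsonlite::unbox(t$obsolete))
  })
  as.character(jsonlite::toJSON(unname(recs), auto_unbox = FALSE, digits = NA))
}

#' Transitive ancestors of a term
#'
#' @param graph An [ontology_graph()].
#' @param id CURIE present in the graph.
#' @return Character vector of ancestor CURIEs (excluding `id` itself).
#' @export
ancestors <- function(graph, id) {
  if (!id %in% names(graph$terms)) {
    sdrf_abort(sprintf("unknown term id: %s", id), "sdrf_lookup_error")
  }
  seen <- character()
  frontier <- graph$terms[[id]]$parents
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(lapply(new, function(p) graph$terms[[p]]$parents)))
  }
  sort(unique(seen))
}

# Structural graph equality (ignores term ordering).
graph_equal <- function(a, b) {
  if (!setequal(names(a$terms), names(b$terms))) return(FALSE)
  for (id in names(a$terms)) {
    ta <- a$terms[[id]]; tb <- b$terms[[id]]
    if (!identical(ta$label, tb$label)) return(FALSE)
    if (!setequal(ta$parents, tb$parents)) return(FALSE)
    if (!setequal(ta$synonyms, tb$synonyms)) return(FALSE)
    if (!identical(ta$obsolete, tb$obsolete)) return(FALSE)
  }
  TRUE
}
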