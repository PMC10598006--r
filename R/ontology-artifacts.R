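# Derived ontology artifacts --------------------------------------------
#
# Each vocabulary is rendered into three persisted shapes: a flat element
# list (autocomplete source), a nested label dictionary mirroring the
# ontology tree, and a nodes tree carrying CURIEs for tree-select widgets.
# All three exclude obsolete terms and are written as gzipped JSON.

#' Flat element list of an ontology
#'
#' Labels of all non-obsolete terms, sorted case-insensitively. Duplicate
#' labels (distinct terms sharing a label) are preserved.
#'
#' @param graph An [ontology_graph()].
#' @return A list of class `sdrf_element_list` with `ontology` and `elements`.
#' @export
build_element_list <- function(graph) {
  labels <- vapply(graph$terms[graph_term_ids(graph)],
                   function(t) t$label, character(1))
  labels <- unname(labels)
  labels <- labels[order(tolower(labels), labels, method = "radix")]
  structure(list(ontology = graph$name, elements = labels),
            class = "sdrf_element_list")
}

# children ids of each non-obsolete term, ordered case-insensitively by label
child_map <- function(graph) {
  ids <- graph_term_ids(graph)
  kids <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    for (p in graph$terms[[id]]$parents) {
      if (p %in% ids) kids[[p]] <- c(kids[[p]], id)
    }
  }
  lab <- function(i) graph$terms[[i]]$label
  lapply(kids, function(ch) {
    if (is.null(ch)) return(character())
    labs <- vapply(ch, lab, character(1))
    ch[order(tolower(labs), labs, method = "radix")]
  })
}

empty_node <- function() stats::setNames(list(), character())

#' Nested label dictionary of an ontology
#'
#' A recursive map from term label to the map of its children's labels
#' (leaves are empty maps). Terms with several parents appear once under
#' each parent. Recursion is truncated at `max_depth` to guard pathological
#' inputs.
#'
#' @param graph An [ontology_graph()].
#' @param max_depth Maximum tree depth rendered (default 50).
#' @return A list of class `sdrf_nested_tree` with `ontology` and `tree`.
#' @export
build_nested_tree <- function(graph, max_depth = 50L) {
  kids <- child_map(graph)
  rec <- function(id, depth) {
    if (depth >= max_depth) return(empty_node())
    ch <- kids[[id]]
    if (!length(ch)) return(empty_node())
    stats::setNames(lapply(ch, rec, depth = depth + 1L),
                    vapply(ch, function(i) graph$terms[[i]]$label, character(1)))
  }
  roots <- graph$roots
  labs <- vapply(roots, function(i) graph$terms[[i]]$label, character(1))
  ord <- order(tolower(labs), labs, method = "radix")
  tree <- stats::setNames(lapply(roots[ord], rec, depth = 1L), labs[ord])
  structure(list(ontology = graph$name, tree = tree),
            class = "sdrf_nested_tree")
}

#' Select-widget nodes tree of an ontology
#'
#' Same structure as [build_nested_tree()] but each node is a record
#' `{label, value = CURIE, children}` suitable for tree-select components.
#'
#' @inheritParams build_nested_tree
#' @return A list of class `sdrf_select_nodes` with `ontology` and `nodes`.
#' @export
build_select_nodes <- function(graph, max_depth = 50L) {
  kids <- child_map(graph)
  rec <- function(id, depth) {
    ch <- if (depth >= max_depth) character() else kids[[id]]
    list(label = graph$terms[[id]]$label,
         value = id,
         children = lapply(ch, rec, depth = depth + 1L))
  }
  roots <- graph$roots
  labs <- vapply(roots, function(i) graph$terms[[i]]$label, character(1))
  ord <- order(tolower(labs), labs, method = "radix")
  structure(list(ontology = graph$name,
                 nodes = lapply(roots[ord], rec, depth = 1L)),
            class = "sdrf_select_nodes")
}

# Preorder label sequences; used to check structural agreement between the
# two tree artifacts.
nested_tree_preorder <- function(tree) {
  walk <- function(node) {
    out <- character()
    for (nm in names(node)) out <- c(out, nm, walk(node[[nm]]))
    out
  }
  walk(tree$tree)
}

select_nodes_preorder <- function(nodes) {
  walk <- function(ns) {
    out <- character()
    for (n in ns) out <- c(out, n$label, walk(n$children))
    out
  }
  walk(nodes$nodes)
}

# Gzipped-JSON persistence ----------------------------------------------

artifact_to_json <- function(x) {
  payload <- switch(class(x)[1],
    sdrf_element_list = list(
      type = jsonlite::unbox("element_list"),
      ontology = jsonlite::unbox(x$ontology),
      elements = as.list(x$elements)),
    sdrf_nested_tree = list(
      type = jsonlite::unbox("nested_tree"),
      ontology = jsonlite::unbox(x$ontology),
      tree = x$tree),
    sdrf_select_nodes = list(
      type = jsonlite::unbox("select_nodes"),
      ontology = jsonlite::unbox(x$ontology),
      nodes = nodes_to_json(x$nodes)),
    sdrf_abort(sprintf("not a persistable artifact: %s", class(x)[1]),
               "sdrf_artifact_error")
  )
  as.character(jsonlite::toJSON(payload, auto_unbox = FALSE, digits = NA))
}

nodes_to_json <- function(nodes) {
  lapply(nodes, function(n) {
    list(label = jsonlite::unbox(n$label),
         value = jsonlite::unbox(n$value),
         children = nodes_to_json(n$children))
  })
}

#' Write an artifact as gzipped JSON
#'
#' @param x An element list, nested tree or select-nodes artifact.
#' @param path Output file path (conventionally ending `.json.gz`).
#' @return `path`, invisibly.
#' @export
write_artifact <- function(x, path) {
  write_gzip_text(artifact_to_json(x), path)
  invisible(path)
}

# gzfile writes a fixed (zero-mtime) gzip header, so identical content
# yields byte-identical files.
write_gzip_text <- function(text, path) {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(text)), con)
  invisible(path)
}

#' Read a gzipped-JSON artifact
#'
#' @param path File written by [write_artifact()].
#' @return The artifact, structurally equal to what was written.
#' @export
read_artifact <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 2L || raw[1] != as.raw(0x1f) || raw[2] != as.raw(0x8b)) {
    sdrf_abort(sprintf("%s is not a gzip file (magic bytes missing)", path),
               "sdrf_format_error")
  }
  json <- tryCatch(rawToChar(memDecompress(raw, type = "gzip")),
                   error = function(e) {
                     sdrf_abort(sprintf("truncated or corrupt gzip stream in %s", path),
                                "sdrf_integrity_error")
                   })
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  switch(obj$type %||% "",
    element_list = structure(
      list(ontology = obj$ontology,
           elements = as.character(unlist(obj$elements))),
      class = "sdrf_element_list"),
    nested_tree = structure(
      list(ontology = obj$ontology, tree = canonicalize_tree(obj$tree)),
      class = "sdrf_nested_tree"),
    select_nodes = structure(
      list(ontology = obj$ontology, nodes = canonicalize_nodes(obj$nodes)),
      class = "sdrf_select_nodes"),
    sdrf_abort(sprintf("unrecognized artifact type in %s", path),
               "sdrf_artifact_error")
  )
}

# fromJSON renders {} as an unnamed empty list; restore the named-empty-map
# convention so round trips are identical().
canonicalize_tree <- function(tree) {
  if (!length(tree)) return(empty_node())
  stats::setNames(lapply(tree, canonicalize_tree), names(tree))
}

canonicalize_nodes <- function(nodes) {
  lapply(nodes, function(n) {
    list(label = n$label, value = n$value,
         children = canonicalize_nodes(n$children))
  })
}

#' Write the standard artifact set for one ontology
#'
#' Emits `<name>_all_elements.json.gz`, `<name>_tree.json.gz`,
#' `<name>_nodes.json.gz` and `<name>_terms.json.gz` (the flat term-list
#' export, kept so indexes can be rebuilt without the source file).
#'
#' @param graph An [ontology_graph()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four paths, invisibly.
#' @export
export_ontology_artifacts <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    elements = file.path(dir, paste0(graph$name, "_all_elements.json.gz")),
    tree     = file.path(dir, paste0(graph$name, "_tree.json.gz")),
    nodes    = file.path(dir, paste0(graph$name, "_nodes.json.gz")),
    terms    = file.path(dir, paste0(graph$name, "_terms.json.gz"))
  )
  write_artifact(build_element_list(graph), paths[["elements"]])
  write_artifact(build_nested_tree(graph), paths[["tree"]])
  write_artifact(build_select_nodes(graph), paths[["nodes"]])
  write_gzip_text(export_term_list_json(graph), paths[["terms"]])
  invisible(paths)
}

#' Read back a `<name>_terms.json.gz` term-list export
#'
#' @param path Path written by [export_ontology_artifacts()].
#' @param name Ontology key for the rebuilt graph.
#' @return An [ontology_graph()].
#' @export
read_term_list_gz <- function(path, name = "ontology") {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 2L || raw[1] != as.raw(0x1f) || raw[2] != as.raw(0x8b)) {
    sdrf_abort(sprintf("%s is not a gzip file", path), "sdrf_format_error")
  }
  import_term_list_json(rawToChar(memDecompress(raw, type = "gzip")), name = name)
}
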