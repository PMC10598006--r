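# Fixture generators and worked-example arithmetic -----------------------
#
# Deterministic toy vocabularies and metadata tables stand in for real
# ontology releases in tests and demos: same formats, desk scale. Every
# generator is a pure function of its arguments (RNG state is saved and
# restored).

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  code
}

# Fixed mini-taxonomy present in every generated ontology so cross-module
# examples resolve stably.
FIXED_TAXA <- list(
  list(id = "NCBITaxon:1", name = "organism", parents = character(),
       synonyms = character()),
  list(id = "NCBITaxon:9606", name = "Homo sapiens", parents = "NCBITaxon:1",
       synonyms = "human"),
  list(id = "NCBITaxon:63221", name = "Homo sapiens neanderthalensis",
       parents = "NCBITaxon:9606", synonyms = character())
)

#' Generate a deterministic toy ontology in OBO format
#'
#' Produces `n_terms` `[Term]` stanzas: a fixed mini-taxonomy (root
#' `organism`; `Homo sapiens` with synonym `human`; a subspecies) followed
#' by randomly parented terms forming a DAG no deeper than `depth`, with
#' occasional second parents so multi-parent handling is exercised. About
#' `synonym_rate` of the random terms get a synonym and about
#' `obsolete_rate` are marked obsolete (only childless terms, so the live
#' tree stays fully reachable). Identical arguments give byte-identical
#' output.
#'
#' @param n_terms Total number of term stanzas (>= 1).
#' @param depth Maximum DAG depth of the random part.
#' @param seed RNG seed.
#' @param synonym_rate,obsolete_rate Fractions in `[0, 1]`.
#' @return OBO text as a single string.
#' @export
generate_toy_ontology <- function(n_terms = 50L, depth = 4L, seed = 1L,
                                  synonym_rate = 0.2, obsolete_rate = 0.05) {
  if (n_terms < 1L) sdrf_abort("n_terms must be >= 1", "sdrf_fixture_error")
  if (depth < 1L || depth > n_terms) {
    sdrf_abort(sprintf("depth %d incompatible with %d term(s)", depth, n_terms),
               "sdrf_fixture_error")
  }
  fixed <- FIXED_TAXA[seq_len(min(3L, n_terms))]
  n_rand <- n_terms - length(fixed)
  rand <- with_seed(seed, {
    out <- vector("list", n_rand)
    levels <- integer(n_rand)
    words <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "theta",
               "kappa", "lambda", "sigma")
    for (i in seq_len(n_rand)) {
      id <- sprintf("TOY:%04d", i)
      label <- sprintf("term %03d %s", i, words[(i - 1L) %% length(words) + 1L])
      chain <- min(depth, n_rand)
      if (i == 1L) {
        parents <- character(); levels[i] <- 1L
      } else if (i <= chain) {
        # a guaranteed chain realizes the requested depth
        parents <- sprintf("TOY:%04d", i - 1L); levels[i] <- i
      } else {
        eligible <- which(levels[seq_len(i - 1L)] < depth)
        p <- eligible[sample.int(length(eligible), 1L)]
        parents <- sprintf("TOY:%04d", p)
        levels[i] <- levels[p] + 1L
        extra <- setdiff(eligible, p)
        if (length(extra) && stats::runif(1) < 0.10) {
          q <- extra[sample.int(length(extra), 1L)]
          parents <- c(parents, sprintf("TOY:%04d", q))
          levels[i] <- max(levels[i], levels[q] + 1L)
        }
      }
      synonyms <- if (stats::runif(1) < synonym_rate) paste("alias", label)
                  else character()
      out[[i]] <- list(id = id, name = label, parents = parents,
                       synonyms = synonyms, obsolete = FALSE)
    }
    if (obsolete_rate > 0 && n_rand > 0L) {
      used_as_parent <- unique(unlist(lapply(out, `[[`, "parents")))
      leaves <- which(!sprintf("TOY:%04d", seq_len(n_rand)) %in% used_as_parent)
      flags <- stats::runif(n_rand) < obsolete_rate
      for (i in intersect(which(flags), leaves)) out[[i]]$obsolete <- TRUE
    }
    out
  })
  stanza <- function(t) {
    lines <- c("[Term]", paste0("id: ", t$id), paste0("name: ", t$name))
    for (p in t$parents) lines <- c(lines, paste0("is_a: ", p))
    for (s in t$synonyms) {
      lines <- c(lines, sprintf("synonym: \"%s\" EXACT []", s))
    }
    if (isTRUE(t$obsolete)) lines <- c(lines, "is_obsolete: true")
    paste(lines, collapse = "\n")
  }
  paste0("format-version: 1.2\nontology: toy\n\n",
         paste(vapply(c(fixed, rand), stanza, character(1)), collapse = "\n\n"),
         "\n")
}

#' Generate a deterministic toy local-metadata table
#'
#' Tab-delimited text with header `file, organism, organism part,
#' instrument, disease` and `n_samples` rows. Organism values mix the
#' canonical spelling and its synonym; when `n_samples >= 5` exactly one
#' unresolvable organism value (`"unobtainium"`) is planted so mapping
#' reports have a known shape.
#'
#' @param n_samples Number of sample rows (>= 1).
#' @param seed RNG seed.
#' @return TSV content as a single string.
#' @export
generate_toy_metadata <- function(n_samples, seed = 1L) {
  if (n_samples < 1L) sdrf_abort("n_samples must be >= 1", "sdrf_fixture_error")
  parts <- c("liver", "kidney", "plasma", "brain")
  instruments <- c("Orbitrap Fusion Lumos", "Q Exactive HF")
  diseases <- c("normal", "hepatocellular carcinoma")
  rows <- with_seed(seed, {
    vapply(seq_len(n_samples), function(i) {
      organism <- if (n_samples >= 5L && i == 5L) "unobtainium"
                  else if (i %% 2L == 0L) "human" else "Homo sapiens"
      paste(sprintf("file_%02d.raw", i), organism,
            parts[sample.int(length(parts), 1L)],
            instruments[sample.int(length(instruments), 1L)],
            diseases[sample.int(length(diseases), 1L)],
            sep = "\t")
    }, character(1))
  })
  paste0(paste(c("file\torganism\torganism part\tinstrument\tdisease", rows),
               collapse = "\n"), "\n")
}

#' Annotation-adoption percentage
#'
#' Share of repository datasets carrying structured sample metadata, on the
#' 0-100 scale, rounded half-up to one decimal.
#'
#' @param n_annotated Annotated dataset count (>= 0).
#' @param n_total Total dataset count (> 0, >= `n_annotated`).
#' @return A list of class `sdrf_adoption_stats`: `n_annotated`, `n_total`,
#'   `percent`.
#' @export
adoption_percentage <- function(n_annotated, n_total) {
  if (n_total <= 0L || n_annotated < 0L || n_annotated > n_total) {
    sdrf_abort("need 0 <= n_annotated <= n_total with n_total > 0",
               "sdrf_domain_error")
  }
  percent <- floor(1000 * n_annotated / n_total + 0.5) / 10
  structure(list(n_annotated = as.integer(n_annotated),
                 n_total = as.integer(n_total), percent = percent),
            class = "sdrf_adoption_stats")
}

#' Dataset-selection funnel
#'
#' Sequentially removes labelled exclusion counts from a starting dataset
#' count, tracing every step; any step that would drive the running total
#' negative is an error.
#'
#' @param n_start Starting count.
#' @param exclusions List of `(label, count)` pairs (list of 2-element
#'   lists, or a named numeric vector).
#' @return A list of class `sdrf_funnel`: `remaining` and a `trace` data
#'   frame (`step`, `removed`, `remaining`).
#' @export
project_funnel <- function(n_start, exclusions = list()) {
  if (!is.numeric(n_start) || n_start < 0L) {
    sdrf_abort("n_start must be non-negative", "sdrf_funnel_error")
  }
  if (is.numeric(exclusions) && !is.null(names(exclusions))) {
    exclusions <- mapply(function(l, c) list(l, c), names(exclusions),
                         exclusions, SIMPLIFY = FALSE)
  }
  remaining <- as.integer(n_start)
  trace <- data.frame(step = "start", removed = 0L, remaining = remaining,
                      stringsAsFactors = FALSE)
  for (ex in exclusions) {
    label <- as.character(ex[[1]]); count <- as.integer(ex[[2]])
    if (count < 0L) {
      sdrf_abort(sprintf("negative exclusion count at step '%s'", label),
                 "sdrf_funnel_error")
    }
    if (remaining - count < 0L) {
      sdrf_abort(sprintf("step '%s' removes %d but only %d remain",
                         label, count, remaining),
                 "sdrf_funnel_error")
    }
    remaining <- remaining - count
    trace <- rbind(trace, data.frame(step = label, removed = count,
                                     remaining = remaining,
                                     stringsAsFactors = FALSE))
  }
  structure(list(remaining = remaining, trace = trace), class = "sdrf_funnel")
}
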