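# SDRF column taxonomy ---------------------------------------------------
#
# Six column categories; headers render lowercase as "source name",
# "characteristics[<attr>]", "assay name", "comment[<attr>]",
# "factor value[<attr>]", "technology type".

COLUMN_CATEGORIES <- c(source_name = 1L, characteristics = 2L,
                       technology_type = 3L, assay_name = 4L,
                       comment = 5L, factor_value = 6L)

BARE_HEADERS <- c("source name" = "source_name",
                  "assay name" = "assay_name",
                  "technology type" = "technology_type")

ATTR_CATEGORIES <- c("characteristics" = "characteristics",
                     "comment" = "comment",
                     "factor value" = "factor_value")

#' Render an SDRF column header
#'
#' @param category One of `source_name`, `characteristics`, `assay_name`,
#'   `comment`, `factor_value`, `technology_type`.
#' @param attribute Bracketed attribute; required for characteristics /
#'   comment / factor value, forbidden otherwise.
#' @return Lowercase rendered header string.
#' @export
column_header <- function(category, attribute = "") {
  category <- match.arg(category, names(COLUMN_CATEGORIES))
  attribute <- trimws(attribute)
  needs_attr <- category %in% ATTR_CATEGORIES
  if (needs_attr && !nzchar(attribute)) {
    sdrf_abort(sprintf("%s columns need a non-empty attribute", category),
               "sdrf_column_error")
  }
  if (!needs_attr && nzchar(attribute)) {
    sdrf_abort(sprintf("%s columns take no attribute", category),
               "sdrf_column_error")
  }
  if (!needs_attr) return(names(BARE_HEADERS)[BARE_HEADERS == category])
  sprintf("%s[%s]", names(ATTR_CATEGORIES)[ATTR_CATEGORIES == category],
          tolower(attribute))
}

#' Parse an SDRF column header
#'
#' Case-insensitive; surrounding whitespace ignored.
#'
#' @param header Header token from an SDRF file.
#' @return List with `category`, `attribute` and the canonical lowercase
#'   `header`, or an error for unrecognizable tokens.
#' @export
parse_column_header <- function(header) {
  h <- tolower(gsub("[[:space:]]+", " ", trimws(header)))
  if (h %in% names(BARE_HEADERS)) {
    return(list(category = unname(BARE_HEADERS[h]), attribute = "", header = h))
  }
  m <- regmatches(h, regexec("^(characteristics|comment|factor value) ?\\[(.+)\\]$", h))[[1]]
  if (length(m) == 3L && nzchar(trimws(m[3]))) {
    cat <- unname(ATTR_CATEGORIES[m[2]])
    attr <- trimws(m[3])
    return(list(category = cat, attribute = attr,
                header = sprintf("%s[%s]", m[2], attr)))
  }
  sdrf_abort(sprintf("unrecognizable SDRF column header: %s", deparse(header)),
             "sdrf_header_error")
}

column_category <- function(header) parse_column_header(header)$category

column_attribute <- function(header) parse_column_header(header)$attribute

#' Canonical SDRF column order
#'
#' Source name first, then characteristics (stable by insertion order),
#' technology type, assay name, comment columns, and factor value columns
#' last. Idempotent; a permutation of its input.
#'
#' @param headers Character vector of rendered headers.
#' @return Reordered character vector.
#' @export
canonical_order <- function(headers) {
  if (!length(headers)) return(character())
  rank <- vapply(headers, function(h) COLUMN_CATEGORIES[[column_category(h)]],
                 integer(1))
  headers[order(rank, seq_along(headers), method = "radix")]
}
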