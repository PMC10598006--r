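#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the CLI) can distinguish failure kinds
# without string-matching messages.
sdrf_abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "sdrfkit_error")))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Normalization used for all case-insensitive term/label matching:
# trim, collapse internal whitespace, lowercase.
norm_label <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(x)))
}

# Tokens that stand for a legitimately unknown / void value in SDRF cells.
MISSING_TOKENS <- c("not available", "not applicable")

is_missing_token <- function(x) norm_label(x) %in% MISSING_TOKENS
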