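#' @keywords internal
"_PACKAGE"

# Shared helpers: term normalization, SCTID checks, deterministic ordering.

#' Normalize a term for dictionary comparison
#'
#' Case-folds, collapses internal whitespace runs to a single space, and
#' strips leading/trailing whitespace. No stemming is applied.
#'
#' @param x character vector of terms.
#' @return character vector of normalized terms.
#' @export
#' @examples
#' normalize_term("  Non-small   CELL lung cancer ")
normalize_term <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

is_sctid <- function(x) {
  is.character(x) & nzchar(x) & grepl("^[0-9]+$", x)
}

# Numeric-string ascending order for SCTIDs (identifiers can exceed the
# exact-integer range of doubles, so order by width then lexicographically).
sctid_order <- function(ids) {
  order(nchar(ids), ids)
}

sort_sctid <- function(ids) {
  ids[sctid_order(ids)]
}

stop_lookup <- function(id) {
  stop(sprintf("unknown concept id: %s", id), call. = FALSE)
}

# Half-open interval overlap on [start, end)
spans_overlap <- function(s1, e1, s2, e2) {
  s1 < e2 & s2 < e1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
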