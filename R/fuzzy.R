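# Greedy longest-common-substring similarity matching, used to recover
# concept mentions whose spelling deviates slightly from a terminology
# description (e.g. "nonsmall cell lung cancer" vs the description
# "non-small cell lung cancer").

#' Fuzzy matching configuration
#'
#' @param threshold_percent inclusion threshold as a percentage; a phrase is
#'   accepted when its similarity to a description is at least this value.
#'   The default of 95 corresponds to tolerating a 5% character error margin.
#' @param case_fold compare case-insensitively (default `TRUE`).
#' @return an object of class `fuzzy_config`.
#' @export
fuzzy_config <- function(threshold_percent = 95, case_fold = TRUE) {
  stopifnot(is.numeric(threshold_percent), length(threshold_percent) == 1,
            threshold_percent > 0, threshold_percent <= 100,
            is.logical(case_fold), length(case_fold) == 1)
  structure(list(threshold_percent = threshold_percent, case_fold = case_fold),
            class = "fuzzy_config")
}

# First longest common run of identical characters between two integer
# vectors (code points). Ties break to the earliest start in `x`, then the
# earliest start in `y`: only strictly longer runs displace the incumbent.
longest_common_run <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  best <- 0L
  bi <- 0L
  bj <- 0L
  i <- 1L
  while (i <= nx) {
    if (nx - i + 1L <= best) break
    j <- 1L
    while (j <= ny) {
      if (ny - j + 1L <= best) break
      k <- 0L
      while (i + k <= nx && j + k <= ny && x[i + k] == y[j + k]) k <- k + 1L
      if (k > best) {
        best <- k
        bi <- i
        bj <- j
      }
      j <- j + 1L
    }
    i <- i + 1L
  }
  list(len = best, i = bi, j = bj)
}

match_count_int <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) return(0L)
  m <- longest_common_run(x, y)
  if (m$len == 0L) return(0L)
  xr <- if (m$i + m$len <= length(x)) x[(m$i + m$len):length(x)] else integer(0)
  yr <- if (m$j + m$len <= length(y)) y[(m$j + m$len):length(y)] else integer(0)
  m$len +
    match_count_int(x[seq_len(m$i - 1L)], y[seq_len(m$j - 1L)]) +
    match_count_int(xr, yr)
}

#' Greedy common-substring match count
#'
#' Counts matching characters between two strings by the greedy recursion:
#' find the longest common substring (ties: earliest occurrence in `a`, then
#' in `b`), add its length, and recurse independently on the left remainders
#' and the right remainders. This is the matching scheme popularised by
#' PHP's `similar_text`.
#'
#' @param a,b single strings. Comparison is case-sensitive; callers wanting
#'   case folding should fold beforehand (see [similarity_percent()]).
#' @return a single non-negative integer, at most `min(nchar(a), nchar(b))`.
#' @export
#' @examples
#' match_count("nonsmall cell lung cancer", "non-small cell lung cancer") # 25
match_count <- function(a, b) {
  stopifnot(is.character(a), length(a) == 1, is.character(b), length(b) == 1)
  match_count_int(utf8ToInt(a), utf8ToInt(b))
}

#' Percent similarity between two strings
#'
#' The greedy match count divided by the average of the two string lengths,
#' times 100. Two empty strings are 100% similar; exactly one empty string
#' gives 0.
#'
#' @param a free-text phrase (by convention the first argument is always the
#'   free text and the second the dictionary description; the greedy
#'   recursion is not guaranteed symmetric).
#' @param b dictionary description.
#' @param config a [fuzzy_config()]; only `case_fold` is used here.
#' @return similarity percentage in \[0, 100\].
#' @export
#' @examples
#' similarity_percent("non small cell lung cancer", "non-small cell lung cancer")
similarity_percent <- function(a, b, config = fuzzy_config()) {
  stopifnot(inherits(config, "fuzzy_config"))
  if (config$case_fold) {
    a <- tolower(a)
    b <- tolower(b)
  }
  la <- nchar(a)
  lb <- nchar(b)
  if (la == 0 && lb == 0) return(100)
  if (la == 0 || lb == 0) return(0)
  match_count(a, b) / ((la + lb) / 2) * 100
}

#' Threshold-gated fuzzy lookup against a description index
#'
#' Computes [similarity_percent()] between `phrase` and every candidate
#' description in the index whose length could possibly reach the threshold,
#' and returns the hits at or above it. The length prefilter keeps only
#' candidate lengths in \[l·t/(2−t), l·(2−t)/t\] where l = nchar(phrase) and
#' t = threshold/100; since the match count cannot exceed the shorter
#' length, terms outside this band cannot reach the threshold, so the
#' prefilter never changes the result set.
#'
#' @param phrase non-empty free-text phrase.
#' @param index a description index from [build_description_index()].
#' @param config a [fuzzy_config()].
#' @param use_length_band disable only for testing prefilter soundness.
#' @return data frame with columns `concept_id`, `description`,
#'   `similarity`, sorted by similarity descending then SCTID ascending.
#' @export
fuzzy_lookup <- function(phrase, index, config = fuzzy_config(),
                         use_length_band = TRUE) {
  stopifnot(inherits(index, "description_index"),
            inherits(config, "fuzzy_config"),
            is.character(phrase), length(phrase) == 1, nzchar(phrase))
  phrase_norm <- normalize_term(phrase)
  terms <- index$terms
  cand <- !duplicated(terms$term_norm)
  if (use_length_band) {
    t <- config$threshold_percent / 100
    lp <- nchar(phrase_norm)
    lt <- nchar(terms$term_norm)
    cand <- cand & lt >= lp * t / (2 - t) & lt <= lp * (2 - t) / t
  }
  uniq <- terms$term_norm[cand]
  if (length(uniq) == 0L) {
    return(data.frame(concept_id = character(), description = character(),
                      similarity = numeric(), stringsAsFactors = FALSE))
  }
  sims <- vapply(uniq, function(tm) {
    similarity_percent(phrase_norm, tm, config)
  }, numeric(1), USE.NAMES = FALSE)
  keep <- sims >= config$threshold_percent
  if (!any(keep)) {
    return(data.frame(concept_id = character(), description = character(),
                      similarity = numeric(), stringsAsFactors = FALSE))
  }
  hit_terms <- uniq[keep]
  hit_sims <- sims[keep]
  rows <- terms[terms$term_norm %in% hit_terms, , drop = FALSE]
  rows$similarity <- hit_sims[match(rows$term_norm, hit_terms)]
  rows <- rows[!duplicated(rows[c("term_norm", "concept_id")]), , drop = FALSE]
  ord <- order(-rows$similarity, nchar(rows$concept_id), rows$concept_id)
  rows <- rows[ord, , drop = FALSE]
  data.frame(concept_id = rows$concept_id, description = rows$term,
             similarity = rows$similarity, stringsAsFactors = FALSE,
             row.names = NULL)
}
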