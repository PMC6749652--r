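# Tokenization, dictionary-lookup named-entity recognition, and ingestion
# of dependency parses. Character offsets are 0-based half-open into the
# original document throughout; CoNLL-U 1-based token indices are converted
# to 0-based at the boundary.

new_sentence <- function(tokens, edges = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(governor = integer(), dependent = integer(),
                        label = character(), stringsAsFactors = FALSE)
  }
  list(tokens = tokens, edges = edges)
}

empty_annotations <- function() {
  data.frame(start = integer(), end = integer(), concept_id = character(),
             term = character(), source = character(),
             similarity = numeric(), stringsAsFactors = FALSE)
}

# Word tokens keep internal hyphens ("non-small" is one token); any other
# non-space character is its own token.
token_regex <- "[[:alnum:]]+(?:-[[:alnum:]]+)*|[^[:space:]]"

#' Tokenize a document into sentences
#'
#' Sentences are split after `.`, `!` or `?` tokens followed by whitespace
#' (or end of text). Tokens are split on whitespace and punctuation
#' boundaries, with hyphenated words kept whole. Token spans are 0-based
#' half-open character offsets into the original document; together the
#' tokens tile every non-whitespace character exactly once.
#'
#' @param text a single document string (may be empty).
#' @return list of sentences; each sentence is a list with a `tokens` data
#'   frame (`index` 0-based within the sentence, `start`, `end`, `text`)
#'   and an empty `edges` data frame.
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(text)) return(list())
  m <- gregexpr(token_regex, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(list())
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  words <- substring(text, starts, starts + lens - 1L)
  n <- length(words)
  # sentence break after ./!/? followed by whitespace or end of document
  brk <- logical(n)
  for (k in seq_len(n)) {
    if (words[k] %in% c(".", "!", "?")) {
      nxt <- starts[k] + lens[k]
      if (nxt > nchar(text) || grepl("^[[:space:]]",
                                     substr(text, nxt, nxt))) {
        brk[k] <- TRUE
      }
    }
  }
  sent_id <- cumsum(c(0L, brk[-n])) + 1L
  out <- lapply(split(seq_len(n), sent_id), function(ix) {
    new_sentence(data.frame(index = seq_along(ix) - 1L,
                            start = starts[ix] - 1L,
                            end = starts[ix] - 1L + lens[ix],
                            text = words[ix], stringsAsFactors = FALSE))
  })
  names(out) <- NULL
  out
}

sort_annotations <- function(ann) {
  if (!nrow(ann)) return(ann)
  ann <- ann[order(ann$start, ann$end, nchar(ann$concept_id),
                   ann$concept_id), , drop = FALSE]
  row.names(ann) <- NULL
  ann
}

#' Dictionary-lookup concept annotation
#'
#' Matches every contiguous token window (up to the longest term in the
#' index) whose normalized text equals an index term, case-insensitively,
#' left to right within each sentence. Overlapping shorter matches are
#' deliberately still emitted — resolving them is the concept filter's job.
#' One annotation is emitted per concept an ambiguous term maps to.
#'
#' @param sentences list of sentences from [tokenize()] or [read_conllu()].
#' @param index a `description_index` from [build_description_index()].
#' @return annotation data frame (`start`, `end`, `concept_id`, `term`,
#'   `source`, `similarity`), sorted by (start, end, SCTID). `source` is
#'   `"custom"` for custom-dictionary entries, else `"dictionary"`;
#'   `similarity` is 100 for these exact matches.
#' @export
annotate_dictionary <- function(sentences, index) {
  stopifnot(inherits(index, "description_index"))
  out <- list()
  for (sent in sentences) {
    tok <- sent$tokens
    n <- nrow(tok)
    if (!n) next
    for (i in seq_len(n)) {
      for (j in i:min(n, i + index$max_words - 1L)) {
        window_norm <- normalize_term(paste(tok$text[i:j], collapse = " "))
        hits <- index_lookup(index, window_norm)
        if (nrow(hits)) {
          out[[length(out) + 1L]] <- data.frame(
            start = tok$start[i], end = tok$end[j],
            concept_id = hits$concept_id, term = hits$term,
            source = hits$source,
            similarity = rep(100, nrow(hits)), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) return(empty_annotations())
  sort_annotations(do.call(rbind, out))
}

#' Read a CoNLL-U dependency parse aligned to a document
#'
#' Parses the 10-column CoNLL-U format and aligns each token FORM to the
#' document text by sequential search, recovering document-level character
#' spans. Dependency edges are built from the HEAD/DEPREL columns (the root
#' attachment is excluded); labels are lower-cased. Multiword-token and
#' empty-node lines are ignored.
#'
#' @param path CoNLL-U file path.
#' @param text the document the parse annotates.
#' @return list of sentences as in [tokenize()], with `edges` populated
#'   (`governor` and `dependent` are 0-based token indices).
#' @export
read_conllu <- function(path, text) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sentences <- list()
  cur <- list()
  cursor <- 1L
  flush_sentence <- function(rows) {
    if (!length(rows)) return(NULL)
    ids <- vapply(rows, `[[`, integer(1), "id")
    if (!identical(ids, seq_along(ids))) {
      stop(sprintf("parse error: non-contiguous token ids near line %d",
                   rows[[1]]$line), call. = FALSE)
    }
    heads <- vapply(rows, `[[`, integer(1), "head")
    bad <- which(heads < 0L | heads > length(rows))
    if (length(bad)) {
      stop(sprintf("parse error: HEAD index %d out of range at line %d",
                   heads[bad[1]], rows[[bad[1]]]$line), call. = FALSE)
    }
    tokens <- data.frame(
      index = ids - 1L,
      start = vapply(rows, `[[`, integer(1), "start"),
      end = vapply(rows, `[[`, integer(1), "end"),
      text = vapply(rows, `[[`, character(1), "form"),
      stringsAsFactors = FALSE)
    dep <- heads > 0L
    edges <- data.frame(governor = heads[dep] - 1L,
                        dependent = ids[dep] - 1L,
                        label = tolower(vapply(rows[dep], `[[`,
                                               character(1), "deprel")),
                        stringsAsFactors = FALSE)
    new_sentence(tokens, edges)
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (startsWith(line, "#")) next
    if (!nzchar(trimws(line))) {
      s <- flush_sentence(cur)
      if (!is.null(s)) sentences[[length(sentences) + 1L]] <- s
      cur <- list()
      next
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 10L) {
      stop(sprintf("parse error: expected 10 tab-separated fields at line %d",
                   ln), call. = FALSE)
    }
    if (grepl("[-.]", fields[1])) next  # multiword token / empty node
    id <- suppressWarnings(as.integer(fields[1]))
    head <- suppressWarnings(as.integer(fields[7]))
    if (is.na(id) || is.na(head)) {
      stop(sprintf("parse error: non-integer ID or HEAD at line %d", ln),
           call. = FALSE)
    }
    form <- fields[2]
    rel <- regexpr(form, substr(text, cursor, nchar(text)), fixed = TRUE)
    if (rel == -1L) {
      stop(sprintf("alignment error: token '%s' (line %d) not found in text",
                   form, ln), call. = FALSE)
    }
    start <- cursor + as.integer(rel) - 1L
    cursor <- start + nchar(form)
    cur[[length(cur) + 1L]] <- list(id = id, form = form, head = head,
                                    deprel = fields[8],
                                    start = start - 1L,  # to 0-based
                                    end = start - 1L + nchar(form),
                                    line = ln)
  }
  s <- flush_sentence(cur)
  if (!is.null(s)) sentences[[length(sentences) + 1L]] <- s
  sentences
}

#' Write annotations as JSON Lines
#'
#' One JSON object per annotation with fields `start`, `end`, `conceptId`,
#' `term`, `source`, `similarity` (plus any extra columns such as
#' `chartId`).
#'
#' @param ann annotation data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations_jsonl <- function(ann, path) {
  df <- ann
  names(df)[names(df) == "concept_id"] <- "conceptId"
  names(df)[names(df) == "chart_id"] <- "chartId"
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(df)) {
    for (k in seq_len(nrow(df))) {
      writeLines(jsonlite::toJSON(as.list(df[k, , drop = FALSE]),
                                  auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}
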