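# Concept relationship detection over dependency edges, fuzzy recovery of
# unannotated mention words, MRCM attribute-relationship detection, and
# compositional-grammar serialization of post-coordinated expressions.

#' Relation extraction configuration
#'
#' @param allowed_labels dependency relation labels whose edges are
#'   considered for concept relationships. The default set is: nominal
#'   subject (nsubj), adjectival modifier (amod), modifier of nominal
#'   (nmod), adverbial modifier (advmod), noun compound modifier (nn),
#'   attribute (attr), direct object (dobj), object of a preposition
#'   (pobj), and modifier in hyphenation (hmod).
#' @param include_npadvmod also consider noun-phrase-as-adverbial-modifier
#'   edges (default `FALSE`).
#' @return an object of class `relation_config`.
#' @export
relation_config <- function(allowed_labels = c("nsubj", "amod", "nmod",
                                               "advmod", "nn", "attr",
                                               "dobj", "pobj", "hmod"),
                            include_npadvmod = FALSE) {
  allowed_labels <- tolower(allowed_labels)
  stopifnot(length(allowed_labels) > 0, is.logical(include_npadvmod))
  structure(list(allowed_labels = allowed_labels,
                 include_npadvmod = include_npadvmod),
            class = "relation_config")
}

effective_labels <- function(config) {
  if (config$include_npadvmod) {
    unique(c(config$allowed_labels, "npadvmod"))
  } else {
    config$allowed_labels
  }
}

# Label subtypes ("nmod:poss") compare on their base label.
label_base <- function(label) sub(":.*$", "", label)

allowed_edges <- function(sent, config) {
  ed <- sent$edges
  ed[label_base(ed$label) %in% effective_labels(config), , drop = FALSE]
}

token_covered <- function(tok, ann) {
  if (!nrow(ann)) return(rep(FALSE, nrow(tok)))
  vapply(seq_len(nrow(tok)), function(k) {
    any(spans_overlap(tok$start[k], tok$end[k], ann$start, ann$end))
  }, logical(1))
}

#' Fuzzy recovery of unannotated mention words
#'
#' For each token that participates in an allowed-label dependency edge but
#' is not covered by any existing annotation, candidate token windows
#' containing it are looked up with [fuzzy_lookup()] and the best hit
#' (highest similarity, then lowest SCTID, then leftmost and shortest
#' window) becomes a new annotation with source `"fuzzy"`. A candidate
#' window is any contiguous token run containing the uncovered token, no
#' longer than the longest index term plus one word, that does not cut an
#' existing annotation in half (every annotation overlapping the window
#' must lie entirely inside it). Windows may therefore absorb an existing
#' shorter annotation — in "recurrent nonsmall cell lung cancer" the
#' dictionary may already have matched "lung cancer" inside the misspelled
#' phrase, and the recovered phrase-level concept must still be found;
#' the absorbed shorter annotation is then removed by a final pass of the
#' overlap filter in the pipeline. This recovers misspelled mentions such
#' as "nonsmall cell lung cancer" at 98% similarity to the dictionary
#' description "non-small cell lung cancer".
#'
#' @param sentences sentences with dependency edges.
#' @param annotations already-filtered annotations.
#' @param index a `description_index`.
#' @param config a [relation_config()].
#' @param fuzzy a [fuzzy_config()].
#' @return data frame of only the newly added annotations.
#' @export
recover_unmatched <- function(sentences, annotations, index,
                              config = relation_config(),
                              fuzzy = fuzzy_config()) {
  stopifnot(inherits(index, "description_index"))
  ann <- annotations
  out <- list()
  max_win <- index$max_words + 1L
  for (sent in sentences) {
    tok <- sent$tokens
    n <- nrow(tok)
    if (!n) next
    ed <- allowed_edges(sent, config)
    if (!nrow(ed)) next
    covered <- token_covered(tok, ann)
    edge_toks <- unique(c(ed$dependent, ed$governor)) + 1L  # to row index
    targets <- sort(edge_toks[!covered[edge_toks]])
    if (!length(targets)) next
    window_ok <- function(i, j) {
      ws <- tok$start[i]
      we <- tok$end[j]
      ov <- spans_overlap(ws, we, ann$start, ann$end)
      all(ann$start[ov] >= ws & ann$end[ov] <= we)
    }
    cache <- new.env(parent = emptyenv())
    for (tk in targets) {
      best <- NULL
      for (i in max(1L, tk - max_win + 1L):tk) {
        for (j in tk:min(n, i + max_win - 1L)) {
          key <- sprintf("%d.%d", i, j)
          cached <- get0(key, envir = cache, ifnotfound = NULL)
          hit <- if (!is.null(cached)) {
            if (identical(cached, FALSE)) NULL else cached
          } else {
            h <- NULL
            if (window_ok(i, j)) {
              hits <- fuzzy_lookup(paste(tok$text[i:j], collapse = " "),
                                   index, fuzzy)
              if (nrow(hits)) {
                h <- data.frame(start = tok$start[i], end = tok$end[j],
                                concept_id = hits$concept_id[1],
                                term = hits$description[1],
                                source = "fuzzy",
                                similarity = hits$similarity[1],
                                stringsAsFactors = FALSE)
              }
            }
            cache[[key]] <- if (is.null(h)) FALSE else h
            h
          }
          if (!is.null(hit) && (is.null(best) ||
                hit$similarity > best$similarity ||
                (hit$similarity == best$similarity &&
                 hit$concept_id != best$concept_id &&
                 sctid_order(c(hit$concept_id, best$concept_id))[1] == 1L))) {
            best <- hit
          }
        }
      }
      if (!is.null(best)) out[[length(out) + 1L]] <- best
    }
  }
  if (!length(out)) return(empty_annotations())
  new <- do.call(rbind, out)
  new <- new[!duplicated(new[c("start", "end", "concept_id")]), ,
             drop = FALSE]
  # a recovery duplicating an existing annotation adds nothing
  if (nrow(ann)) {
    dup <- mapply(function(s, e, c) {
      any(ann$start == s & ann$end == e & ann$concept_id == c)
    }, new$start, new$end, new$concept_id)
    new <- new[!dup, , drop = FALSE]
  }
  sort_annotations(new)
}

empty_relations <- function() {
  data.frame(source_concept = character(), dest_concept = character(),
             source_start = integer(), source_end = integer(),
             dest_start = integer(), dest_end = integer(),
             label = character(), sentence_index = integer(),
             stringsAsFactors = FALSE)
}

#' Extract concept relations from dependency edges
#'
#' For every dependency edge with an allowed label, pairs annotations
#' overlapping the dependent token (the modifier, becoming the relation
#' source) with annotations overlapping the governor token (the head,
#' becoming the destination). Pairs with identical concept ids are skipped;
#' identical (source concept, destination concept, sentence) triples are
#' deduplicated.
#'
#' @param sentences sentences with dependency edges.
#' @param annotations annotations including any fuzzy recoveries.
#' @param config a [relation_config()].
#' @return data frame with columns `source_concept`, `dest_concept`,
#'   `source_start`/`source_end`, `dest_start`/`dest_end`, `label`,
#'   `sentence_index`, in deterministic order.
#' @export
extract_relations <- function(sentences, annotations,
                              config = relation_config()) {
  ann <- annotations
  out <- list()
  for (si in seq_along(sentences)) {
    sent <- sentences[[si]]
    tok <- sent$tokens
    ed <- allowed_edges(sent, config)
    if (!nrow(ed) || !nrow(ann)) next
    for (k in seq_len(nrow(ed))) {
      dep <- ed$dependent[k] + 1L
      gov <- ed$governor[k] + 1L
      src <- ann[spans_overlap(tok$start[dep], tok$end[dep],
                               ann$start, ann$end), , drop = FALSE]
      dst <- ann[spans_overlap(tok$start[gov], tok$end[gov],
                               ann$start, ann$end), , drop = FALSE]
      if (!nrow(src) || !nrow(dst)) next
      for (a in seq_len(nrow(src))) {
        for (b in seq_len(nrow(dst))) {
          if (src$concept_id[a] == dst$concept_id[b]) next
          out[[length(out) + 1L]] <- data.frame(
            source_concept = src$concept_id[a],
            dest_concept = dst$concept_id[b],
            source_start = src$start[a], source_end = src$end[a],
            dest_start = dst$start[b], dest_end = dst$end[b],
            label = ed$label[k], sentence_index = si - 1L,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) return(empty_relations())
  rel <- do.call(rbind, out)
  rel <- rel[!duplicated(rel[c("source_concept", "dest_concept",
                               "sentence_index")]), , drop = FALSE]
  rel <- rel[order(rel$sentence_index,
                   nchar(rel$source_concept), rel$source_concept,
                   nchar(rel$dest_concept), rel$dest_concept), , drop = FALSE]
  row.names(rel) <- NULL
  rel
}

empty_expressions <- function() {
  data.frame(focus_id = character(), attribute_id = character(),
             value_id = character(), sentence_index = integer(),
             stringsAsFactors = FALSE)
}

#' Qualify concept relations with MRCM-licensed attributes
#'
#' For each relation, the destination (head) concept becomes the focus and
#' the source (modifier) concept the attribute value; one post-coordinated
#' expression is emitted per attribute returned by [attributes_linking()]
#' for that pair (ascending attribute id). Relations licensing no attribute
#' yield nothing, so every emitted expression satisfies its MRCM rule by
#' construction.
#'
#' @param relations data frame from [extract_relations()].
#' @param graph a `terminology_graph`.
#' @return data frame with columns `focus_id`, `attribute_id`, `value_id`,
#'   `sentence_index`.
#' @export
detect_attribute_relations <- function(relations, graph) {
  stopifnot(inherits(graph, "terminology_graph"))
  out <- list()
  for (k in seq_len(nrow(relations))) {
    focus <- relations$dest_concept[k]
    value <- relations$source_concept[k]
    atts <- attributes_linking(graph, focus, value)
    if (length(atts)) {
      out[[length(out) + 1L]] <- data.frame(
        focus_id = focus, attribute_id = atts, value_id = value,
        sentence_index = relations$sentence_index[k],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_expressions())
  ex <- do.call(rbind, out)
  ex <- ex[!duplicated(ex[c("focus_id", "attribute_id", "value_id",
                            "sentence_index")]), , drop = FALSE]
  row.names(ex) <- NULL
  ex
}

fsn_of <- function(graph, id) {
  graph$concepts$fsn[match(id, graph$concepts$concept_id)]
}

#' Serialize a post-coordinated expression
#'
#' Short form is SNOMED compositional grammar without whitespace,
#' `"focusId:attributeId=valueId"`. The long form interleaves fully
#' specified names, `"id | fsn | : id | fsn | = id | fsn |"`, and requires
#' the terminology graph.
#'
#' @param expr a list or one-row data frame with `focus_id`,
#'   `attribute_id`, `value_id`.
#' @param graph a `terminology_graph` (needed when `long = TRUE`).
#' @param long emit the long form with FSN annotations.
#' @return a single string.
#' @export
serialize_expression <- function(expr, graph = NULL, long = FALSE) {
  f <- as.character(expr$focus_id)
  a <- as.character(expr$attribute_id)
  v <- as.character(expr$value_id)
  if (!long) {
    return(sprintf("%s:%s=%s", f, a, v))
  }
  stopifnot(inherits(graph, "terminology_graph"))
  sprintf("%s | %s | : %s | %s | = %s | %s |",
          f, fsn_of(graph, f), a, fsn_of(graph, a), v, fsn_of(graph, v))
}

#' Parse a short-form post-coordinated expression
#'
#' Inverse of [serialize_expression()] for the short form.
#'
#' @param text a string like `"93880001:263502005=255227004"`.
#' @return list with `focus_id`, `attribute_id`, `value_id`.
#' @export
parse_expression <- function(text) {
  m <- regmatches(text, regexec("^([0-9]+):([0-9]+)=([0-9]+)$", text))[[1]]
  if (length(m) != 4) {
    stop(sprintf("parse error: not a short-form expression: '%s'", text),
         call. = FALSE)
  }
  list(focus_id = m[2], attribute_id = m[3], value_id = m[4])
}
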