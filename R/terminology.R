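# RF2-lite terminology: concepts, descriptions, is-a hierarchy, historical
# substitutions for inactive concepts, and MRCM attribute rules. All
# subsumption and attribute-licensing queries in the package run against
# the object built here.

new_terminology_graph <- function(concepts, descriptions, is_a,
                                  substitutions, mrcm) {
  parents <- split(is_a$parent_id, factor(is_a$child_id,
                                          levels = unique(is_a$child_id)))
  structure(list(concepts = concepts,
                 descriptions = descriptions,
                 is_a = is_a,
                 substitutions = substitutions,
                 mrcm = mrcm,
                 parents = parents),
            class = "terminology_graph")
}

# Depth-first search for a directed cycle; returns NULL or one cycle as a
# vector of concept ids.
find_is_a_cycle <- function(parents, nodes) {
  state <- new.env(parent = emptyenv())  # 1 = in stack, 2 = done
  dfs <- function(v, path) {
    st <- get0(v, envir = state, ifnotfound = 0L)
    if (st == 1L) {
      return(c(path[which(path == v)[1]:length(path)], v))
    }
    if (st == 2L) return(NULL)
    state[[v]] <- 1L
    for (p in parents[[v]] %||% character()) {
      cyc <- dfs(p, c(path, v))
      if (!is.null(cyc)) return(cyc)
    }
    state[[v]] <- 2L
    NULL
  }
  for (v in nodes) {
    cyc <- dfs(v, character())
    if (!is.null(cyc)) return(cyc)
  }
  NULL
}

validate_terminology <- function(graph) {
  co <- graph$concepts
  if (anyNA(co$concept_id) || !all(is_sctid(co$concept_id))) {
    stop("validation error: concept ids must be non-empty digit strings",
         call. = FALSE)
  }
  dup <- co$concept_id[duplicated(co$concept_id)]
  if (length(dup)) {
    stop(sprintf("validation error: duplicate concept id %s", dup[1]),
         call. = FALSE)
  }
  known <- co$concept_id
  active <- co$concept_id[co$active]

  de <- graph$descriptions
  de_terms <- normalize_term(de$term)
  if (any(!nzchar(de_terms))) {
    stop("validation error: empty description term after normalization",
         call. = FALSE)
  }
  miss <- setdiff(de$concept_id, known)
  if (length(miss)) {
    stop(sprintf("validation error: dangling identifier %s in descriptions",
                 miss[1]), call. = FALSE)
  }

  ia <- graph$is_a
  miss <- setdiff(c(ia$child_id, ia$parent_id), known)
  if (length(miss)) {
    stop(sprintf("validation error: dangling identifier %s in is_a", miss[1]),
         call. = FALSE)
  }
  cyc <- find_is_a_cycle(graph$parents, unique(ia$child_id))
  if (!is.null(cyc)) {
    stop(sprintf("validation error: cyclic is-a hierarchy: %s",
                 paste(cyc, collapse = " -> ")), call. = FALSE)
  }

  su <- graph$substitutions
  miss <- setdiff(c(su$inactive_id, su$replacement_id), known)
  if (length(miss)) {
    stop(sprintf("validation error: dangling identifier %s in substitutions",
                 miss[1]), call. = FALSE)
  }
  bad <- intersect(su$inactive_id, active)
  if (length(bad)) {
    stop(sprintf("validation error: substitution source %s is active", bad[1]),
         call. = FALSE)
  }
  bad <- setdiff(su$replacement_id, active)
  if (length(bad)) {
    stop(sprintf(
      "validation error: substitution replacement %s is not active (chained substitutions are not allowed)",
      bad[1]), call. = FALSE)
  }

  mr <- graph$mrcm
  miss <- setdiff(c(mr$attribute_id, mr$domain_id, mr$range_id), known)
  if (length(miss)) {
    stop(sprintf("validation error: dangling identifier %s in mrcm", miss[1]),
         call. = FALSE)
  }
  invisible(graph)
}

read_tsv_cols <- function(path, cols) {
  df <- utils::read.delim(path, colClasses = "character", sep = "\t",
                          quote = "", fileEncoding = "UTF-8",
                          stringsAsFactors = FALSE)
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("load error: %s is missing column(s) %s",
                 basename(path), paste(miss, collapse = ", ")), call. = FALSE)
  }
  df[cols]
}

#' Load an RF2-lite terminology from a directory
#'
#' Expects `concepts.tsv`, `descriptions.tsv`, and `is_a.tsv` (mandatory)
#' plus optional `substitutions.tsv` and `mrcm.tsv` (defaulting to empty).
#' All files are tab-separated UTF-8 with a header row. The loaded graph is
#' validated: ids must be digit strings unique in the concept file, every
#' referenced id must exist, the is-a hierarchy must be acyclic, and
#' substitutions must map inactive concepts to active replacements
#' (no chaining).
#'
#' @param dir_path directory containing the TSV files.
#' @return an object of class `terminology_graph`.
#' @export
load_terminology <- function(dir_path) {
  need <- c("concepts.tsv", "descriptions.tsv", "is_a.tsv")
  for (f in need) {
    if (!file.exists(file.path(dir_path, f))) {
      stop(sprintf("load error: missing mandatory file %s", f), call. = FALSE)
    }
  }
  co <- read_tsv_cols(file.path(dir_path, "concepts.tsv"),
                      c("id", "active", "fsn"))
  concepts <- data.frame(concept_id = co$id,
                         active = co$active == "1",
                         fsn = co$fsn, stringsAsFactors = FALSE)
  de <- read_tsv_cols(file.path(dir_path, "descriptions.tsv"),
                      c("conceptId", "term", "isFsn"))
  descriptions <- data.frame(concept_id = de$conceptId, term = de$term,
                             is_fsn = de$isFsn == "1",
                             stringsAsFactors = FALSE)
  ia <- read_tsv_cols(file.path(dir_path, "is_a.tsv"),
                      c("childId", "parentId"))
  is_a <- data.frame(child_id = ia$childId, parent_id = ia$parentId,
                     stringsAsFactors = FALSE)

  subs_path <- file.path(dir_path, "substitutions.tsv")
  if (file.exists(subs_path)) {
    su <- read_tsv_cols(subs_path, c("inactiveId", "replacementId"))
    substitutions <- data.frame(inactive_id = su$inactiveId,
                                replacement_id = su$replacementId,
                                stringsAsFactors = FALSE)
  } else {
    substitutions <- data.frame(inactive_id = character(),
                                replacement_id = character(),
                                stringsAsFactors = FALSE)
  }
  mrcm_path <- file.path(dir_path, "mrcm.tsv")
  if (file.exists(mrcm_path)) {
    mr <- read_tsv_cols(mrcm_path, c("attributeId", "domainId", "rangeId"))
    mrcm <- data.frame(attribute_id = mr$attributeId,
                       domain_id = mr$domainId,
                       range_id = mr$rangeId, stringsAsFactors = FALSE)
  } else {
    mrcm <- data.frame(attribute_id = character(), domain_id = character(),
                       range_id = character(), stringsAsFactors = FALSE)
  }
  validate_terminology(new_terminology_graph(concepts, descriptions, is_a,
                                             substitutions, mrcm))
}

#' Write a terminology back to RF2-lite TSV files
#'
#' Inverse of [load_terminology()]; loading the written directory yields an
#' identical graph.
#'
#' @param graph a `terminology_graph`.
#' @param dir_path output directory (created if needed).
#' @return `dir_path`, invisibly.
#' @export
write_terminology <- function(graph, dir_path) {
  stopifnot(inherits(graph, "terminology_graph"))
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir_path)) {
    stop(sprintf("I/O error: cannot create directory %s", dir_path),
         call. = FALSE)
  }
  wr <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  co <- graph$concepts
  wr(data.frame(id = co$concept_id, active = as.integer(co$active),
                fsn = co$fsn), file.path(dir_path, "concepts.tsv"))
  de <- graph$descriptions
  wr(data.frame(conceptId = de$concept_id, term = de$term,
                isFsn = as.integer(de$is_fsn)),
     file.path(dir_path, "descriptions.tsv"))
  wr(data.frame(childId = graph$is_a$child_id,
                parentId = graph$is_a$parent_id),
     file.path(dir_path, "is_a.tsv"))
  wr(data.frame(inactiveId = graph$substitutions$inactive_id,
                replacementId = graph$substitutions$replacement_id),
     file.path(dir_path, "substitutions.tsv"))
  wr(data.frame(attributeId = graph$mrcm$attribute_id,
                domainId = graph$mrcm$domain_id,
                rangeId = graph$mrcm$range_id),
     file.path(dir_path, "mrcm.tsv"))
  invisible(dir_path)
}

#' @export
print.terminology_graph <- function(x, ...) {
  cat(sprintf(
    "<terminology_graph> %d concepts (%d active), %d descriptions, %d is-a edges, %d substitutions, %d MRCM rows\n",
    nrow(x$concepts), sum(x$concepts$active), nrow(x$descriptions),
    nrow(x$is_a), nrow(x$substitutions), nrow(x$mrcm)))
  invisible(x)
}

check_known <- function(graph, ids) {
  miss <- setdiff(ids, graph$concepts$concept_id)
  if (length(miss)) stop_lookup(miss[1])
  invisible(TRUE)
}

#' Resolve a concept to its active form(s)
#'
#' An active concept resolves to itself. An inactive concept resolves to its
#' replacement concepts (possibly several, in the order the substitution
#' rows were loaded; possibly none). Substitution is applied once, never
#' chained; load-time validation guarantees replacements are active.
#'
#' @param graph a `terminology_graph`.
#' @param concept_id SCTID present in the graph.
#' @return character vector of active SCTIDs.
#' @export
resolve_active <- function(graph, concept_id) {
  stopifnot(inherits(graph, "terminology_graph"), length(concept_id) == 1)
  check_known(graph, concept_id)
  co <- graph$concepts
  if (co$active[co$concept_id == concept_id]) return(concept_id)
  su <- graph$substitutions
  su$replacement_id[su$inactive_id == concept_id]
}

ancestors_of <- function(graph, id) {
  seen <- id
  frontier <- id
  while (length(frontier)) {
    nxt <- unique(unlist(graph$parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Is-a subsumption test
#'
#' `TRUE` iff `descendant_id` equals `ancestor_id` or reaches it through one
#' or more is-a edges (SNOMED's self-or-descendant convention: every concept
#' subsumes itself).
#'
#' @param graph a `terminology_graph`.
#' @param ancestor_id,descendant_id SCTIDs present in the graph.
#' @return logical scalar.
#' @export
subsumes <- function(graph, ancestor_id, descendant_id) {
  stopifnot(inherits(graph, "terminology_graph"))
  check_known(graph, c(ancestor_id, descendant_id))
  if (ancestor_id == descendant_id) return(TRUE)
  ancestor_id %in% ancestors_of(graph, descendant_id)
}

#' Read a custom dictionary TSV
#'
#' Tab-separated file with header columns `term` and `conceptId`, mapping
#' keywords not present in the terminology descriptions (such as alternate
#' word forms like "recurrence") to concepts.
#'
#' @param path file path.
#' @return data frame with columns `term`, `concept_id`.
#' @export
read_custom_dict <- function(path) {
  df <- read_tsv_cols(path, c("term", "conceptId"))
  data.frame(term = df$term, concept_id = df$conceptId,
             stringsAsFactors = FALSE)
}

#' Build the term-to-concept description index
#'
#' Combines terminology descriptions with optional custom-dictionary entries
#' into a case-folded, whitespace-normalized multimap from term to concept.
#' A term may map to several concepts; disambiguation is left to the
#' annotation filter. Custom entries are flagged so downstream annotations
#' carry their provenance.
#'
#' @param graph a `terminology_graph`.
#' @param custom_dict `NULL`, or a data frame with columns `term` and
#'   `concept_id` (see [read_custom_dict()]).
#' @return an object of class `description_index`.
#' @export
build_description_index <- function(graph, custom_dict = NULL) {
  stopifnot(inherits(graph, "terminology_graph"))
  de <- graph$descriptions
  terms <- data.frame(term = de$term,
                      term_norm = normalize_term(de$term),
                      concept_id = de$concept_id,
                      source = rep("dictionary", nrow(de)),
                      stringsAsFactors = FALSE)
  if (!is.null(custom_dict) && nrow(custom_dict)) {
    stopifnot(all(c("term", "concept_id") %in% names(custom_dict)))
    miss <- !(custom_dict$concept_id %in% graph$concepts$concept_id)
    if (any(miss)) {
      stop(sprintf(
        "validation error: custom dictionary term '%s' maps to unknown concept %s",
        custom_dict$term[miss][1], custom_dict$concept_id[miss][1]),
        call. = FALSE)
    }
    terms <- rbind(terms, data.frame(
      term = custom_dict$term,
      term_norm = normalize_term(custom_dict$term),
      concept_id = custom_dict$concept_id,
      source = rep("custom", nrow(custom_dict)),
      stringsAsFactors = FALSE))
  }
  terms <- terms[nzchar(terms$term_norm), , drop = FALSE]
  terms <- terms[!duplicated(terms[c("term_norm", "concept_id")]), ,
                 drop = FALSE]
  row.names(terms) <- NULL
  structure(list(terms = terms,
                 max_words = max(1L, lengths(strsplit(terms$term_norm, " ")))),
            class = "description_index")
}

#' @export
print.description_index <- function(x, ...) {
  cat(sprintf("<description_index> %d entries (%d custom), longest term: %d word(s)\n",
              nrow(x$terms), sum(x$terms$source == "custom"), x$max_words))
  invisible(x)
}

index_lookup <- function(index, term_norm) {
  index$terms[index$terms$term_norm == term_norm, , drop = FALSE]
}

#' MRCM attributes licensing a concept pair
#'
#' Returns every attribute concept for which some MRCM rule's domain
#' subsumes `source_id` and at least one of the rule's range members
#' subsumes `destination_id` — i.e. the attributes that may link a focus
#' concept (`source_id`) to an attribute value (`destination_id`) in a
#' post-coordinated expression.
#'
#' @param graph a `terminology_graph`.
#' @param source_id focus-concept SCTID (must fall in the rule's domain).
#' @param destination_id value SCTID (must fall in the rule's range).
#' @return character vector of attribute SCTIDs, deduplicated, ascending.
#' @export
attributes_linking <- function(graph, source_id, destination_id) {
  stopifnot(inherits(graph, "terminology_graph"))
  check_known(graph, c(source_id, destination_id))
  mr <- graph$mrcm
  if (!nrow(mr)) return(character())
  src_anc <- ancestors_of(graph, source_id)
  dst_anc <- ancestors_of(graph, destination_id)
  ok <- mr$domain_id %in% src_anc & mr$range_id %in% dst_anc
  sort_sctid(unique(mr$attribute_id[ok]))
}
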