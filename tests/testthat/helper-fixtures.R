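# Shared test fixtures and independent oracles. Oracles are deliberately
# written from different primitives than the implementation they check.

# One toy terminology per test run, generated by the fixture module.
toy_term_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      d <- file.path(tempdir(), "clinconcept-toy-terminology")
      generate_terminology(d)
      dir <<- d
    }
    dir
  }
})

toy_graph <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- load_terminology(toy_term_dir())
    g
  }
})

toy_index <- local({
  ix <- NULL
  function() {
    if (is.null(ix)) {
      ix <<- build_description_index(
        toy_graph(), read_custom_dict(file.path(toy_term_dir(),
                                                "custom_dict.tsv")))
    }
    ix
  }
})

# Write an RF2-lite terminology directory from raw data frames.
write_term_tsv <- function(dir, concepts, descriptions = NULL, is_a = NULL,
                           substitutions = NULL, mrcm = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) {
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr(concepts, "concepts.tsv")
  if (is.null(descriptions)) {
    descriptions <- data.frame(conceptId = concepts$id,
                               term = paste("term", concepts$id),
                               isFsn = 0L)
  }
  wr(descriptions, "descriptions.tsv")
  if (is.null(is_a)) is_a <- data.frame(childId = character(),
                                        parentId = character())
  wr(is_a, "is_a.tsv")
  if (!is.null(substitutions)) wr(substitutions, "substitutions.tsv")
  if (!is.null(mrcm)) wr(mrcm, "mrcm.tsv")
  dir
}

# Random is-a DAG over n concepts: edges only from higher to lower id, so
# acyclicity holds by construction.
random_dag_graph <- function(n, p_edge = 0.3) {
  ids <- as.character(1000 + seq_len(n))
  edges <- list()
  for (child in seq_len(n)) {
    for (parent in seq_len(child - 1)) {
      if (stats::runif(1) < p_edge) {
        edges[[length(edges) + 1L]] <- data.frame(childId = ids[child],
                                                  parentId = ids[parent])
      }
    }
  }
  is_a <- if (length(edges)) {
    do.call(rbind, edges)
  } else {
    data.frame(childId = character(), parentId = character())
  }
  dir <- tempfile("dag")
  write_term_tsv(dir, data.frame(id = ids, active = 1L,
                                 fsn = paste("concept", ids)),
                 is_a = is_a)
  list(graph = load_terminology(dir), ids = ids, is_a = is_a)
}

# Independent reachability oracle over the raw edge table.
reachable <- function(is_a, from, to) {
  if (from == to) return(TRUE)
  frontier <- from
  seen <- character()
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(is_a$parentId[is_a$childId %in% frontier], seen)
    if (to %in% frontier) return(TRUE)
  }
  FALSE
}

# Independent match-count oracle: the same left/right recursion built from
# a dynamic-programming longest-common-substring primitive instead of the
# scanning search used by the implementation.
dp_match_count <- function(a, b) {
  rec <- function(x, y) {
    nx <- length(x)
    ny <- length(y)
    if (!nx || !ny) return(0L)
    L <- matrix(0L, nx + 1L, ny + 1L)
    for (i in seq_len(nx)) {
      for (j in seq_len(ny)) {
        if (x[i] == y[j]) L[i + 1L, j + 1L] <- L[i, j] + 1L
      }
    }
    best <- max(L)
    if (best == 0L) return(0L)
    ends <- which(L == best, arr.ind = TRUE)
    si <- ends[, 1] - best   # 1-based start in x (row index is i + 1)
    sj <- ends[, 2] - best
    o <- order(si, sj)[1]
    s_i <- si[o]
    s_j <- sj[o]
    best +
      rec(x[seq_len(s_i - 1L)], y[seq_len(s_j - 1L)]) +
      rec(if (s_i + best <= nx) x[(s_i + best):nx] else character(),
          if (s_j + best <= ny) y[(s_j + best):ny] else character())
  }
  rec(strsplit(a, "")[[1]], strsplit(b, "")[[1]])
}

# Brute-force filter oracle: applies the four rules by direct set
# operations over the annotation rows.
brute_filter <- function(ann, graph, keep_ties = TRUE) {
  act <- graph$concepts$concept_id[graph$concepts$active]
  rows <- list()
  for (k in seq_len(nrow(ann))) {
    if (ann$concept_id[k] %in% act) {
      rows[[length(rows) + 1L]] <- ann[k, , drop = FALSE]
    } else {
      su <- graph$substitutions
      for (r in su$replacement_id[su$inactive_id == ann$concept_id[k]]) {
        row <- ann[k, , drop = FALSE]
        row$concept_id <- r
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  if (!length(rows)) return(ann[0, c("start", "end", "concept_id")])
  a <- do.call(rbind, rows)
  len <- a$end - a$start
  keep <- vapply(seq_len(nrow(a)), function(k) {
    ov <- a$start < a$end[k] & a$end > a$start[k]
    ov[k] <- FALSE
    if (any(ov & len > len[k])) return(FALSE)
    if (!keep_ties) {
      tie <- ov & len == len[k] & a$concept_id != a$concept_id[k]
      if (any(tie)) {
        ids <- c(a$concept_id[tie], a$concept_id[k])
        first <- ids[order(nchar(ids), ids)][1]
        if (first != a$concept_id[k]) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  a <- a[keep, , drop = FALSE]
  a <- a[!duplicated(a[c("start", "end", "concept_id")]), , drop = FALSE]
  keep <- vapply(seq_len(nrow(a)), function(k) {
    for (m in seq_len(nrow(a))) {
      if (m == k) next
      if (a$start[m] == a$start[k] && a$end[m] == a$end[k] &&
          a$concept_id[m] != a$concept_id[k] &&
          subsumes(graph, a$concept_id[k], a$concept_id[m])) {
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  a <- a[keep, c("start", "end", "concept_id")]
  a <- a[order(a$start, a$end, nchar(a$concept_id), a$concept_id), ,
         drop = FALSE]
  row.names(a) <- NULL
  a
}

make_ann <- function(start, end, concept_id,
                     term = sprintf("t%d", seq_along(start)),
                     source = "dictionary", similarity = 100) {
  n <- length(start)
  data.frame(start = as.integer(start), end = as.integer(end),
             concept_id = concept_id, term = term,
             source = rep_len(source, n),
             similarity = rep_len(similarity, n), stringsAsFactors = FALSE)
}

# The flagship sentence and its dependency parse in CoNLL-U form.
flagship_text <- function() {
  "This patient is diagnosed with recurrent nonsmall cell lung cancer"
}

flagship_conllu <- function() {
  path <- tempfile(fileext = ".conllu")
  forms <- c("This", "patient", "is", "diagnosed", "with", "recurrent",
             "nonsmall", "cell", "lung", "cancer")
  heads <- c(2, 4, 4, 0, 4, 10, 10, 10, 10, 5)
  rels <- c("det", "nsubj", "aux", "root", "prep", "amod", "amod", "nn",
            "nn", "pobj")
  writeLines(sprintf("%d\t%s\t_\t_\t_\t_\t%d\t%s\t_\t_",
                     seq_along(forms), forms, heads, rels), path)
  path
}

# Small deterministic chart fixture directory for pipeline tests.
fixture_run <- function(seed = 7, n_charts = 12, misspell_rate = 0.2,
                        max_edit_fraction = 0.05) {
  base <- tempfile("fixrun")
  charts <- file.path(base, "charts")
  generate_charts(fixture_spec(seed = seed, n_charts = n_charts,
                               misspell_rate = misspell_rate,
                               max_edit_fraction = max_edit_fraction),
                  toy_graph(), charts)
  list(base = base, charts = charts)
}

run_toy_pipeline <- function(charts, out = tempfile("out"), ...) {
  run_pipeline(pipeline_config(toy_term_dir(), charts, out,
                               log_level = "quiet", ...))
}
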