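# Synthetic study material: a toy oncology terminology in RF2-lite form, a
# custom dictionary, and templated charts with dependency parses, seeded
# misspellings, gold chart labels, and a ground-truth file. Everything is
# deterministic under the spec seed, so the full pipeline and evaluation
# run with no external data.

#' Fixture generation parameters
#'
#' @param seed integer RNG seed; the entire fixture set is a deterministic
#'   function of it.
#' @param n_charts number of charts (>= 1); chart 0 is always the flagship
#'   sentence about recurrent non-small cell lung cancer.
#' @param misspell_rate probability that a chart's perturbable mention is
#'   corrupted.
#' @param max_edit_fraction cap on the number of character edits per
#'   corrupted mention, as a fraction of the term length. The default 0.05
#'   matches the similarity matcher's 5% error margin, so every injected
#'   misspelling stays recoverable; raising it (e.g. 0.2) forces
#'   misspellings beyond the margin.
#' @param label_mix sampling proportions for positive / negative /
#'   not-listed chart templates.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 42, n_charts = 30, misspell_rate = 0.2,
                         max_edit_fraction = 0.05,
                         label_mix = c(positive = 0.6, negative = 0.1,
                                       not_listed = 0.3)) {
  stopifnot(n_charts >= 1, misspell_rate >= 0, misspell_rate <= 1,
            max_edit_fraction >= 0, length(label_mix) == 3,
            all(label_mix >= 0), sum(label_mix) > 0)
  structure(list(seed = as.integer(seed), n_charts = as.integer(n_charts),
                 misspell_rate = misspell_rate,
                 max_edit_fraction = max_edit_fraction,
                 label_mix = label_mix / sum(label_mix)),
            class = "fixture_spec")
}

#' Generate the toy oncology terminology
#'
#' Writes an RF2-lite file set (`concepts.tsv`, `descriptions.tsv`,
#' `is_a.tsv`, `substitutions.tsv`, `mrcm.tsv`) plus a `custom_dict.tsv`
#' mapping "recurrence" to the Recurrent qualifier. It contains the real
#' SNOMED CT concepts for primary malignant neoplasm of lung (93880001),
#' non-small cell lung cancer (254637007), Recurrent (255227004), Clinical
#' course (263502005) and Courses (288524001), the is-a edge making
#' non-small cell lung cancer a descendant of primary malignant neoplasm
#' of lung, and a Clinical-course MRCM rule whose domain covers clinical
#' findings and whose range covers Courses. Additional invented concepts
#' use 99-prefixed identifiers outside real SNOMED namespaces and carry
#' "(synthetic)" in their FSN, including one inactive concept with a
#' substitution. Output is deterministic: generating twice yields
#' byte-identical files.
#'
#' @param out_dir writable output directory.
#' @return `out_dir`, invisibly.
#' @export
generate_terminology <- function(out_dir) {
  concepts <- data.frame(
    concept_id = c("138875005", "404684003", "93880001", "254637007",
                   "255227004", "263502005", "288524001", "362981000",
                   "39607008", "990000101", "990000102", "990000103"),
    active = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
               FALSE, FALSE, TRUE),
    fsn = c("SNOMED CT Concept (SNOMED RT+CTV3)",
            "Clinical finding (finding)",
            "Primary malignant neoplasm of lung (disorder)",
            "Non-small cell lung cancer (disorder)",
            "Recurrent (qualifier value)",
            "Clinical course (attribute)",
            "Courses (qualifier value)",
            "Qualifier value (qualifier value)",
            "Lung structure (body structure)",
            "Retired lung cancer code (synthetic)",
            "Retired recurrence code (synthetic)",
            "Recurrent disease (synthetic)"),
    stringsAsFactors = FALSE)
  descriptions <- data.frame(
    concept_id = c("404684003", "93880001", "93880001", "254637007",
                   "254637007", "255227004", "263502005", "288524001",
                   "39607008", "990000103"),
    term = c("Clinical finding", "Primary malignant neoplasm of lung",
             "Lung cancer", "Non-small cell lung cancer", "NSCLC",
             "Recurrent", "Clinical course", "Courses", "Lung structure",
             "Recurrent disease"),
    is_fsn = rep(FALSE, 10),
    stringsAsFactors = FALSE)
  is_a <- data.frame(
    child_id = c("404684003", "93880001", "254637007", "263502005",
                 "288524001", "255227004", "362981000", "39607008",
                 "990000103"),
    parent_id = c("138875005", "404684003", "93880001", "138875005",
                  "362981000", "288524001", "138875005", "138875005",
                  "404684003"),
    stringsAsFactors = FALSE)
  substitutions <- data.frame(
    inactive_id = c("990000101", "990000102", "990000102"),
    replacement_id = c("254637007", "255227004", "288524001"),
    stringsAsFactors = FALSE)
  mrcm <- data.frame(attribute_id = "263502005", domain_id = "404684003",
                     range_id = "288524001", stringsAsFactors = FALSE)
  graph <- validate_terminology(
    new_terminology_graph(concepts, descriptions, is_a, substitutions, mrcm))
  write_terminology(graph, out_dir)
  utils::write.table(
    data.frame(term = "recurrence", conceptId = "255227004"),
    file.path(out_dir, "custom_dict.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, fileEncoding = "UTF-8")
  invisible(out_dir)
}

# Chart templates. Token heads are 1-based with 0 = root, as in CoNLL-U.
# `gold` holds one label per target and mode; `mention` rows tie token
# ranges to ground-truth concepts. At most one mention per template is
# perturbable: a phrase bounded on the left by another annotated concept
# and running to the end of the sentence, which is the configuration the
# recovery algorithm (maximal unannotated window) can always repair.
fixture_targets <- function() {
  c(lung_cancer = "93880001", nsclc = "254637007", recurrence = "255227004",
    relation = "93880001:263502005=255227004")
}

chart_templates <- function() {
  g <- function(lc_i, lc_s, nsclc_i, nsclc_s, rec_i, rec_s, rel_i, rel_s) {
    list(`93880001` = c(implied = lc_i, strict = lc_s),
         `254637007` = c(implied = nsclc_i, strict = nsclc_s),
         `255227004` = c(implied = rec_i, strict = rec_s),
         `93880001:263502005=255227004` = c(implied = rel_i, strict = rel_s))
  }
  mention <- function(tokens, concept_id, canonical, perturbable = FALSE) {
    list(tokens = tokens, concept_id = concept_id, canonical = canonical,
         perturbable = perturbable)
  }
  list(
    flagship = list(
      category = "positive",
      tokens = c("This", "patient", "is", "diagnosed", "with", "recurrent",
                 "nonsmall", "cell", "lung", "cancer"),
      heads = c(2L, 4L, 4L, 0L, 4L, 10L, 10L, 10L, 10L, 5L),
      labels = c("det", "nsubj", "aux", "root", "prep", "amod", "amod",
                 "nn", "nn", "pobj"),
      mentions = list(
        mention(6L, "255227004", "recurrent"),
        mention(7:10, "254637007", "non-small cell lung cancer")),
      relations = "254637007:263502005=255227004",
      gold = g("positive", "positive", "positive", "positive",
               "positive", "positive", "positive", "positive")),
    recurrent_nsclc = list(
      category = "positive",
      tokens = c("She", "presented", "with", "recurrent", "non-small",
                 "cell", "lung", "cancer"),
      heads = c(2L, 0L, 2L, 8L, 8L, 8L, 8L, 3L),
      labels = c("nsubj", "root", "prep", "amod", "amod", "nn", "nn",
                 "pobj"),
      mentions = list(
        mention(4L, "255227004", "recurrent"),
        mention(5:8, "254637007", "non-small cell lung cancer",
                perturbable = TRUE)),
      relations = "254637007:263502005=255227004",
      gold = g("positive", "positive", "positive", "positive",
               "positive", "positive", "positive", "positive")),
    plain_nsclc = list(
      category = "positive",
      tokens = c("The", "patient", "has", "non-small", "cell", "lung",
                 "cancer", "."),
      heads = c(2L, 3L, 0L, 7L, 7L, 7L, 3L, 3L),
      labels = c("det", "nsubj", "root", "amod", "nn", "nn", "dobj",
                 "punct"),
      mentions = list(
        mention(4:7, "254637007", "non-small cell lung cancer")),
      relations = character(),
      gold = g("positive", "positive", "positive", "positive",
               "not_listed", "not_listed", "not_listed", "not_listed")),
    recurrence_of = list(
      category = "positive",
      tokens = c("Imaging", "confirms", "recurrence", "of", "lung",
                 "cancer", "."),
      heads = c(2L, 0L, 2L, 3L, 6L, 4L, 2L),
      labels = c("nsubj", "root", "dobj", "prep", "nn", "pobj", "punct"),
      mentions = list(
        mention(3L, "255227004", "recurrence"),
        mention(5:6, "93880001", "lung cancer")),
      relations = character(),
      gold = g("positive", "positive", "not_listed", "not_listed",
               "positive", "positive", "positive", "not_listed")),
    recurrent_lc = list(
      category = "positive",
      tokens = c("Recurrent", "lung", "cancer", "was", "treated", "."),
      heads = c(3L, 3L, 5L, 5L, 0L, 5L),
      labels = c("amod", "nn", "nsubj", "aux", "root", "punct"),
      mentions = list(
        mention(1L, "255227004", "recurrent"),
        mention(2:3, "93880001", "lung cancer")),
      relations = "93880001:263502005=255227004",
      gold = g("positive", "positive", "not_listed", "not_listed",
               "positive", "positive", "positive", "positive")),
    no_recurrence = list(
      category = "negative",
      tokens = c("There", "is", "no", "evidence", "of", "recurrence", "."),
      heads = c(2L, 0L, 4L, 2L, 4L, 5L, 2L),
      labels = c("expl", "root", "det", "nsubj", "prep", "pobj", "punct"),
      mentions = list(mention(6L, "255227004", "recurrence")),
      relations = character(),
      gold = g("not_listed", "not_listed", "not_listed", "not_listed",
               "negative", "not_listed", "not_listed", "not_listed")),
    vitals = list(
      category = "not_listed",
      tokens = c("Blood", "pressure", "is", "stable", "today", "."),
      heads = c(2L, 4L, 4L, 0L, 4L, 4L),
      labels = c("nn", "nsubj", "cop", "root", "npadvmod", "punct"),
      mentions = list(),
      relations = character(),
      gold = g("not_listed", "not_listed", "not_listed", "not_listed",
               "not_listed", "not_listed", "not_listed", "not_listed")),
    denies_pain = list(
      category = "not_listed",
      tokens = c("Patient", "denies", "chest", "pain", "."),
      heads = c(2L, 0L, 4L, 2L, 2L),
      labels = c("nsubj", "root", "nn", "dobj", "punct"),
      mentions = list(),
      relations = character(),
      gold = g("not_listed", "not_listed", "not_listed", "not_listed",
               "not_listed", "not_listed", "not_listed", "not_listed"))
  )
}

# Join tokens with spaces, attaching sentence-final punctuation directly.
detokenize <- function(tokens) {
  out <- tokens[1]
  for (k in seq_along(tokens)[-1]) {
    sep <- if (tokens[k] %in% c(".", ",", ";", ":", "!", "?")) "" else " "
    out <- paste0(out, sep, tokens[k])
  }
  out
}

conllu_text <- function(tokens, heads, labels) {
  rows <- sprintf("%d\t%s\t_\t_\t_\t_\t%d\t%s\t_\t_",
                  seq_along(tokens), tokens, heads, labels)
  paste0(paste(rows, collapse = "\n"), "\n")
}

# Apply n_edits random single-character deletions/insertions to the token
# strings of a mention. The first character of the mention is never
# touched, single-character tokens are never deleted away, and token
# boundaries are preserved (edits happen inside tokens), so the dependency
# parse stays valid.
perturb_tokens <- function(tokens, n_edits) {
  for (e in seq_len(n_edits)) {
    op <- sample(c("delete", "insert"), 1)
    if (op == "delete") {
      cand <- do.call(rbind, lapply(seq_along(tokens), function(ti) {
        nc <- nchar(tokens[ti])
        if (nc < 2) return(NULL)
        pos <- seq_len(nc)
        if (ti == 1) pos <- pos[-1]
        if (!length(pos)) return(NULL)
        cbind(ti, pos)
      }))
      if (is.null(cand)) next
      pick <- cand[sample(nrow(cand), 1), ]
      tk <- tokens[pick[1]]
      tokens[pick[1]] <- paste0(substr(tk, 1, pick[2] - 1),
                                substr(tk, pick[2] + 1, nchar(tk)))
    } else {
      cand <- do.call(rbind, lapply(seq_along(tokens), function(ti) {
        pos <- seq_len(nchar(tokens[ti]) + 1L)
        if (ti == 1) pos <- pos[-1]
        cbind(ti, pos)
      }))
      pick <- cand[sample(nrow(cand), 1), ]
      ch <- sample(letters, 1)
      tk <- tokens[pick[1]]
      tokens[pick[1]] <- paste0(substr(tk, 1, pick[2] - 1), ch,
                                substr(tk, pick[2], nchar(tk)))
    }
  }
  tokens
}

#' Generate synthetic charts with parses, misspellings and gold labels
#'
#' Instantiates templated oncology sentences (chart 0 is always the
#' flagship sentence "This patient is diagnosed with recurrent nonsmall
#' cell lung cancer"), writes one plain-text file and one CoNLL-U parse
#' per chart, a `gold_labels.tsv` with implied and strict chart labels for
#' the three concept targets and the recurrent-lung-cancer relation
#' target, and a `ground_truth.jsonl` recording the generating mentions,
#' relations and injected misspellings. Misspellings are injected into
#' perturbable mentions with probability `misspell_rate`; the number of
#' character edits is `max(1, floor(max_edit_fraction * nchar(term)))`, and
#' the first character of a term is never perturbed. Fully seeded: the same
#' `fixture_spec` yields byte-identical files.
#'
#' @param spec a [fixture_spec()].
#' @param terminology a `terminology_graph` (used to sanity-check mention
#'   concepts).
#' @param out_dir writable output directory.
#' @return invisibly, a list with the per-chart manifest data frame.
#' @export
generate_charts <- function(spec, terminology, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"),
            inherits(terminology, "terminology_graph"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(spec$seed)

  templates <- chart_templates()
  for (tp in templates) {
    for (mn in tp$mentions) check_known(terminology, mn$concept_id)
  }
  pools <- split(names(templates),
                 vapply(templates, `[[`, character(1), "category"))
  cats <- names(spec$label_mix)

  gold_rows <- list()
  truth_lines <- character()
  manifest <- list()
  for (ci in seq_len(spec$n_charts) - 1L) {
    if (ci == 0L) {
      tname <- "flagship"
    } else {
      cat_pick <- sample(cats, 1, prob = spec$label_mix)
      tname <- sample(pools[[cat_pick]], 1)
    }
    tp <- templates[[tname]]
    tokens <- tp$tokens
    perturbed <- list()
    for (mn in tp$mentions) {
      if (isTRUE(mn$perturbable) && stats::runif(1) < spec$misspell_rate) {
        n_edits <- max(1L, floor(spec$max_edit_fraction *
                                   nchar(mn$canonical)))
        # within the matcher's margin the corruption must stay recoverable;
        # resample edit positions that happen to fall below the threshold
        within_margin <- spec$max_edit_fraction <= 0.05
        for (try in 1:50) {
          new_toks <- perturb_tokens(tokens[mn$tokens], n_edits)
          mention_text <- paste(new_toks, collapse = " ")
          sim <- similarity_percent(mention_text, mn$canonical)
          if (!within_margin || sim >= 95) break
        }
        tokens[mn$tokens] <- new_toks
        perturbed[[length(perturbed) + 1L]] <- list(
          canonical = mn$canonical, text = mention_text, similarity = sim)
      }
    }
    chart_id <- sprintf("chart_%03d", ci)
    writeLines(detokenize(tokens), file.path(out_dir,
                                             paste0(chart_id, ".txt")),
               useBytes = TRUE)
    cat(conllu_text(tokens, tp$heads, tp$labels),
        file = file.path(out_dir, paste0(chart_id, ".conllu")))
    for (tg in names(tp$gold)) {
      for (md in c("implied", "strict")) {
        gold_rows[[length(gold_rows) + 1L]] <- data.frame(
          chartId = chart_id, target = tg, mode = md,
          label = tp$gold[[tg]][[md]], stringsAsFactors = FALSE)
      }
    }
    truth_lines <- c(truth_lines, as.character(jsonlite::toJSON(list(
      chartId = chart_id, template = tname,
      concepts = vapply(tp$mentions, `[[`, character(1), "concept_id"),
      relations = tp$relations,
      perturbed = perturbed), auto_unbox = TRUE, digits = NA)))
    manifest[[length(manifest) + 1L]] <- data.frame(
      chart_id = chart_id, template = tname,
      n_perturbed = length(perturbed), stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, gold_rows),
                     file.path(out_dir, "gold_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  writeLines(truth_lines, file.path(out_dir, "ground_truth.jsonl"),
             useBytes = TRUE)
  invisible(list(manifest = do.call(rbind, manifest)))
}
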