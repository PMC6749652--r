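# End-to-end workflow: annotate each chart by dictionary lookup, filter,
# recover misspelled mentions, extract dependency-based concept relations,
# qualify them with MRCM attributes, and predict chart-level labels; then
# score predictions against gold labels.

#' Pipeline configuration
#'
#' @param terminology_dir directory with the RF2-lite terminology files.
#' @param charts_dir directory with `chart_*.txt` documents and matching
#'   `chart_*.conllu` parses (a chart without a parse is tokenized without
#'   dependency edges, so no relations are extracted for it).
#' @param out_dir output directory for artifacts.
#' @param custom_dict_path custom dictionary TSV, or `NULL`; defaults to
#'   `custom_dict.tsv` inside `terminology_dir` when present.
#' @param targets concept SCTIDs and/or short-form expression templates to
#'   predict chart labels for.
#' @param fuzzy a [fuzzy_config()].
#' @param fuzzy_enabled run the misspelled-mention recovery stage; with
#'   `FALSE` the pipeline degrades to pure dictionary lookup.
#' @param relations a [relation_config()].
#' @param seed integer seed recorded with the run.
#' @param name implementation label written into metrics output.
#' @param log_level one of `"quiet"`, `"info"`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(terminology_dir, charts_dir, out_dir,
                            custom_dict_path = NULL,
                            targets = c("93880001", "254637007", "255227004",
                                        "93880001:263502005=255227004"),
                            fuzzy = fuzzy_config(), fuzzy_enabled = TRUE,
                            relations = relation_config(), seed = 1,
                            name = "pipeline", log_level = "info") {
  if (is.null(custom_dict_path)) {
    cand <- file.path(terminology_dir, "custom_dict.tsv")
    if (file.exists(cand)) custom_dict_path <- cand
  }
  structure(list(terminology_dir = terminology_dir, charts_dir = charts_dir,
                 out_dir = out_dir, custom_dict_path = custom_dict_path,
                 targets = targets, fuzzy = fuzzy,
                 fuzzy_enabled = fuzzy_enabled, relations = relations,
                 seed = as.integer(seed), name = name,
                 log_level = log_level),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; `fuzzy` and
#' `relations` may be nested maps with `threshold_percent` / `case_fold`
#' and `allowed_labels` / `include_npadvmod`.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  fz <- do.call(fuzzy_config, y$fuzzy %||% list())
  rl <- do.call(relation_config, y$relations %||% list())
  pipeline_config(
    terminology_dir = y$terminology_dir, charts_dir = y$charts_dir,
    out_dir = y$out_dir, custom_dict_path = y$custom_dict_path,
    targets = unlist(y$targets) %||% eval(formals(pipeline_config)$targets),
    fuzzy = fz, fuzzy_enabled = y$fuzzy_enabled %||% TRUE,
    relations = rl, seed = y$seed %||% 1,
    name = y$name %||% "pipeline", log_level = y$log_level %||% "info")
}

pipe_log <- function(config, fmt, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf(fmt, ...))
}

#' Read gold chart labels
#'
#' @param path `gold_labels.tsv` with columns `chartId`, `target`, `mode`,
#'   `label`.
#' @return data frame with columns `chart_id`, `target`, `mode`, `label`.
#' @export
read_gold_labels <- function(path) {
  df <- read_tsv_cols(path, c("chartId", "target", "mode", "label"))
  data.frame(chart_id = df$chartId, target = df$target, mode = df$mode,
             label = df$label, stringsAsFactors = FALSE)
}

#' Run the full annotation pipeline over a chart directory
#'
#' Per chart: dictionary annotation, concept filtering, fuzzy recovery of
#' misspelled mentions (when enabled), dependency-based relation
#' extraction, MRCM attribute qualification, and chart-label prediction
#' for each configured target. Artifacts written to `out_dir`:
#' `annotations.jsonl`, `relations.jsonl`, `expressions.tsv`,
#' `predictions.tsv`, and — when `gold_labels.tsv` exists in `charts_dir` —
#' `metrics.csv` with precision/recall/F1 per target and mode. Two runs
#' with identical configuration and inputs produce byte-identical outputs.
#'
#' @param config a [pipeline_config()] (or path handled by
#'   [read_pipeline_config()]).
#' @return invisibly, a list with `annotations`, `relations`,
#'   `expressions`, `predictions`, `metrics` (or `NULL`), and the loaded
#'   `graph`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  graph <- load_terminology(config$terminology_dir)
  custom <- if (!is.null(config$custom_dict_path)) {
    read_custom_dict(config$custom_dict_path)
  }
  index <- build_description_index(graph, custom)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  chart_files <- sort(list.files(config$charts_dir,
                                 pattern = "^chart_.*\\.txt$"))
  all_ann <- list()
  all_rel <- list()
  all_expr <- list()
  all_pred <- list()
  for (cf in chart_files) {
    chart_id <- sub("\\.txt$", "", cf)
    text <- paste(readLines(file.path(config$charts_dir, cf),
                            encoding = "UTF-8", warn = FALSE),
                  collapse = "\n")
    conllu <- file.path(config$charts_dir, paste0(chart_id, ".conllu"))
    sentences <- tryCatch({
      if (file.exists(conllu)) read_conllu(conllu, text) else tokenize(text)
    }, error = function(e) {
      stop(sprintf("%s: %s", chart_id, conditionMessage(e)), call. = FALSE)
    })
    raw <- annotate_dictionary(sentences, index)
    report <- filter_annotations(raw, graph)
    ann <- report$kept
    if (config$fuzzy_enabled) {
      recovered <- recover_unmatched(sentences, ann, index,
                                     config$relations, config$fuzzy)
      if (nrow(recovered)) {
        # a recovered phrase may absorb a shorter dictionary match inside
        # it; the overlap filter resolves that in favour of the longer term
        ann <- filter_annotations(rbind(ann, recovered), graph)$kept
      }
    }
    rel <- extract_relations(sentences, ann, config$relations)
    expr <- detect_attribute_relations(rel, graph)
    expr_str <- if (nrow(expr)) {
      vapply(seq_len(nrow(expr)), function(k) {
        serialize_expression(expr[k, ])
      }, character(1))
    } else {
      character()
    }
    preds <- vapply(config$targets, function(tg) {
      predict_chart_label(ann$concept_id, expr_str, tg, graph)
    }, character(1))
    pipe_log(config,
             "%s: %d raw, %d kept, %d relations, %d expressions",
             chart_id, nrow(raw), nrow(ann), nrow(rel), nrow(expr))
    if (nrow(ann)) all_ann[[chart_id]] <- cbind(chart_id = chart_id, ann)
    if (nrow(rel)) all_rel[[chart_id]] <- cbind(chart_id = chart_id, rel)
    if (length(expr_str)) {
      all_expr[[chart_id]] <- data.frame(chart_id = chart_id,
                                         expression = unique(expr_str),
                                         stringsAsFactors = FALSE)
    }
    all_pred[[chart_id]] <- data.frame(chart_id = chart_id,
                                       target = config$targets,
                                       label = unname(preds),
                                       stringsAsFactors = FALSE)
  }
  bind <- function(lst, empty) {
    if (length(lst)) do.call(rbind, c(lst, list(make.row.names = FALSE)))
    else empty
  }
  annotations <- bind(all_ann, cbind(chart_id = character(),
                                     empty_annotations()))
  rel_all <- bind(all_rel, cbind(chart_id = character(), empty_relations()))
  expr_all <- bind(all_expr, data.frame(chart_id = character(),
                                        expression = character(),
                                        stringsAsFactors = FALSE))
  pred_all <- bind(all_pred, data.frame(chart_id = character(),
                                        target = character(),
                                        label = character(),
                                        stringsAsFactors = FALSE))
  write_annotations_jsonl(annotations,
                          file.path(config$out_dir, "annotations.jsonl"))
  write_relations_jsonl(rel_all,
                        file.path(config$out_dir, "relations.jsonl"))
  utils::write.table(expr_all, file.path(config$out_dir, "expressions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  utils::write.table(data.frame(chartId = pred_all$chart_id,
                                target = pred_all$target,
                                label = pred_all$label),
                     file.path(config$out_dir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")

  metrics_df <- NULL
  gold_path <- file.path(config$charts_dir, "gold_labels.tsv")
  if (file.exists(gold_path)) {
    gold <- read_gold_labels(gold_path)
    metrics_df <- evaluate_predictions(pred_all, gold,
                                       implementation = config$name)
    utils::write.csv(metrics_df, file.path(config$out_dir, "metrics.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(list(annotations = annotations, relations = rel_all,
                 expressions = expr_all, predictions = pred_all,
                 metrics = metrics_df, graph = graph))
}

write_relations_jsonl <- function(rel, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (k in seq_len(nrow(rel))) {
    writeLines(jsonlite::toJSON(list(
      chartId = rel$chart_id[k],
      sourceConceptId = rel$source_concept[k],
      destConceptId = rel$dest_concept[k],
      label = rel$label[k],
      sentenceIndex = rel$sentence_index[k],
      sourceSpan = c(rel$source_start[k], rel$source_end[k]),
      destSpan = c(rel$dest_start[k], rel$dest_end[k])),
      auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Score chart-label predictions against a gold standard
#'
#' @param predictions data frame with columns `chart_id`, `target`,
#'   `label`.
#' @param gold data frame from [read_gold_labels()].
#' @param implementation label for the output rows.
#' @param modes gold modes to evaluate.
#' @return data frame with one row per (target, mode): confusion counts
#'   and precision/recall/F1.
#' @export
evaluate_predictions <- function(predictions, gold,
                                 implementation = "pipeline",
                                 modes = c("implied", "strict")) {
  out <- list()
  for (tg in unique(gold$target)) {
    pred_t <- predictions[predictions$target == tg, , drop = FALSE]
    if (!nrow(pred_t)) next
    for (md in modes) {
      gold_t <- gold[gold$target == tg & gold$mode == md, , drop = FALSE]
      if (!nrow(gold_t)) next
      cm <- confusion(pred_t, gold_t, mode = md)
      mt <- metrics(cm)
      out[[length(out) + 1L]] <- data.frame(
        implementation = implementation, concept = tg, mode = md,
        tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
        precision = mt$precision, recall = mt$recall, f1 = mt$f1,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Compare two prediction sets with the paired permutation test
#'
#' @param pred_a,pred_b prediction data frames (columns `chart_id`,
#'   `target`, `label`) from two pipeline runs over the same charts.
#' @param gold gold standard from [read_gold_labels()].
#' @param targets targets to compare (default: all in `gold`).
#' @param mode gold mode.
#' @param n_permutations,seed passed to [permutation_test()].
#' @return data frame with one row per target: observed |dF1| and p-value.
#' @export
compare_runs <- function(pred_a, pred_b, gold, targets = NULL,
                         mode = "implied", n_permutations = 10000,
                         seed = 1) {
  targets <- targets %||% unique(gold$target)
  out <- list()
  for (tg in targets) {
    gold_t <- gold[gold$target == tg & gold$mode == mode, , drop = FALSE]
    oa <- chart_outcomes(pred_a[pred_a$target == tg, , drop = FALSE],
                         gold_t, mode)
    ob <- chart_outcomes(pred_b[pred_b$target == tg, , drop = FALSE],
                         gold_t, mode)
    pt <- permutation_test(oa, ob, n_permutations = n_permutations,
                           seed = seed)
    out[[length(out) + 1L]] <- data.frame(
      concept = tg, mode = mode, observed_dF1 = pt$observed_stat,
      p_value = pt$p_value,
      n_permutations = as.character(pt$n_permutations), seed = seed,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
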