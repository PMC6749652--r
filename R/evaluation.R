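# Chart-level labelling, confusion counting, precision/recall/F1, and the
# paired two-tailed permutation test used to compare annotation pipelines
# on the same chart set.

#' Predict the chart-level label for a target
#'
#' A chart is `positive` for a concept target when any detected concept is
#' the target or one of its descendants (a detected non-small cell lung
#' cancer makes the chart positive for primary malignant neoplasm of lung).
#' For a relation target (a short-form expression), the chart is positive
#' when some detected expression has a focus subsumed by the target focus,
#' the same attribute, and a value subsumed by the target value. Otherwise
#' the prediction is `not_listed`. The `negative` label exists only in gold
#' standards (explicit absence statements); predicting it would require
#' negation detection, which this pipeline does not attempt.
#'
#' @param concepts character vector of detected concept SCTIDs for one
#'   chart.
#' @param expressions character vector of detected short-form expressions
#'   for the same chart.
#' @param target a concept SCTID or a short-form expression template such
#'   as `"93880001:263502005=255227004"`.
#' @param graph a `terminology_graph`.
#' @return `"positive"` or `"not_listed"`.
#' @export
predict_chart_label <- function(concepts, expressions, target, graph) {
  stopifnot(inherits(graph, "terminology_graph"))
  if (grepl(":", target, fixed = TRUE)) {
    tg <- parse_expression(target)
    check_known(graph, c(tg$focus_id, tg$attribute_id, tg$value_id))
    for (e in expressions) {
      ex <- parse_expression(e)
      if (ex$attribute_id == tg$attribute_id &&
          subsumes(graph, tg$focus_id, ex$focus_id) &&
          subsumes(graph, tg$value_id, ex$value_id)) {
        return("positive")
      }
    }
    return("not_listed")
  }
  check_known(graph, target)
  for (cid in unique(concepts)) {
    if (subsumes(graph, target, cid)) return("positive")
  }
  "not_listed"
}

#' Confusion counts from chart-level predictions
#'
#' Counts over charts: `tp` gold-positive and predicted positive, `fp` gold
#' not-positive and predicted positive, `fn` gold-positive and predicted
#' not-positive, `tn` the remainder. Gold `negative` charts (explicit
#' absence) count as not-positive.
#'
#' @param predictions data frame with columns `chart_id`, `label`.
#' @param gold data frame with columns `chart_id`, `label`, and optionally
#'   `mode`; when `mode` is present only rows matching the `mode` argument
#'   are used.
#' @param mode `"implied"` or `"strict"` gold labelling.
#' @return an object of class `confusion_counts` (fields `tp`, `fp`, `fn`,
#'   `tn`).
#' @export
confusion <- function(predictions, gold, mode = "implied") {
  g <- gold
  if ("mode" %in% names(g)) g <- g[g$mode == mode, , drop = FALSE]
  if (anyDuplicated(g$chart_id) || anyDuplicated(predictions$chart_id)) {
    stop("alignment error: duplicate chart ids", call. = FALSE)
  }
  if (!setequal(g$chart_id, predictions$chart_id)) {
    stop("alignment error: prediction and gold chart ids differ",
         call. = FALSE)
  }
  pred <- predictions$label[match(g$chart_id, predictions$chart_id)]
  gold_pos <- g$label == "positive"
  pred_pos <- pred == "positive"
  structure(list(tp = sum(gold_pos & pred_pos),
                 fp = sum(!gold_pos & pred_pos),
                 fn = sum(gold_pos & !pred_pos),
                 tn = sum(!gold_pos & !pred_pos)),
            class = "confusion_counts")
}

#' Harmonic-mean F1 from precision and recall
#'
#' `2·P·R/(P+R)`, defined as 0 when `P + R` is 0.
#'
#' @param precision,recall numeric vectors in \[0, 1\].
#' @return numeric vector of F1 scores.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, and F1 their harmonic
#' mean; every 0/0 is defined as 0 (a pipeline detecting nothing scores
#' 0.000 across the board).
#'
#' @param counts a `confusion_counts` object, or any list with `tp`, `fp`,
#'   `fn`.
#' @return an object of class `metrics_result` (fields `precision`,
#'   `recall`, `f1`).
#' @export
metrics <- function(counts) {
  tp <- counts$tp
  precision <- if (tp + counts$fp == 0) 0 else tp / (tp + counts$fp)
  recall <- if (tp + counts$fn == 0) 0 else tp / (tp + counts$fn)
  structure(list(precision = precision, recall = recall,
                 f1 = f1_score(precision, recall)),
            class = "metrics_result")
}

#' @export
print.metrics_result <- function(x, ...) {
  cat(sprintf("precision %.3f, recall %.3f, F1 %.3f\n",
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' Per-chart confusion contributions
#'
#' Expands chart-level predictions against a gold standard into one row per
#' chart with 0/1 `tp`, `fp`, `fn` contributions — the pairing unit of
#' [permutation_test()].
#'
#' @inheritParams confusion
#' @return data frame with columns `chart_id`, `tp`, `fp`, `fn`, ordered by
#'   `chart_id`.
#' @export
chart_outcomes <- function(predictions, gold, mode = "implied") {
  g <- gold
  if ("mode" %in% names(g)) g <- g[g$mode == mode, , drop = FALSE]
  if (!setequal(g$chart_id, predictions$chart_id)) {
    stop("alignment error: prediction and gold chart ids differ",
         call. = FALSE)
  }
  g <- g[order(g$chart_id), , drop = FALSE]
  pred <- predictions$label[match(g$chart_id, predictions$chart_id)]
  gold_pos <- g$label == "positive"
  pred_pos <- pred == "positive"
  data.frame(chart_id = g$chart_id,
             tp = as.integer(gold_pos & pred_pos),
             fp = as.integer(!gold_pos & pred_pos),
             fn = as.integer(gold_pos & !pred_pos),
             stringsAsFactors = FALSE, row.names = NULL)
}

# F1 from summed (tp, fp, fn) contribution columns; algebraically
# 2TP/(2TP+FP+FN), which equals the harmonic mean of precision and recall
# and inherits the 0/0 -> 0 convention.
f1_from_sums <- function(s) {
  denom <- 2 * s[, 1] + s[, 2] + s[, 3]
  ifelse(denom == 0, 0, 2 * s[, 1] / denom)
}

#' Paired two-tailed permutation test on an F1 difference
#'
#' Compares two pipelines evaluated on the same charts. The statistic is
#' the absolute difference of the two F1 scores, each computed from summed
#' per-chart TP/FP/FN contributions. The null distribution swaps, per
#' chart, which pipeline produced which outcome (paired label swap). All
#' `2^n` swap assignments are enumerated exactly when `n <= 20`; otherwise
#' `n_permutations` Monte Carlo draws are taken with the given seed and the
#' p-value uses +1 smoothing, `(count + 1)/(n_permutations + 1)`, so it is
#' never exactly 0. Exact mode reports the true proportion (which includes
#' the identity swap, so it is still positive).
#'
#' @param outcomes_a,outcomes_b data frames with per-chart `tp`, `fp`, `fn`
#'   columns (see [chart_outcomes()]), covering the same charts in the same
#'   order.
#' @param n_permutations Monte Carlo draws when exact enumeration is not
#'   used.
#' @param seed integer seed for Monte Carlo mode.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   default `NULL` enumerates exactly when `n <= 20`.
#' @return an object of class `permutation_result` (fields `p_value`,
#'   `n_permutations` — the string `"exact"` in exact mode —,
#'   `observed_stat`, `seed`).
#' @export
permutation_test <- function(outcomes_a, outcomes_b, n_permutations = 10000,
                             seed = 1, exact = NULL) {
  A <- as.matrix(outcomes_a[, c("tp", "fp", "fn")])
  B <- as.matrix(outcomes_b[, c("tp", "fp", "fn")])
  if (nrow(A) != nrow(B)) {
    stop("alignment error: outcome vectors differ in length", call. = FALSE)
  }
  if ("chart_id" %in% names(outcomes_a) && "chart_id" %in% names(outcomes_b) &&
      !identical(outcomes_a$chart_id, outcomes_b$chart_id)) {
    stop("alignment error: outcome vectors cover different charts",
         call. = FALSE)
  }
  n <- nrow(A)
  tot_a <- matrix(colSums(A), 1)
  tot_b <- matrix(colSums(B), 1)
  obs <- abs(f1_from_sums(tot_a) - f1_from_sums(tot_b))
  delta <- A - B
  use_exact <- exact %||% (n <= 20)
  stat_for <- function(S) {
    # S: draws x n matrix of 0/1 swap indicators
    moved <- S %*% delta
    a2 <- matrix(rep(tot_a, nrow(S)), ncol = 3, byrow = TRUE) - moved
    b2 <- matrix(rep(tot_b, nrow(S)), ncol = 3, byrow = TRUE) + moved
    abs(f1_from_sums(a2) - f1_from_sums(b2))
  }
  eps <- 1e-12
  if (use_exact) {
    total <- 2^n
    count <- 0
    chunk <- 65536L
    from <- 0
    while (from < total) {
      idx <- from:min(total - 1, from + chunk - 1)
      S <- vapply(idx, function(m) as.integer(intToBits(m)[1:n]), integer(n))
      if (is.null(dim(S))) S <- matrix(S, nrow = n)
      S <- t(S)
      count <- count + sum(stat_for(S) >= obs - eps)
      from <- from + chunk
    }
    p <- count / total
    res <- list(p_value = p, n_permutations = "exact", observed_stat = obs,
                seed = seed)
  } else {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                       .GlobalEnv)
    set.seed(seed)
    S <- matrix(sample(c(0L, 1L), n * n_permutations, replace = TRUE),
                nrow = n_permutations, ncol = n)
    count <- sum(stat_for(S) >= obs - eps)
    p <- (count + 1) / (n_permutations + 1)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    res <- list(p_value = p, n_permutations = n_permutations,
                observed_stat = obs, seed = seed)
  }
  structure(res, class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("paired permutation test: |dF1| = %.4f, p = %.4g (%s)\n",
              x$observed_stat, x$p_value,
              if (identical(x$n_permutations, "exact")) "exact enumeration"
              else sprintf("%d Monte Carlo draws, seed %d",
                           x$n_permutations, x$seed)))
  invisible(x)
}
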