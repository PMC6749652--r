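# The concept filter: resolve inactive concepts to their substitutes, keep
# only the longest term among overlapping annotations, collapse duplicates,
# and keep the most detailed concept when a parent and child annotate the
# same span. Rules apply in that fixed order.

#' Filter competing concept annotations
#'
#' Applies four rules in order:
#' \enumerate{
#'   \item activity resolution — each annotation of an inactive concept is
#'     replaced by one annotation per substitute concept (same span); the
#'     original is dropped with reason `inactive_replaced`;
#'   \item overlap resolution — an annotation overlapping a strictly longer
#'     one (span length in characters) is dropped with reason
#'     `shorter_overlap`; equal-length overlapping spans are both kept by
#'     default;
#'   \item per-span deduplication — identical (span, concept) pairs collapse
#'     to one (reason `duplicate`);
#'   \item detail refinement — when two surviving annotations share a span
#'     and one concept strictly subsumes the other, only the descendant
#'     survives (reason `less_detailed` for the ancestor).
#' }
#' The filter is idempotent: running it on its own `kept` output changes
#' nothing.
#'
#' @param annotations annotation data frame (`start`, `end`, `concept_id`,
#'   `term`, `source`, `similarity`).
#' @param graph a `terminology_graph`; all annotation concept ids must
#'   exist in it.
#' @param keep_equal_length_ties keep equal-length overlapping annotations
#'   of different concepts (default `TRUE`); when `FALSE`, only the lowest
#'   SCTID among an equal-length overlapping group survives.
#' @return an object of class `filter_report`: list with `kept` (sorted by
#'   start, end, SCTID) and `dropped` (annotations plus a `reason` column).
#' @export
filter_annotations <- function(annotations, graph,
                               keep_equal_length_ties = TRUE) {
  stopifnot(inherits(graph, "terminology_graph"))
  ann <- annotations
  check_known(graph, unique(ann$concept_id))
  dropped <- cbind(empty_annotations(),
                   data.frame(reason = character(), stringsAsFactors = FALSE))
  drop_rows <- function(rows, reason) {
    if (nrow(rows)) {
      rows$reason <- reason
      dropped <<- rbind(dropped, rows)
    }
  }

  # 1. activity resolution
  if (nrow(ann)) {
    active_ids <- graph$concepts$concept_id[graph$concepts$active]
    inactive <- !(ann$concept_id %in% active_ids)
    if (any(inactive)) {
      repl <- list()
      for (k in which(inactive)) {
        subs <- resolve_active(graph, ann$concept_id[k])
        if (length(subs)) {
          r <- ann[rep(k, length(subs)), , drop = FALSE]
          r$concept_id <- subs
          repl[[length(repl) + 1L]] <- r
        }
      }
      drop_rows(ann[inactive, , drop = FALSE], "inactive_replaced")
      ann <- rbind(ann[!inactive, , drop = FALSE],
                   if (length(repl)) do.call(rbind, repl))
    }
  }

  # 2. overlap resolution (single simultaneous pass over the current set)
  if (nrow(ann) > 1) {
    len <- ann$end - ann$start
    doomed <- logical(nrow(ann))
    for (k in seq_len(nrow(ann))) {
      ov <- spans_overlap(ann$start[k], ann$end[k], ann$start, ann$end)
      ov[k] <- FALSE
      if (any(ov & len > len[k])) {
        doomed[k] <- TRUE
      } else if (!keep_equal_length_ties &&
                 any(ov & len == len[k] &
                     (nchar(ann$concept_id) < nchar(ann$concept_id[k]) |
                      (nchar(ann$concept_id) == nchar(ann$concept_id[k]) &
                       ann$concept_id < ann$concept_id[k])))) {
        doomed[k] <- TRUE
      }
    }
    drop_rows(ann[doomed, , drop = FALSE], "shorter_overlap")
    ann <- ann[!doomed, , drop = FALSE]
  }

  # 3. per-span deduplication
  if (nrow(ann) > 1) {
    dup <- duplicated(ann[c("start", "end", "concept_id")])
    drop_rows(ann[dup, , drop = FALSE], "duplicate")
    ann <- ann[!dup, , drop = FALSE]
  }

  # 4. detail refinement: same span, strict ancestor loses
  if (nrow(ann) > 1) {
    doomed <- logical(nrow(ann))
    for (k in seq_len(nrow(ann))) {
      same <- which(ann$start == ann$start[k] & ann$end == ann$end[k])
      for (m in setdiff(same, k)) {
        if (ann$concept_id[k] != ann$concept_id[m] &&
            subsumes(graph, ann$concept_id[k], ann$concept_id[m])) {
          doomed[k] <- TRUE
          break
        }
      }
    }
    drop_rows(ann[doomed, , drop = FALSE], "less_detailed")
    ann <- ann[!doomed, , drop = FALSE]
  }

  row.names(dropped) <- NULL
  structure(list(kept = sort_annotations(ann), dropped = dropped),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> kept %d, dropped %d", nrow(x$kept),
              nrow(x$dropped)))
  if (nrow(x$dropped)) {
    tab <- table(x$dropped$reason)
    cat(" (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
        ")", sep = "")
  }
  cat("\n")
  invisible(x)
}
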