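flagship_setup <- function() {
  text <- flagship_text()
  sents <- read_conllu(flagship_conllu(), text)
  ann <- filter_annotations(annotate_dictionary(sents, toy_index()),
                            toy_graph())$kept
  list(text = text, sents = sents, ann = ann)
}

test_that("fuzzy recovery finds the misspelled NSCLC phrase in the flagship sentence", {
  fs <- flagship_setup()
  rec <- recover_unmatched(fs$sents, fs$ann, toy_index())
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$concept_id, "254637007")
  expect_identical(rec$source, "fuzzy")
  expect_equal(rec$similarity, 25 / 25.5 * 100, tolerance = 1e-9)
  expect_identical(substr(fs$text, rec$start + 1L, rec$end),
                   "nonsmall cell lung cancer")
})

test_that("recovery does nothing when all edge tokens are annotated or misspellings exceed the margin", {
  g <- toy_graph()
  text <- "Recurrent lung cancer"
  sents <- tokenize(text)
  sents[[1]]$edges <- data.frame(governor = c(2L, 2L), dependent = c(0L, 1L),
                                 label = c("amod", "nn"))
  ann <- filter_annotations(annotate_dictionary(sents, toy_index()), g)$kept
  expect_identical(nrow(recover_unmatched(sents, ann, toy_index())), 0L)

  # >5% corruption of the full phrase: the phrase-level concept is not
  # recovered (sub-phrases within the margin of some other description may
  # still be, at a similarity the threshold licenses)
  text2 <- "recurrent smll cell lng cancer"
  s2 <- tokenize(text2)
  s2[[1]]$edges <- data.frame(governor = c(4L, 4L, 4L, 4L),
                              dependent = c(0L, 1L, 2L, 3L),
                              label = c("amod", "amod", "nn", "nn"))
  ann2 <- filter_annotations(annotate_dictionary(s2, toy_index()), g)$kept
  expect_identical(ann2$concept_id, "255227004")
  rec2 <- recover_unmatched(s2, ann2, toy_index())
  expect_false("254637007" %in% rec2$concept_id)
  expect_true(all(rec2$similarity >= 95))
  # direct check: the corrupted phrase stays below the threshold
  expect_lt(similarity_percent("smll cell lng cancer",
                               "non-small cell lung cancer"), 95)
})

combined_flagship_ann <- function(fs) {
  # mirror the pipeline: recovered phrases then pass the overlap filter,
  # which drops the shorter "lung cancer" match absorbed by the phrase
  filter_annotations(
    rbind(fs$ann, recover_unmatched(fs$sents, fs$ann, toy_index())),
    toy_graph())$kept
}

test_that("relations pair the modifier annotation with the governed annotation", {
  fs <- flagship_setup()
  ann <- combined_flagship_ann(fs)
  rel <- extract_relations(fs$sents, ann)
  expect_identical(nrow(rel), 1L)
  expect_identical(rel$source_concept, "255227004")
  expect_identical(rel$dest_concept, "254637007")
  expect_identical(rel$label, "amod")
})

test_that("edges with disallowed labels or unannotated endpoints yield no relations", {
  fs <- flagship_setup()
  ann <- combined_flagship_ann(fs)
  only_det <- relation_config(allowed_labels = "det")
  expect_identical(nrow(extract_relations(fs$sents, ann, only_det)), 0L)
  # governor token "with" (index 4) carries no annotation
  pobj_only <- relation_config(allowed_labels = "pobj")
  expect_identical(nrow(extract_relations(fs$sents, ann, pobj_only)), 0L)
})

test_that("enlarging the allowed label set never removes a relation", {
  fs <- flagship_setup()
  ann <- combined_flagship_ann(fs)
  labels <- c("amod", "nn", "nsubj", "pobj", "det", "aux")
  set.seed(501)
  for (k in 1:20) {
    small <- sample(labels, sample(1:3, 1))
    big <- unique(c(small, sample(labels, sample(1:4, 1))))
    rel_small <- extract_relations(fs$sents, ann,
                                   relation_config(allowed_labels = small))
    rel_big <- extract_relations(fs$sents, ann,
                                 relation_config(allowed_labels = big))
    key <- function(df) paste(df$source_concept, df$dest_concept,
                              df$sentence_index)
    expect_true(all(key(rel_small) %in% key(rel_big)))
  }
})

test_that("npadvmod participates only when enabled", {
  sents <- tokenize("pain worsens daily")
  sents[[1]]$edges <- data.frame(governor = 0L, dependent = 1L,
                                 label = "npadvmod")
  ann <- make_ann(c(0, 5), c(4, 12), c("255227004", "254637007"))
  expect_identical(nrow(extract_relations(sents, ann)), 0L)
  rel <- extract_relations(sents, ann,
                           relation_config(include_npadvmod = TRUE))
  expect_identical(nrow(rel), 1L)
})

test_that("attribute detection emits only MRCM-licensed expressions with the head as focus", {
  g <- toy_graph()
  rel <- data.frame(source_concept = "255227004",
                    dest_concept = "254637007",
                    source_start = 0L, source_end = 9L,
                    dest_start = 10L, dest_end = 35L,
                    label = "amod", sentence_index = 0L,
                    stringsAsFactors = FALSE)
  ex <- detect_attribute_relations(rel, g)
  expect_identical(ex$focus_id, "254637007")
  expect_identical(ex$attribute_id, "263502005")
  expect_identical(ex$value_id, "255227004")

  # reversed direction: qualifier as focus licenses nothing
  rel_rev <- rel
  rel_rev$source_concept <- "254637007"
  rel_rev$dest_concept <- "255227004"
  expect_identical(nrow(detect_attribute_relations(rel_rev, g)), 0L)
})

test_that("a pair licensed by two rules yields two expressions in ascending attribute order", {
  dir <- write_term_tsv(
    tempfile(),
    data.frame(id = c("1", "2", "3", "4", "990000201"), active = 1L,
               fsn = c("finding (synthetic)", "cancer (synthetic)",
                       "course root (synthetic)", "recurrent (synthetic)",
                       "extra attribute (synthetic)")),
    is_a = data.frame(childId = c("2", "4"), parentId = c("1", "3")),
    mrcm = data.frame(attributeId = c("990000201", "263502005"),
                      domainId = "1", rangeId = "3"))
  # note: 263502005 used as a plain id here must exist in this graph
  expect_error(load_terminology(dir), "263502005")
  dir <- write_term_tsv(
    tempfile(),
    data.frame(id = c("1", "2", "3", "4", "5", "6"), active = 1L,
               fsn = paste(c("finding", "cancer", "course root",
                             "recurrent", "attr a", "attr b"),
                           "(synthetic)")),
    is_a = data.frame(childId = c("2", "4"), parentId = c("1", "3")),
    mrcm = data.frame(attributeId = c("6", "5"), domainId = "1",
                      rangeId = "3"))
  g2 <- load_terminology(dir)
  rel <- data.frame(source_concept = "4", dest_concept = "2",
                    source_start = 0L, source_end = 1L, dest_start = 2L,
                    dest_end = 3L, label = "amod", sentence_index = 0L,
                    stringsAsFactors = FALSE)
  ex <- detect_attribute_relations(rel, g2)
  expect_identical(ex$attribute_id, c("5", "6"))
})

test_that("every emitted expression satisfies its MRCM rule", {
  fs <- flagship_setup()
  ann <- combined_flagship_ann(fs)
  rel <- extract_relations(fs$sents, ann)
  ex <- detect_attribute_relations(rel, toy_graph())
  expect_gt(nrow(ex), 0)
  for (k in seq_len(nrow(ex))) {
    expect_true(ex$attribute_id[k] %in%
                  attributes_linking(toy_graph(), ex$focus_id[k],
                                     ex$value_id[k]))
  }
})

test_that("expression serialization round-trips in short and long form", {
  e <- list(focus_id = "93880001", attribute_id = "263502005",
            value_id = "255227004")
  short <- serialize_expression(e)
  expect_identical(short, "93880001:263502005=255227004")
  expect_identical(parse_expression(short), e)
  long <- serialize_expression(e, toy_graph(), long = TRUE)
  expect_identical(
    long,
    paste("93880001 | Primary malignant neoplasm of lung (disorder) | :",
          "263502005 | Clinical course (attribute) | =",
          "255227004 | Recurrent (qualifier value) |"))
  expect_error(parse_expression("not-an-expression"), "parse error")
})
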