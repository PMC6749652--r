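test_that("chart labels are subsumption-aware for concept and relation targets", {
  g <- toy_graph()
  expect_identical(predict_chart_label("254637007", character(),
                                       "93880001", g), "positive")
  expect_identical(predict_chart_label(character(), character(),
                                       "93880001", g), "not_listed")
  expect_identical(
    predict_chart_label("255227004", "254637007:263502005=255227004",
                        "93880001:263502005=255227004", g),
    "positive")
  expect_identical(
    predict_chart_label("255227004", character(),
                        "93880001:263502005=255227004", g),
    "not_listed")
  expect_error(predict_chart_label("254637007", character(), "42", g),
               "unknown concept")
})

test_that("confusion counts follow the gold-positive / predicted-positive table", {
  charts <- sprintf("c%02d", 1:10)
  gold <- data.frame(chart_id = charts,
                     label = c("positive", "positive", "positive",
                               "positive", "negative", "negative",
                               "not_listed", "not_listed", "not_listed",
                               "not_listed"),
                     stringsAsFactors = FALSE)
  pred <- data.frame(chart_id = charts,
                     label = c("positive", "positive", "positive",
                               "not_listed", "positive", "not_listed",
                               "positive", "not_listed", "not_listed",
                               "not_listed"),
                     stringsAsFactors = FALSE)
  cm <- confusion(pred, gold)
  # hand enumeration: tp c1-c3, fn c4, fp c5 and c7, tn the rest
  expect_identical(cm$tp, 3L)
  expect_identical(cm$fp, 2L)
  expect_identical(cm$fn, 1L)
  expect_identical(cm$tn, 4L)

  perfect <- confusion(gold, gold)
  expect_identical(perfect$fp + perfect$fn, 0L)

  none <- pred
  none$label <- "not_listed"
  cm0 <- confusion(none, gold)
  expect_identical(cm0$tp, 0L)
  expect_identical(cm0$fn, 4L)

  expect_error(confusion(pred[-1, ], gold), "alignment error")
})

test_that("metrics reproduce the recurrence confusion arithmetic and conventions", {
  m <- metrics(list(tp = 29, fp = 4, fn = 1))
  expect_equal(round(m$precision, 3), 0.879)
  expect_equal(round(m$recall, 3), 0.967)
  expect_equal(round(m$f1, 3), 0.921)

  zero <- metrics(list(tp = 0, fp = 0, fn = 0))
  expect_identical(c(zero$precision, zero$recall, zero$f1), c(0, 0, 0))

  ones <- metrics(list(tp = 5, fp = 0, fn = 0))
  expect_identical(c(ones$precision, ones$recall, ones$f1), c(1, 1, 1))
})

test_that("metrics are invariant to scaling all counts", {
  set.seed(601)
  for (k in 1:25) {
    counts <- list(tp = sample(0:20, 1), fp = sample(0:20, 1),
                   fn = sample(0:20, 1))
    m1 <- metrics(counts)
    m5 <- metrics(lapply(counts, `*`, 5))
    expect_equal(m1$precision, m5$precision)
    expect_equal(m1$recall, m5$recall)
    expect_equal(m1$f1, m5$f1)
  }
})

random_outcomes <- function(n) {
  data.frame(chart_id = sprintf("c%02d", seq_len(n)),
             tp = sample(0:1, n, TRUE), fp = sample(0:1, n, TRUE),
             fn = sample(0:1, n, TRUE), stringsAsFactors = FALSE)
}

test_that("identical or single-chart outcome vectors give p = 1", {
  set.seed(602)
  oc <- random_outcomes(8)
  expect_equal(permutation_test(oc, oc)$p_value, 1)
  # one discordant chart: both swap states give the same |dF1|
  a <- data.frame(chart_id = "c1", tp = 1L, fp = 0L, fn = 0L)
  b <- data.frame(chart_id = "c1", tp = 0L, fp = 0L, fn = 1L)
  res <- permutation_test(a, b)
  expect_identical(res$n_permutations, "exact")
  expect_equal(res$p_value, 1)
})

test_that("Monte Carlo and exact permutation p-values agree within 3 standard errors", {
  set.seed(603)
  for (k in 1:3) {
    oa <- random_outcomes(10)
    ob <- random_outcomes(10)
    ex <- permutation_test(oa, ob, exact = TRUE)
    mc <- permutation_test(oa, ob, n_permutations = 100000, seed = 11,
                           exact = FALSE)
    se <- sqrt(ex$p_value * (1 - ex$p_value) / 100000)
    expect_lt(abs(mc$p_value - ex$p_value), 3 * se + 2 / 100000)
  }
})

test_that("permutation p-values are super-uniform under an exchangeable null", {
  set.seed(604)
  n_rep <- 150
  pvals <- replicate(n_rep, {
    # per-chart outcomes drawn iid for both pipelines: pairs exchangeable
    oa <- random_outcomes(8)
    ob <- oa
    ob[, c("tp", "fp", "fn")] <- random_outcomes(8)[, c("tp", "fp", "fn")]
    permutation_test(oa, ob, exact = TRUE)$p_value
  })
  for (alpha in c(0.05, 0.1, 0.2, 0.5)) {
    emp <- mean(pvals <= alpha)
    expect_lte(emp, alpha + 3 * sqrt(alpha * (1 - alpha) / n_rep))
  }
})

test_that("permutation test rejects misaligned outcome vectors", {
  oa <- random_outcomes(5)
  expect_error(permutation_test(oa, random_outcomes(4)),
               "alignment error")
})

test_that("chart_outcomes expands predictions into per-chart contributions", {
  gold <- data.frame(chart_id = c("a", "b", "c"),
                     label = c("positive", "negative", "not_listed"),
                     stringsAsFactors = FALSE)
  pred <- data.frame(chart_id = c("a", "b", "c"),
                     label = c("positive", "positive", "not_listed"),
                     stringsAsFactors = FALSE)
  oc <- chart_outcomes(pred, gold)
  expect_identical(oc$tp, c(1L, 0L, 0L))
  expect_identical(oc$fp, c(0L, 1L, 0L))
  expect_identical(oc$fn, c(0L, 0L, 0L))
})
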