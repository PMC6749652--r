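test_that("the toy terminology loads with the expected oncology concepts", {
  g <- toy_graph()
  expect_s3_class(g, "terminology_graph")
  expect_true(all(c("93880001", "254637007", "255227004", "263502005") %in%
                    g$concepts$concept_id))
  expect_true(g$concepts$active[g$concepts$concept_id == "254637007"])
})

test_that("optional terminology files default to empty tables", {
  dir <- write_term_tsv(tempfile(), data.frame(id = "1", active = 1L,
                                               fsn = "thing (synthetic)"))
  g <- load_terminology(dir)
  expect_identical(nrow(g$substitutions), 0L)
  expect_identical(nrow(g$mrcm), 0L)
})

test_that("load errors name the missing file, a cycle, or a dangling id", {
  dir <- tempfile()
  dir.create(dir)
  expect_error(load_terminology(dir), "concepts\\.tsv")

  dir <- write_term_tsv(tempfile(),
                        data.frame(id = c("1", "2"), active = 1L,
                                   fsn = c("a (synthetic)", "b (synthetic)")),
                        is_a = data.frame(childId = c("1", "2"),
                                          parentId = c("2", "1")))
  expect_error(load_terminology(dir), "cyclic")

  dir <- write_term_tsv(tempfile(),
                        data.frame(id = "1", active = 1L,
                                   fsn = "a (synthetic)"),
                        is_a = data.frame(childId = "1", parentId = "99"))
  expect_error(load_terminology(dir), "99")
})

test_that("substitution chains and active substitution sources are rejected", {
  dir <- write_term_tsv(
    tempfile(),
    data.frame(id = c("1", "2", "3"), active = c(0L, 0L, 1L),
               fsn = paste(c("a", "b", "c"), "(synthetic)")),
    substitutions = data.frame(inactiveId = "1", replacementId = "2"))
  expect_error(load_terminology(dir), "not active")
})

test_that("resolve_active is identity on active concepts and follows substitutions", {
  g <- toy_graph()
  expect_identical(resolve_active(g, "254637007"), "254637007")
  expect_identical(resolve_active(g, "990000101"), "254637007")
  # two replacements, input order preserved
  expect_identical(resolve_active(g, "990000102"),
                   c("255227004", "288524001"))
  expect_error(resolve_active(g, "42"), "unknown concept")
})

test_that("resolve_active returns only active ids and is idempotent", {
  g <- toy_graph()
  for (id in g$concepts$concept_id) {
    res <- resolve_active(g, id)
    for (r in res) {
      expect_true(g$concepts$active[g$concepts$concept_id == r])
      expect_identical(resolve_active(g, r), r)
    }
  }
})

test_that("subsumes follows is-a paths, is reflexive, and rejects unknown ids", {
  g <- toy_graph()
  expect_true(subsumes(g, "93880001", "254637007"))
  expect_true(subsumes(g, "404684003", "254637007"))
  expect_true(subsumes(g, "254637007", "254637007"))
  expect_false(subsumes(g, "255227004", "254637007"))
  expect_error(subsumes(g, "93880001", "42"), "unknown concept")
})

test_that("subsumes is reflexive and transitive on random DAGs and matches reachability", {
  set.seed(101)
  for (rep in 1:5) {
    dag <- random_dag_graph(n = 8)
    g <- dag$graph
    ids <- dag$ids
    for (x in ids) expect_true(subsumes(g, x, x))
    for (k in 1:40) {
      pair <- sample(ids, 2)
      expect_identical(subsumes(g, pair[1], pair[2]),
                       reachable(dag$is_a, pair[2], pair[1]))
    }
    # transitivity: a subsumes b and b subsumes c implies a subsumes c
    for (k in 1:20) {
      tri <- sample(ids, 3)
      if (subsumes(g, tri[1], tri[2]) && subsumes(g, tri[2], tri[3])) {
        expect_true(subsumes(g, tri[1], tri[3]))
      }
    }
  }
})

test_that("the description index merges custom entries with provenance", {
  ix <- toy_index()
  hit <- ix$terms[ix$terms$term_norm == "recurrence", ]
  expect_identical(hit$concept_id, "255227004")
  expect_identical(hit$source, "custom")
  # terminology-only index equals the descriptions alone
  ix0 <- build_description_index(toy_graph())
  expect_identical(nrow(ix0$terms), nrow(toy_graph()$descriptions))
  expect_error(
    build_description_index(toy_graph(),
                            data.frame(term = "ghost", concept_id = "42")),
    "ghost")
})

test_that("a term mapping to two concepts keeps both entries", {
  dir <- write_term_tsv(
    tempfile(),
    data.frame(id = c("10", "11"), active = 1L,
               fsn = paste(c("x", "y"), "(synthetic)")),
    descriptions = data.frame(conceptId = c("10", "11"),
                              term = c("shared term", "shared term"),
                              isFsn = 0L))
  ix <- build_description_index(load_terminology(dir))
  expect_setequal(ix$terms$concept_id[ix$terms$term_norm == "shared term"],
                  c("10", "11"))
})

test_that("attributes_linking honours MRCM domain and range subsumption", {
  g <- toy_graph()
  expect_identical(attributes_linking(g, "254637007", "255227004"),
                   "263502005")
  expect_identical(attributes_linking(g, "93880001", "255227004"),
                   "263502005")
  # no applicable rule: qualifier as source
  expect_identical(attributes_linking(g, "255227004", "254637007"),
                   character())
  # destination outside every range
  expect_identical(attributes_linking(g, "254637007", "93880001"),
                   character())
})

test_that("every attribute returned satisfies its rule's domain/range check", {
  g <- toy_graph()
  ids <- g$concepts$concept_id[g$concepts$active]
  for (s in ids) {
    for (d in ids) {
      for (att in attributes_linking(g, s, d)) {
        rules <- g$mrcm[g$mrcm$attribute_id == att, ]
        ok <- any(vapply(seq_len(nrow(rules)), function(k) {
          subsumes(g, rules$domain_id[k], s) &&
            subsumes(g, rules$range_id[k], d)
        }, logical(1)))
        expect_true(ok)
      }
    }
  }
})

test_that("write/load round-trips the terminology exactly", {
  g <- toy_graph()
  dir <- tempfile()
  write_terminology(g, dir)
  g2 <- load_terminology(dir)
  for (slot in c("concepts", "descriptions", "is_a", "substitutions",
                 "mrcm")) {
    expect_identical(g2[[slot]], g[[slot]])
  }
})
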