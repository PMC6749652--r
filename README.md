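# clinconcept

Clinical narratives carry most of their information as free text, and
abstracting structured facts out of them by hand is slow and expensive.
`clinconcept` detects SNOMED CT concepts in clinical free text — including
misspelled mentions — and composes detected concept pairs into
post-coordinated SNOMED CT expressions, so that a chart saying *"This
patient is diagnosed with recurrent nonsmall cell lung cancer"* can be
encoded as

```
254637007 | Non-small cell lung cancer (disorder) | :
    263502005 | Clinical course (attribute) | = 255227004 | Recurrent (qualifier value) |
```

It is aimed at medical-informatics researchers who want a transparent,
fully scriptable post-processing pipeline behind any tokenizer/parser
front end, together with the evaluation machinery (chart-level
precision/recall/F1 and a paired permutation test) needed to compare
annotation pipelines on the same chart set.

## What the pipeline does

1. **Dictionary NER** — greedy longest-window lookup of terminology
   descriptions plus a custom keyword dictionary (e.g. "recurrence" →
   `255227004 | Recurrent |`), case- and whitespace-normalized.
2. **Concept filter** — inactive concepts are replaced by their
   substitutes; among overlapping annotations only the longest term
   survives ("Lung cancer" beats "Lung"); duplicates collapse; on a shared
   span the most detailed concept wins (NSCLC beats lung cancer).
3. **Fuzzy recovery** — unannotated words on relevant dependency edges are
   matched against descriptions with a greedy longest-common-substring
   similarity: matched characters m(a, b) are counted by repeatedly taking
   the longest common substring and recursing on both remainders, and

   similarity(a, b) = m(a, b) / ((|a| + |b|) / 2) × 100.

   Mentions at or above the 95% threshold (a 5% error margin) are
   annotated: "nonsmall cell lung cancer" reaches 98.04% against
   "non-small cell lung cancer" and is recovered.
4. **Relation extraction** — dependency edges with labels nsubj, amod,
   nmod, advmod, nn, attr, dobj, pobj, hmod (npadvmod optional) connect
   the modifier's concept to the head's concept.
5. **Attribute qualification** — the Machine Readable Concept Model
   licenses attributes whose domain subsumes the head (focus) concept and
   whose range subsumes the modifier (value); each licensed attribute
   yields one expression `focus:attribute=value`.
6. **Evaluation** — charts are labelled positive for a target concept when
   any detected concept is the target or a descendant; precision = TP/(TP+FP),
   recall = TP/(TP+FN), F1 their harmonic mean (0/0 defined as 0); two
   pipelines are compared with a paired two-tailed permutation test on
   |ΔF1| (exact enumeration up to 20 charts, seeded Monte Carlo beyond).

Terminology comes in as plain RF2-lite TSV files (concepts, descriptions,
is-a edges, inactive-concept substitutions, MRCM triples), parses as
CoNLL-U, annotations go out as JSON Lines. A fixture module generates a
toy oncology terminology and synthetic charts (with seeded, bounded
misspellings and hand-written parses) so everything runs with no external
data.

## Worked example

```r
library(clinconcept)

base  <- tempfile()
term  <- file.path(base, "terminology")
charts <- file.path(base, "charts")
generate_terminology(term)
graph <- load_terminology(term)

similarity_percent("nonsmall cell lung cancer", "non-small cell lung cancer")
#> [1] 98.03922

generate_charts(fixture_spec(seed = 42, n_charts = 30), graph, charts)
out <- run_pipeline(pipeline_config(term, charts, file.path(base, "out"),
                                    log_level = "quiet"))
head(out$expressions, 3)
#>    chart_id                    expression
#> 1 chart_000 254637007:263502005=255227004
#> 2 chart_002 254637007:263502005=255227004
#> 3 chart_007  93880001:263502005=255227004

m <- out$metrics
m[m$mode == "implied", c("concept", "tp", "fp", "fn", "precision", "recall", "f1")]
#>                        concept tp fp fn precision recall    f1
#> 1                     93880001 11  0  0     1.000    1.0 1.000
#> 3                    254637007  7  0  0     1.000    1.0 1.000
#> 5                    255227004 10  5  0     0.667    1.0 0.800
#> 7 93880001:263502005=255227004  8  0  2     1.000    0.8 0.889
```

Chart 0 is the flagship misspelled sentence; its recovered phrase becomes
the expression `254637007:263502005=255227004` (recurrent non-small cell
lung cancer). The recurrence false positives come from gold-*negative*
charts ("There is no evidence of recurrence") — the pipeline performs no
negation detection, so explicit absence statements are predicted positive.
The missed relations are charts phrasing the relation across a
prepositional link the dependency labels do not connect ("recurrence of
lung cancer").

Comparing against a dictionary-only run:

```r
nofz <- run_pipeline(pipeline_config(term, charts, file.path(base, "out2"),
                                     fuzzy_enabled = FALSE, name = "dict-only",
                                     log_level = "quiet"))
gold <- read_gold_labels(file.path(charts, "gold_labels.tsv"))
compare_runs(out$predictions, nofz$predictions, gold,
             targets = "254637007", seed = 1)
#>     concept    mode observed_dF1   p_value n_permutations seed
#> 1 254637007 implied          0.4 0.1234877          10000    1
```

A command-line wrapper is installed as `exec/clinconcept` with subcommands
`gen-fixtures`, `annotate`, `relate`, `evaluate`, `compare`.

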