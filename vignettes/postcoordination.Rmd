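---
title: "Detecting and post-coordinating SNOMED CT concepts in clinical text"
author: "clinconcept"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and post-coordinating SNOMED CT concepts in clinical text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinconcept)
```

## The problem

Clinical charts describe diagnoses, qualifiers and their connections in
free text. Encoding a chart means more than spotting concept mentions: a
phrase like "recurrent non-small cell lung cancer" asserts a *typed*
relationship — the disorder has Clinical course = Recurrent — which SNOMED
CT can express as a post-coordinated expression
`254637007:263502005=255227004`. `clinconcept` implements the
post-processing stages that turn tokenized, optionally dependency-parsed
text plus a terminology into such expressions, and the evaluation
machinery to measure how well that works at chart level.

The package deliberately ships no statistical tokenizer or parser: any
front end that produces sentences, token spans and labelled dependency
edges (CoNLL-U is read natively) can sit upstream. All downstream logic —
filtering, fuzzy recovery, relation extraction, MRCM qualification,
scoring — is pure, deterministic R.

## The pipeline and its assumptions

**Dictionary lookup.** Terms are compared after Unicode case folding,
whitespace collapsing and trimming; no stemming. Every contiguous token
window matching an index term emits one annotation per mapped concept;
nothing is disambiguated at this stage. The assumption is that the
terminology's description set, possibly extended by a small custom
dictionary of local word forms ("recurrence"), covers the vocabulary;
anything else must be caught by the similarity matcher.

**Concept filter.** Four rules in a fixed order: (1) inactive concepts
are replaced by their substitution targets (applied once — substitution
chains are rejected at load time); (2) among overlapping annotations only
those of maximal character length survive; (3) identical (span, concept)
pairs collapse; (4) when a span carries both a concept and one of its
descendants, the descendant wins. The order matters and matches the
narrative staging of the filter: activity first, then overlap, then
span-level refinement. The filter is idempotent, which the test suite
asserts on random inputs, and a brute-force enumerator over all rules
serves as an oracle for instances of up to six annotations.

**Similarity matching.** The matcher counts matching characters by a
greedy recursion: take the longest common substring (ties: earliest
occurrence in the first argument, then in the second), then recurse
independently on the left and right remainders. The similarity is the
count divided by the mean of the two lengths, times 100; two empty
strings are 100% similar, one empty string scores 0. The greedy recursion
is *not* symmetric — the suite records the counterexample
`match_count("aaaba", "abaab") = 4` but `3` in the reverse order — so
every call site fixes the argument order as (free text, description).
The inclusion threshold defaults to 95% ("at least" semantics, so the
comparison is `>=`), i.e. a 5% character error margin: one deleted or
inserted character in a 26-character phrase still scores about 98%.

A length prefilter skips candidate descriptions that cannot reach the
threshold. With phrase length *l* and threshold *t* (as a fraction), the
admissible description lengths are `[l·t/(2−t), l·(2−t)/t]`: since the
match count is bounded by the shorter string, a description of length *d*
can score at most `2·min(l,d)/(l+d)`, and that bound drops below *t*
exactly outside this band. A naive band `[l·t, l/t]` would be slightly too
narrow and could drop true hits; the property suite verifies the
implemented band never changes results.

**Fuzzy recovery.** Only tokens that participate in a dependency edge
with a relevant label and are not yet annotated trigger recovery. For
such a token the package scores candidate token windows containing it —
bounded in length by the longest index term plus one word — and keeps the
best hit (highest similarity, then lowest concept id, then leftmost and
shortest window). A window may not cut an existing annotation in half,
but it may wholly absorb one. This last point is a deliberate design
choice: in "recurrent nonsmall cell lung cancer" the dictionary typically
already matched "lung cancer" inside the misspelled phrase, and
restricting recovery to entirely unannotated runs would leave only
"nonsmall cell", which matches nothing — the phrase-level concept would
be unreachable exactly in the situation recovery exists for. After
recovery the pipeline re-runs the overlap filter, so the longer recovered
phrase displaces the absorbed shorter match, consistent with the
longest-term rule.

**Relation extraction.** For every edge with label in {nsubj, amod, nmod,
advmod, nn, attr, dobj, pobj, hmod} (npadvmod behind a flag, default
off), annotations overlapping the dependent token become relation
sources (modifiers) and annotations overlapping the governor become
destinations (heads). Pairs with equal concept ids are skipped — both
tokens inside one phrase annotation carry the same concept — and
identical (source, destination, sentence) triples deduplicate. Relations
never cross sentence boundaries; charts that mention a cancer in one
sentence and qualify it in the next are out of reach by design, and this
shows up as relation-target false negatives in the fixture evaluation.
When a span still maps to several concepts after filtering, all pairings
are emitted.

**Attribute qualification.** MRCM rules are flat (attribute, domain,
range) triples; attribute grouping and cardinality are not modelled. An
attribute links a relation's head concept (focus) to its modifier
(value) when some rule's domain subsumes the focus and a range member
subsumes the value, with subsumption reflexive (self-or-descendant).
Every emitted expression therefore satisfies its rule by construction,
and the tests re-check this against the rule table directly.

## Evaluation model

Chart labels are binary from the predictor's point of view: *positive*
when any detected concept is the target or a descendant (or, for an
expression target, when a detected expression matches focus/value by
subsumption and the attribute exactly), else *not listed*. Gold standards
additionally use *negative* for explicit absence statements; since the
pipeline performs no negation detection, gold-negative charts count as
not-positive in the confusion table and typically surface as false
positives. Precision, recall and F1 use the 0/0 → 0 convention, so a
pipeline that detects nothing scores 0.000 across the board.

Two pipelines on the same charts are compared with a paired two-tailed
permutation test. Each chart contributes a (TP, FP, FN) triple per
pipeline; F1 is computed from the summed triples as `2TP/(2TP+FP+FN)`
(algebraically the harmonic mean of precision and recall); the statistic
is |ΔF1|. The null swaps, independently per chart, which pipeline
produced which triple. With n ≤ 20 charts all 2^n assignments are
enumerated and the p-value is the exact proportion (the identity
assignment keeps it positive); beyond that, seeded Monte Carlo draws are
used with +1 smoothing, `(count + 1)/(B + 1)`, to avoid p = 0. The suite
checks exact-vs-Monte-Carlo agreement within three standard errors and
super-uniformity of the exact p-value under an exchangeable null.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `threshold_percent` | 95 (%) | minimal similarity for a fuzzy hit; inclusive |
| `case_fold` | `TRUE` | fold case before similarity comparison |
| `allowed_labels` | 9 labels | dependency labels that license relations |
| `include_npadvmod` | `FALSE` | add the noun-phrase-as-adverbial-modifier label |
| `keep_equal_length_ties` | `TRUE` | keep equal-length overlapping annotations |
| `fuzzy_enabled` | `TRUE` | run recovery at all (off = dictionary-only baseline) |

Equal-length overlap ties are kept by default because the filter only
mandates dropping strictly shorter terms; a switch resolves ties to the
lowest concept id for pipelines that need a single concept per region.

## The synthetic fixtures

Real oncology charts cannot be redistributed, so the fixture module
generates the study material. The toy terminology contains the genuine
SNOMED CT identifiers at the heart of the use case (93880001 primary
malignant neoplasm of lung, 254637007 non-small cell lung cancer,
255227004 Recurrent, 263502005 Clinical course, 288524001 Courses), the
is-a edges connecting them, one Clinical-course MRCM rule, and a few
clearly marked invented concepts (ids prefixed 99, "(synthetic)" in the
FSN) covering an inactive concept with substitutions and a
recurrent-disease term. The custom dictionary maps "recurrence" to
255227004.

Charts are instantiated from eight hand-parsed sentence templates —
positive (five variants around lung cancer, NSCLC and recurrence),
explicit-absence, and not-listed controls — and chart 0 is always the
flagship misspelled sentence. Defaults: 30 charts (the scale of a
development chart set), a 60/10/30 positive/negative/not-listed mix
(roughly the published chart composition), and a 0.2 misspelling rate
reflecting notes with limited misspellings. Misspellings are injected
only into mentions the template marks perturbable — phrases bounded on
the left by another annotated concept and running to the sentence end,
the configuration recovery can always repair — with
`max(1, floor(max_edit_fraction × term length))` single-character edits
that never touch the term's first character and never cross token
boundaries (the dependency parse stays valid). At the default
`max_edit_fraction = 0.05` the generator verifies each corruption stays
at or above the 95% threshold and resamples edit positions otherwise, so
recoverability holds by construction; raising the fraction (e.g. 0.2)
forces corruptions beyond the margin for negative-control tests.

What the fixtures do **not** emulate: real clinical telegraphic style,
abbreviations, section structure, negation/uncertainty phenomena richer
than one "no evidence of" template, parser errors (all parses are
hand-written gold parses), and vocabulary breadth. Passing the suite
demonstrates the algorithms' correctness on their contracts, not
field performance on real charts.

## Numerical and degenerate-input choices

* Character offsets are 0-based half-open everywhere; CoNLL-U 1-based
  indices are converted at the boundary.
* Deterministic orderings throughout: annotations by (start, end,
  concept id), SCTIDs in numeric-string order (width, then
  lexicographic — identifiers may exceed double precision), fuzzy hits by
  similarity then id. Two runs on identical input are byte-identical.
* Empty text tokenizes to an empty sentence list; an empty chart flows
  through the pipeline to empty artifacts and not-listed predictions.
* Similarity comparisons at the threshold are inclusive; the permutation
  test compares permuted statistics to the observed one with a 1e-12
  slack to absorb floating-point noise in tied statistics.
* Dependency label subtypes ("nmod:poss") match on their base label.

## Problem sizes in the test suite

The property suites use sizes chosen to exhaust the interesting structure
while staying quick: 1000 random string pairs (length ≤ 15, 4-letter
alphabet) against the DP-based match-count oracle, 100 random instances
of ≤ 6 annotations against the brute-force filter oracle, random 8-node
DAGs for subsumption properties, exact permutation enumeration at n = 10
against 100 000 Monte Carlo draws, and fixture runs of 12–40 charts. The
whole suite runs in well under a minute.

## Known limitations

* No negation or uncertainty detection: explicit absence statements are
  predicted positive.
* Single-attribute expressions only; no attribute groups, nesting or
  coordination.
* Fuzzy recovery is character-based; transposed words or token-splitting
  misspellings ("non small" as two tokens is handled only because the
  window may span both) are at the edge of its reach.
* The greedy match count is order-sensitive; similarity values are only
  comparable when computed with a fixed argument-order convention.
* CUI-to-SCTID mapping from UMLS-coded annotations is out of scope; the
  package works in SCTID space directly.
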