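Package: clinconcept
Title: SNOMED CT Concept Detection and Post-Coordination from Clinical Free Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects SNOMED CT concepts in clinical free text by dictionary
    lookup against a terminology description index (including a custom
    keyword dictionary), recovers misspelled mentions with a greedy
    longest-common-substring similarity matcher, filters competing
    annotations (activity resolution, longest-term overlap, duplicate
    collapse, most-detailed-concept refinement), extracts relationships
    between detected concepts from dependency parses, and qualifies those
    relationships with MRCM-licensed attributes to form post-coordinated
    expressions. Includes chart-level evaluation (precision, recall, F1),
    a paired two-tailed permutation test for comparing annotation
    pipelines, and a synthetic fixture generator (toy oncology terminology,
    charts with seeded misspellings, dependency parses, gold labels).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
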