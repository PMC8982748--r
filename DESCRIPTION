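Package: omroverlap
Title: Concept Overlap and Specialty Salience Between Outside Medical
    Records and Consultant Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how much of the clinical-concept content
    of scanned outside medical records (OMRs) reappears in the consultant
    notes written after a referred patient's first specialty encounter.
    Concept mentions extracted by a clinical NER engine are reduced to
    unique (term, semantic group, patient) keys, consultant notes are split
    into initial-encounter and 90-day follow-up corpora, and the three
    concept sets are decomposed into the seven disjoint regions of their
    Venn diagram. Exact and terminology-path-based flexible intersection
    ratios, coverage tables by semantic group and note section, and a
    specialty saliency score against a background corpus are computed.
    Includes a synthetic-corpus generator that plants known region
    cardinalities, semantic-group mixtures, and specialty-exclusive
    concepts so that every pipeline stage can be validated without access
    to protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
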