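---
title: "Methods: concept overlap and specialty salience between outside records and consultant notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: concept overlap and specialty salience}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omroverlap)
```

## The problem

When a patient is referred to a specialty clinic, their outside medical
records arrive as scanned faxes. After OCR and clinical NER, both those
records and the clinic's own consultant notes become streams of concept
mentions. Two questions follow: how much of the outside information is
actually re-documented at the clinic — immediately, later, or never — and
how specific to the specialty is the information in each of those
compartments. This package answers both on concept *sets*, not on text.

## Concept identity

The unit of analysis is the triple (normalized term, semantic group,
patient), rendered `term::SEMGROUP::patient`. The choices behind it:

* **Terms are taken as the NER engine emits them** — case-folded and
  whitespace-collapsed, but never stemmed or re-normalized. The engine has
  already mapped surface variation to preferred terms; re-normalizing here
  would silently change its semantics.
* **Semantic groups are canonical code sets.** A single mention tagged
  with several types (warfarin as chemical *and* drug) yields one concept
  with the joint group `CHEM;DRUG` — codes are split, deduplicated, sorted
  and rejoined, so the representation is order-insensitive and
  canonicalization is idempotent. A term tagged FIND in one mention and
  PROC in another yields two distinct concepts. Both behaviors are
  deliberate and coexist.
* **Patient id is part of identity** for all set algebra: the same term in
  two patients' records is two concepts, which makes region cardinalities
  additive across patients and lets the synthetic generator plant them
  per-patient without collisions. Only the saliency module drops the
  patient id, because its frequencies are population-level.
* Mentions whose experiencer is not the patient (a relative's history)
  are filtered out before any set is built. Assertion and temporality are
  carried through I/O untouched but drive no statistic.

## Corpus assignment

Each patient's *reference date* is the latest expert-curated record date,
or the latest PDF creation date when no curated date exists. The *initial
encounter* is the earliest consultant note **strictly after** the
reference date — a note on the reference date itself is taken to belong to
the referral paperwork, not the encounter. Notes on the initial-encounter
date form the ICN corpus (several per patient are allowed, as one patient
may visit multiple practice settings that day); notes 1–90 days after it
form the FCN corpus. The follow-up window is exactly 90 calendar days,
closed at day 90: the day form is more precise than "three months" and
the generator deliberately plants notes on the boundary. Notes outside
the window, and patients whose initial encounter cannot be resolved, are
dropped and counted in the run log — those counts are the denominators a
reader needs to interpret the coverage figures.

## Overlap and matching

Regions A–G are the literal three-set Venn cells of
(C_OMR, C_ICN, C_FCN); the implementation classifies every key of the
union by membership, so disjointness and coverage hold by construction
and are re-checked against a brute-force classifier in the tests.

The exact ratio is r_e = |C_OMR ∩ C_CN| / |C_CN|. The flexible ratio
replaces string identity with the terminology path measure
sim = 1/l, where l counts the *nodes* of the shortest is-a path between
the two mapped concepts (identical concepts: l = 1; parent–child: l = 2).
Edges are traversed undirected — the path measure walks the hierarchy both
up and down. Numerical conventions:

* If either term is unmapped, or the concepts lie in different components,
  the similarity is the sentinel −1 — never 0, so the score range is
  (0, 1] ∪ {−1}. This applies even to two *identical* unmapped strings:
  similarity is defined on the terminology, not on strings. A consequence
  worth stating plainly: r_s ≥ r_e is guaranteed only when the shared
  terms are in the terminology (each exact match then scores 1 and is its
  own argmax). The generator's `map_exact_terms` option plants exactly
  that condition, and the property tests assert dominance under it.
* For each OMR concept the best CN concept with similarity strictly above
  the threshold is recorded; ties go to the lexicographically smallest
  rendered CN key, which makes runs reproducible. C_SIMILAR counts
  *distinct chosen CN concepts*, so r_s can never exceed 1.
* The default threshold is 0 — any mapped, connected pair qualifies,
  which is the most permissive reading consistent with the sentinel — and
  it is exposed as a configuration value because reasonable analyses may
  want to cut at, say, 1/3 (two is-a steps).
* An empty CN-side corpus leaves its ratio undefined; the ratio operations
  raise an error, while the orchestrated pipeline reports `NA` and renders
  a zeroed row rather than aborting a whole run.

Pairwise similarity is computed between deduplicated *terms* (patient and
group stripped), then broadcast back to keys; with unique concept-level
distances cached, the matching cost is |unique OMR terms| × |unique CN
terms|, which is why the flexible stage is demonstrated on a reduced
cohort (analysis stage 03) rather than the full reference corpus.

## Saliency

A concept's saliency is its mention frequency in the specialty's notes
divided by its mention frequency across all practice settings: 1 means
specialty-exclusive, values near 0 mean ubiquitous-or-rare. Frequencies
are raw mention counts (not per-patient indicators) over (term, group)
keys, so the score is invariant to scaling both corpora — the property
tests check this — and monotone in the specialty count.

Per region we report: the mapped count (keys whose concept occurs in the
background corpus at all), coverage = mapped / original cardinality, the
score sum, and the average. The average's denominator is the number of
concepts with *strictly positive* score; because mapped concepts with
zero specialty mentions make the two conventions diverge, the
mapped-count variant is also emitted (`average_mapped`) rather than
silently picking one. Averages render at 3 decimals, coverages and all
percentages at 2, using half-up rounding (base R's `round()` is
half-to-even and disagrees on printed table cells). Rankings break score
ties by higher background frequency, then lexicographic key.

## What the synthetic generator emulates — and what it does not

`generate_corpora()` plants, per region, an exact number of unique
concepts with a chosen semantic-group mixture, assigns them round-robin
to patients, and emits mention records whose dates realize the intended
ICN/FCN split (reference date per patient, initial encounter 7 days
later, follow-up notes scattered over days 1–90 including the boundary).
Concepts appearing only in follow-up notes are constrained to patients
that also hold an initial-encounter concept, since otherwise the earliest
follow-up note would itself resolve as the initial encounter. The
defaults reproduce the reference cohort this pipeline was designed
around: 294 patients; regions A=4793, B=14371, C=6745, D=6050, E=34947,
F=23660, G=141013; overlap-region group counts dominated by FIND, PROC,
DISO, ANAT, CHEM;DRUG and DRUG; sections concentrated in
"Impression/report/plan", "History of present illness" and
"Physical Exam". Adversarial structure is planted on purpose: duplicate
mentions (Poisson, mean 0.2 per record), experiencer-"Others" mentions
with fresh terms, pre-referral and post-window notes with fresh terms —
each detectably corrupts the counts if the corresponding pipeline rule is
broken. Identical seeds produce byte-identical files.

What it does **not** emulate: OCR noise, real clinical language,
per-patient case-mix correlation, term ambiguity (the toy terminology is
many-to-one by design), or the long-tailed mention-frequency
distributions of a real background corpus (background counts are uniform
× beta draws at a configurable scale). Passing tests therefore show the
*bookkeeping* is right — set semantics, window arithmetic, region
algebra, ratio and table construction — not that any clinical conclusion
transfers to real data.

## Problem sizes

The test suite exercises the full reference scale (231,579 unique
concepts, ~330K mention records) once, end to end through file I/O; all
other tests run on corpora of tens to hundreds of concepts, random
terminologies of ≤ 12 nodes (checked against an exhaustive all-paths
oracle), and region partitions of ≤ 30 concepts (checked against the
brute-force classifier). `scripts/acceptance.R` repeats the full-scale
run from scratch.

## Known limitations

* Word-sense handling: one surface term maps to at most one concept; a
  richer sense model would need a disambiguation policy the path measure
  alone cannot supply.
* The saliency average over regions with many zero-score concepts is
  sensitive to the denominator convention; both variants are reported,
  and region-level averages from corpora with inconsistent provenance
  should be compared only under a stated convention.
* No statistical testing is attached to overlap or salience differences;
  the package reports descriptive set statistics.
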