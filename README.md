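# omroverlap

Quantifying how much of the information in a referred patient's **outside
medical records (OMRs)** — the scanned faxes that accompany a referral —
actually reappears in the specialty clinic's own consultant notes, and how
specialty-specific that information is.

The package is aimed at clinical-NLP and medical-informatics researchers
who already have concept mentions extracted from text (by an NER engine
such as MedTagger or cTAKES, normalized against a terminology) and want to
analyse information continuity between document corpora, not at running
OCR or NER themselves.

## The analysis

Every extracted mention is reduced to a concept key
`term::SEMGROUP::patient` (e.g. `chest xray::PROC::0000`): a normalized
term, a canonical semicolon-joined semantic-group code set
(`ACTI, ANAT, CHEM, CONC, DISO, DRUG, FIND, PROC`, compounds like
`CHEM;DRUG` allowed), and the patient identifier. Mentions attributed to
someone other than the patient (experiencer "Others") are discarded.

Three concept sets are built per cohort:

* **C_OMR** — concepts in the outside records;
* **C_ICN** — concepts in *initial consultant notes*, written on the first
  Mayo-style encounter strictly after the patient's reference date (the
  latest expert-curated OMR date, falling back to PDF creation dates);
* **C_FCN** — concepts in *follow-up consultant notes*, written 1–90 days
  after that initial encounter.

With C_CN = C_ICN ∪ C_FCN, the package computes:

* the **exact intersection ratio** r_e = |C_OMR ∩ C_CN| / |C_CN|;
* the **flexible intersection ratio** r_s = |C_SIMILAR| / |C_CN|, where
  C_SIMILAR collects, for each OMR concept, the best consultant-note
  concept by the terminology **path measure**
  sim(c_i, c_j) = 1 / l(c_i, c_j) — l being the node count of the shortest
  is-a path (1 for identical concepts, −1 when either term is unmappable
  or the concepts are disconnected);
* the seven-region **Venn partition** A–G of (C_OMR, C_ICN, C_FCN) — e.g.
  region A = concepts in all three corpora, region C = OMR concepts
  overlooked initially but rediscovered in follow-up, region G = OMR
  concepts never incorporated — with coverage tables by semantic group and
  note section;
* a **saliency score** per concept, its specialty mention frequency over
  its all-practice mention frequency in a background corpus (1 =
  specialty-exclusive), aggregated per region as
  Σ scores / #{score > 0}.

Real referral corpora are protected patient data, so the package ships a
first-class synthetic generator (`synthetic_spec()`, `generate_corpora()`)
that plants exact region cardinalities, semantic-group and section
mixtures, terminology near-matches and specialty-exclusive concepts, and
the whole pipeline is validated against that planted ground truth.

## Worked example

```r
library(omroverlap)

spec <- synthetic_spec(seed = 42, n_patients = 20,
  region_cardinalities = c(A = 10, B = 20, C = 8, D = 6, E = 30, F = 15, G = 50),
  near_match_fraction = 0.2, map_exact_terms = TRUE,
  n_terminology_concepts = 100, n_specialty_exclusive = 3)
d <- tempfile(); generate_corpora(spec, d)

res <- run_pipeline(file.path(d, "annotations.tsv"),
                    file.path(d, "metadata.tsv"),
                    file.path(d, "terminology.tsv"),
                    file.path(d, "background.tsv"))
res$summary$n_regions
#>  A  B  C  D  E  F  G
#> 10 20  8  6 30 15 50
cat(render_report(res)[1:3], sep = "\n")
#> == Corpus sizes ==
#>   C_OMR 88 | C_ICN 66 | C_FCN 39 | union 139
#>   OMR/CN overlap (A+B+C): 38 (27.34% of union, 43.18% of C_OMR, 42.70% of C_ICN u C_FCN)
```

The planted region cardinalities come back exactly; the report goes on to
print the r_e / r_s ratios (here r_s > r_e because 20% of the OMR-only
concepts were planted one is-a step away from a consultant-note concept),
the semantic-group table and the saliency table.

The `analysis/` directory holds the full study as numbered stages —
`01_generate_corpora.R` (reference cohort: 294 patients, 231,579 unique
concepts), `02_overlap_partition.R`, `03_flexible_matching.R` (threshold
sweep), `04_saliency.R` — each writing its tables under `results/`.

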