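test_that("semantic groups canonicalize to sorted unique code sets, idempotently", {
  expect_equal(canonicalize_semgroup("DRUG;CHEM"), "CHEM;DRUG")
  expect_equal(canonicalize_semgroup("CHEM;DRUG;CHEM"), "CHEM;DRUG")
  expect_equal(canonicalize_semgroup(c("FIND", "PROC;ANAT")),
               c("FIND", "ANAT;PROC"))
  # idempotence over random compound groups
  set.seed(11)
  for (i in 1:50) {
    g <- paste(sample(semantic_group_codes(), sample(1:4, 1), replace = TRUE),
               collapse = ";")
    once <- canonicalize_semgroup(g)
    expect_identical(canonicalize_semgroup(once), once)
  }
  expect_error(canonicalize_semgroup("FIND;XYZ"), "unknown semantic code")
  expect_error(canonicalize_semgroup(c("FIND", "")), "empty semantic_group")
})

test_that("concept keys render and split as term::GROUP::patient", {
  expect_equal(concept_key("chest xray", "PROC", "0000"),
               "chest xray::PROC::0000")
  parts <- split_concept_key("chest xray::PROC::0000")
  expect_equal(parts$term, "chest xray")
  expect_equal(parts$semantic_group, "PROC")
  expect_equal(parts$patient_id, "0000")
  expect_error(split_concept_key("no separators"), "malformed")
})

test_that("annotation files round-trip field-for-field in both formats", {
  records <- ann_rows(
    ann_row(term = "chest xray", group = "PROC", patient = "0000"),
    ann_row(term = "chest xray", group = "FIND", patient = "0000"),
    ann_row(corpus = "OMR", doc = "OMR-1", date = NA, section = "UNKNOWN",
            term = "warfarin", group = "DRUG;CHEM"),
    ann_row(term = "heart attack", group = "DISO", experiencer = "Others",
            section = "Family History"))
  for (fmt in c("tsv", "jsonl")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_annotations(records, path, fmt)
    back <- read_annotations(path, fmt)
    expect_equal(back$term, records$term)
    expect_equal(back$note_date, records$note_date)
    expect_equal(back$semantic_group, canonicalize_semgroup(records$semantic_group))
    expect_equal(back$experiencer, records$experiencer)
  }
})

test_that("reading validates schema, canonicalizes groups, tolerates bad dates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    patient_id = "0000", document_id = "D1", corpus_tag = "CN",
    note_date = "not-a-date", section = "Diagnosis", term = "Chest  Xray",
    cui = "", semantic_group = "DRUG;CHEM", experiencer = "Patient",
    assertion = ""), path)
  rec <- read_annotations(path)
  expect_equal(rec$semantic_group, "CHEM;DRUG")
  expect_true(is.na(rec$note_date))
  expect_equal(rec$term, "chest xray") # case-folded, whitespace-collapsed

  # empty file with a valid header reads as zero records
  readr::write_tsv(tibble::tibble(
    patient_id = character(), document_id = character(),
    corpus_tag = character(), note_date = character(), section = character(),
    term = character(), cui = character(), semantic_group = character(),
    experiencer = character(), assertion = character()), path)
  expect_equal(nrow(read_annotations(path)), 0)

  # missing mandatory column is a schema error naming the column
  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(patient_id = "0000", term = "x"), bad)
  expect_error(read_annotations(bad), "semantic_group")
})

test_that("experiencer filter keeps exactly the Patient mentions, in order", {
  records <- ann_rows(
    ann_row(term = "chest pain"),
    ann_row(term = "heart attack", section = "Family History",
            experiencer = "Others"), # "his father had a history of ..."
    ann_row(term = "dyspnea"))
  kept <- filter_patient_experiencer(records)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$term, c("chest pain", "dyspnea"))
  all_others <- ann_rows(ann_row(experiencer = "Others"))
  expect_equal(nrow(filter_patient_experiencer(all_others)), 0)
})

test_that("concept sets apply set semantics over (term, group, patient) triples", {
  # one sentence yielding the same term under two semantic groups -> 2 members
  ct <- ann_rows(
    ann_row(term = "chest xray", group = "FIND", patient = "0000"),
    ann_row(term = "chest xray", group = "PROC", patient = "0000"))
  expect_equal(nrow(build_concept_set(ct)), 2)

  # five identical mentions -> one member
  five <- ann_rows(ann_row(), ann_row(), ann_row(), ann_row(), ann_row())
  expect_equal(nrow(build_concept_set(five)), 1)

  # same term for two patients -> two members
  two <- ann_rows(ann_row(patient = "P1"), ann_row(patient = "P2"))
  cs <- build_concept_set(two, "C_X")
  expect_equal(nrow(cs), 2)
  expect_setequal(cs$key, c("chest pain::FIND::P1", "chest pain::FIND::P2"))
})

test_that("|concept set| <= |records|, with equality iff all triples distinct", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    recs <- dplyr::bind_rows(lapply(seq_len(n), function(j) {
      ann_row(term = paste("term", sample(1:10, 1)),
              group = sample(c("FIND", "PROC", "DISO"), 1),
              patient = paste0("P", sample(1:3, 1)))
    }))
    cs <- build_concept_set(recs)
    expect_lte(nrow(cs), nrow(recs))
    triples <- paste(recs$term, recs$semantic_group, recs$patient_id)
    expect_equal(nrow(cs) == nrow(recs), !anyDuplicated(triples) > 0)
  }
})

test_that("concept-set union has set semantics and C_CN = C_ICN u C_FCN", {
  icn <- build_concept_set(ann_rows(ann_row(term = "a"), ann_row(term = "b")), "C_ICN")
  fcn <- build_concept_set(ann_rows(ann_row(term = "b"), ann_row(term = "c")), "C_FCN")
  cn <- concept_set_union(icn, fcn)
  expect_equal(nrow(cn), 3)
  expect_setequal(cn$key, union(icn$key, fcn$key))
})
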