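test_that("spec validation rejects infeasible requests", {
  expect_error(synthetic_spec(n_patients = 0), "n_patients")
  expect_error(synthetic_spec(region_cardinalities = c(
    A = -1, B = 0, C = 0, D = 0, E = 0, F = 0, G = 0)), "non-negative")
  expect_error(synthetic_spec(region_cardinalities = c(
    A = 0, B = 0, C = 0, D = 0, E = 0, F = 0, G = 0)), "no concepts")
  expect_error(synthetic_spec(semantic_group_weights = c(FIND = 0.5)),
               "sum to 1")
  expect_error(synthetic_spec(region_group_counts = list(
    A = c(FIND = 1), B = c(FIND = 14371), C = c(FIND = 6745),
    D = c(FIND = 6050), E = c(FIND = 34947), F = c(FIND = 23660),
    G = c(FIND = 141013))), "region A")
  # FCN-only concepts need a patient with an initial-encounter note
  bad <- synthetic_spec(n_patients = 3, region_cardinalities = c(
    A = 0, B = 0, C = 0, D = 0, E = 0, F = 5, G = 5))
  expect_error(generate_corpora(bad, withr::local_tempdir()), "infeasible")
})

test_that("generated terminology has the promised tree structure and synonyms", {
  spec <- small_spec(n_synonym_pairs = 3)
  tg <- generate_terminology(spec)
  expect_equal(nrow(tg$concepts), 100)
  expect_equal(nrow(tg$edges), 99) # a tree
  # connected: every node reaches node 1
  expect_false(anyNA(path_length(tg, tg$concepts$id,
                                 rep(tg$concepts$id[1], 100))))
  # synonym pairs share a node, so their similarity is exactly 1
  expect_equal(path_similarity(tg, "node synonym 000002", "node term 000002"), 1)
  # single-concept terminology: self-similarity 1
  tg1 <- generate_terminology(small_spec(n_terminology_concepts = 1,
                                         n_synonym_pairs = 0))
  expect_equal(path_similarity(tg1, "node term 000001", "node term 000001"), 1)
  # a 2-chain gives similarity 1/2, a 3-chain 1/3
  tg3 <- generate_terminology(small_spec(n_terminology_concepts = 3,
                                         terminology_branching = 1,
                                         n_synonym_pairs = 0))
  expect_equal(path_similarity(tg3, "node term 000001", "node term 000003"),
               1 / 3)
})

test_that("planted region cardinalities are recovered exactly by the pipeline", {
  combos <- list(
    c(A = 1, B = 2, C = 1, D = 1, E = 0, F = 1, G = 3),
    c(A = 10, B = 20, C = 8, D = 6, E = 30, F = 15, G = 50),
    c(A = 0, B = 5, C = 0, D = 0, E = 7, F = 0, G = 9))
  for (cards in combos) {
    spec <- synthetic_spec(seed = 99, n_patients = 5,
                           region_cardinalities = cards)
    d <- withr::local_tempdir()
    generate_corpora(spec, d)
    res <- run_pipeline(file.path(d, "annotations.tsv"),
                        file.path(d, "metadata.tsv"))
    expect_equal(res$summary$n_regions, cards)
    # cross-check against the brute-force classifier
    oracle <- brute_force_regions(res$sets$omr$key, res$sets$icn$key,
                                  res$sets$fcn$key)
    expect_equal(lengths(oracle)[names(cards)], cards, ignore_attr = TRUE)
  }
})

test_that("identical seeds generate byte-identical studies; seeds matter", {
  spec <- small_spec(seed = 123)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_corpora(spec, d1)
  generate_corpora(spec, d2)
  for (f in c("annotations.tsv", "metadata.tsv", "terminology.tsv",
              "background.tsv", "manifest.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
  d3 <- withr::local_tempdir()
  generate_corpora(small_spec(seed = 124), d3)
  expect_false(identical(
    readr::read_file(file.path(d1, "annotations.tsv")),
    readr::read_file(file.path(d3, "annotations.tsv"))))
})

test_that("distractors are planted: Others mentions and out-of-window notes", {
  spec <- small_spec(seed = 7, others_fraction = 0.1)
  d <- withr::local_tempdir()
  generate_corpora(spec, d)
  recs <- read_annotations(file.path(d, "annotations.tsv"))
  expect_gt(sum(recs$experiencer == "Others"), 0)
  # Others terms never leak into concept sets once filtered
  res <- run_pipeline(file.path(d, "annotations.tsv"),
                      file.path(d, "metadata.tsv"))
  all_terms <- c(res$sets$omr$term, res$sets$cn$term)
  expect_false(any(grepl("^family history finding", all_terms)))
  expect_false(any(grepl("^late visit finding", all_terms)))
  expect_false(any(grepl("^prior visit finding", all_terms)))
  # a follow-up note on the day-90 boundary exists and is kept as FCN
  assigned <- assign_corpora(filter_patient_experiencer(recs),
                             read_metadata(file.path(d, "metadata.tsv")))
  fcn <- assigned$records[assigned$records$corpus_tag == "FCN", ]
  initial <- assigned$assignments$initial_encounter_date[
    match(fcn$patient_id, assigned$assignments$patient_id)]
  expect_true(any(as.integer(fcn$note_date - initial) == 90))
  expect_true(all(as.integer(fcn$note_date - initial) >= 1))
  expect_true(all(as.integer(fcn$note_date - initial) <= 90))
})

test_that("planted specialty-exclusive concepts score 1.0 and top the ranks", {
  spec <- small_spec(seed = 8, n_specialty_exclusive = 4)
  d <- withr::local_tempdir()
  gt <- generate_corpora(spec, d)
  res <- run_pipeline(file.path(d, "annotations.tsv"),
                      file.path(d, "metadata.tsv"),
                      background = file.path(d, "background.tsv"))
  expect_length(gt$specialty_exclusive, 4)
  top <- res$saliency$top$E
  expect_equal(sort(top$concept[top$score == 1]),
               sort(gt$specialty_exclusive))
  expect_true(all(top$score[seq_along(gt$specialty_exclusive)] == 1))
  # no non-planted concept reaches 1.0 anywhere
  profile <- read_frequency_profile(file.path(d, "background.tsv"))
  ones <- profile[profile$specialty_count == profile$overall_count &
                    profile$overall_count > 0, ]
  expect_setequal(paste(ones$term, ones$semantic_group, sep = "::"),
                  gt$specialty_exclusive)
})

test_that("near-match planting lifts the flexible ratio above the exact ratio", {
  spec <- small_spec(seed = 9, near_match_fraction = 0.2,
                     map_exact_terms = TRUE)
  d <- withr::local_tempdir()
  generate_corpora(spec, d)
  args <- list(file.path(d, "annotations.tsv"), file.path(d, "metadata.tsv"),
               file.path(d, "terminology.tsv"))
  r0 <- do.call(run_pipeline, c(args, threshold = 0))
  expect_gt(r0$ratios$r_s_cn, r0$ratios$r_e_cn)
  # planted near pairs sit at similarity 1/2: a 0.99 threshold removes them
  r99 <- do.call(run_pipeline, c(args, threshold = 0.99))
  expect_equal(r99$ratios$r_s_cn, r99$ratios$r_e_cn)
  # without planting, flexible equals exact at any threshold
  spec0 <- small_spec(seed = 9, near_match_fraction = 0,
                      map_exact_terms = TRUE)
  d0 <- withr::local_tempdir()
  generate_corpora(spec0, d0)
  plain <- run_pipeline(file.path(d0, "annotations.tsv"),
                        file.path(d0, "metadata.tsv"),
                        file.path(d0, "terminology.tsv"))
  expect_equal(plain$ratios$r_s_cn, plain$ratios$r_e_cn)
})
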