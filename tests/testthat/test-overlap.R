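keyset <- function(terms, label = "C") {
  concept_set_from_keys(concept_key(terms, "FIND", "P1"), label)
}

test_that("the seven regions follow their set-algebra definitions", {
  omr <- keyset(c("a", "b", "c"), "C_OMR")
  icn <- keyset(c("b", "c", "d"), "C_ICN")
  fcn <- keyset(c("c", "d", "e"), "C_FCN")
  p <- partition_regions(omr, icn, fcn)
  expect_setequal(p$regions$A, "c::FIND::P1")
  expect_setequal(p$regions$B, "b::FIND::P1")
  expect_length(p$regions$C, 0)
  expect_setequal(p$regions$D, "d::FIND::P1")
  expect_length(p$regions$E, 0)
  expect_setequal(p$regions$F, "e::FIND::P1")
  expect_setequal(p$regions$G, "a::FIND::P1")

  empty <- keyset(character(0))
  p0 <- partition_regions(empty, empty, empty)
  expect_true(all(lengths(p0$regions) == 0))
})

test_that("regions are pairwise disjoint, cover the union, and match the brute-force classifier", {
  set.seed(51)
  universe <- paste("t", 1:30)
  for (rep in 1:40) {
    omr <- keyset(sample(universe, sample(0:20, 1)), "C_OMR")
    icn <- keyset(sample(universe, sample(0:20, 1)), "C_ICN")
    fcn <- keyset(sample(universe, sample(0:20, 1)), "C_FCN")
    p <- partition_regions(omr, icn, fcn)
    all_keys <- unlist(p$regions, use.names = FALSE)
    expect_false(anyDuplicated(all_keys) > 0) # disjoint
    expect_setequal(all_keys, union(union(omr$key, icn$key), fcn$key))
    # A u B = OMR n ICN; A u C = OMR n FCN; A u D = ICN n FCN
    expect_setequal(c(p$regions$A, p$regions$B), intersect(omr$key, icn$key))
    expect_setequal(c(p$regions$A, p$regions$C), intersect(omr$key, fcn$key))
    expect_setequal(c(p$regions$A, p$regions$D), intersect(icn$key, fcn$key))
    oracle <- brute_force_regions(omr$key, icn$key, fcn$key)
    for (r in names(oracle)) expect_setequal(p$regions[[r]], oracle[[r]])
  }
})

test_that("exact intersection ratio is |OMR n CN| / |CN|", {
  omr <- keyset(c("a", "b"))
  cn <- keyset(c("a", "b", "c", "d"))
  expect_equal(exact_intersection_ratio(omr, cn), 0.5)
  expect_equal(exact_intersection_ratio(keyset("x"), cn), 0)
  expect_error(exact_intersection_ratio(omr, keyset(character(0))),
               "undefined ratio")
})

test_that("flexible matching records the best CN concept above threshold", {
  tg <- toy_graph()
  omr <- concept_set_from_keys(c(
    "heart::ANAT::P1",          # exact term present in CN
    "mitral valve::ANAT::P1",   # near match only
    "gallbladder::ANAT::P1"),   # unmapped -> sentinel, no match
    "C_OMR")
  cn <- concept_set_from_keys(c(
    "heart::ANAT::P1", "heart valve::ANAT::P1", "heart valve::PROC::P1"),
    "C_CN")
  m <- best_flexible_match(omr, cn, tg, threshold = 0)
  matches <- m$matches
  expect_equal(matches$similarity[matches$omr_key == "heart::ANAT::P1"], 1)
  expect_equal(matches$cn_key[matches$omr_key == "heart::ANAT::P1"],
               "heart::ANAT::P1")
  # mitral valve (K4) is nearest to heart valve (K2): 2 nodes, sim 1/2;
  # two CN keys carry that term, the lexicographically smaller one wins
  expect_equal(matches$similarity[matches$omr_key == "mitral valve::ANAT::P1"],
               1 / 2)
  expect_equal(matches$cn_key[matches$omr_key == "mitral valve::ANAT::P1"],
               "heart valve::ANAT::P1")
  expect_false("gallbladder::ANAT::P1" %in% matches$omr_key)
  expect_true(all(matches$similarity > 0))
  expect_true(all(m$c_similar %in% cn$key))

  # a threshold above 1/2 excludes the near match
  m2 <- best_flexible_match(omr, cn, tg, threshold = 0.6)
  expect_false("mitral valve::ANAT::P1" %in% m2$matches$omr_key)
})

test_that("flexible ratio counts distinct chosen CN concepts over |CN|", {
  tg <- toy_graph()
  cn <- concept_set_from_keys(
    c("heart::ANAT::P1", "heart valve::ANAT::P1", "heart muscle::ANAT::P1",
      "island concept::ANAT::P1"), "C_CN")
  omr_exact <- concept_set_from_keys("heart::ANAT::P1", "C_OMR")
  m <- best_flexible_match(omr_exact, cn, tg, 0)
  r_e <- exact_intersection_ratio(omr_exact, cn)
  expect_equal(flexible_intersection_ratio(m, cn), r_e) # no flexible gains

  # one extra near-matching OMR concept adds exactly 1/|CN|
  omr_plus <- concept_set_from_keys(
    c("heart::ANAT::P1", "mitral valve::ANAT::P1"), "C_OMR")
  m2 <- best_flexible_match(omr_plus, cn, tg, 0)
  expect_equal(flexible_intersection_ratio(m2, cn), r_e + 1 / nrow(cn))

  # empty OMR set matches nothing
  m0 <- best_flexible_match(concept_set_from_keys(character(0), "C_OMR"),
                            cn, tg, 0)
  expect_equal(flexible_intersection_ratio(m0, cn), 0)
})

test_that("growing C_OMR never shrinks C_SIMILAR", {
  set.seed(61)
  tg <- toy_graph()
  terms <- c("heart", "heart valve", "heart muscle", "mitral valve",
             "island concept", "gallbladder")
  cn <- concept_set_from_keys(
    concept_key(sample(terms, 4), "FIND", "P1"), "C_CN")
  for (rep in 1:10) {
    base_terms <- sample(terms, sample(1:4, 1))
    extra_term <- sample(setdiff(terms, base_terms), 1)
    base <- concept_set_from_keys(concept_key(base_terms, "FIND", "P1"), "C_OMR")
    bigger <- concept_set_from_keys(
      concept_key(c(base_terms, extra_term), "FIND", "P1"), "C_OMR")
    n_base <- length(best_flexible_match(base, cn, tg, 0)$c_similar)
    n_big <- length(best_flexible_match(bigger, cn, tg, 0)$c_similar)
    expect_gte(n_big, n_base)
  }
})

test_that("semantic-group coverage table reports row shares of the overlap", {
  omr <- concept_set_from_keys(
    c("a::FIND::P1", "b::FIND::P1", "c::PROC::P1", "x::DISO::P1"), "C_OMR")
  icn <- concept_set_from_keys(
    c("a::FIND::P1", "b::FIND::P1", "c::PROC::P1", "e1::DISO::P1"), "C_ICN")
  fcn <- concept_set_from_keys(c("a::FIND::P1", "f1::ANAT::P1"), "C_FCN")
  tab <- semtype_coverage_table(partition_regions(omr, icn, fcn))
  find_row <- tab[tab$semantic_group == "FIND", ]
  expect_equal(find_row$freq_A, 1) # a
  expect_equal(find_row$freq_B, 1) # b
  expect_equal(find_row$freq_C, 0)
  expect_equal(find_row$pct_A, 50)
  # groups absent from the overlap are omitted (DISO, ANAT never in A/B/C)
  expect_false("DISO" %in% tab$semantic_group)
  expect_false("ANAT" %in% tab$semantic_group)
  total <- tab[tab$semantic_group == "Total", ]
  expect_equal(total$total, 3)
  expect_equal(total$freq_A + total$freq_B + total$freq_C, 3)
})

test_that("section incidence counts distinct (concept, section) pairs", {
  recs <- ann_rows(
    # one concept in two sections of one note -> contributes 2
    ann_row(term = "tachy brady syndrome", group = "DISO",
            section = "Diagnosis"),
    ann_row(term = "tachy brady syndrome", group = "DISO",
            section = "Impression/report/plan"),
    # one concept in the same section across three documents -> 1
    ann_row(term = "aspirin", group = "DRUG", doc = "d1",
            section = "Current Medications"),
    ann_row(term = "aspirin", group = "DRUG", doc = "d2",
            section = "Current Medications"),
    ann_row(term = "aspirin", group = "DRUG", doc = "d3",
            section = "Current Medications"))
  concepts <- build_concept_set(recs)
  tab <- section_distribution(recs, concepts)
  expect_equal(sum(tab$n), 3)
  expect_equal(tab$n[tab$section == "Current Medications"], 1)

  # empty concept set -> empty mapping
  expect_equal(nrow(section_distribution(recs, keyset(character(0)))), 0)

  # unknown section labels are folded into UNKNOWN with a warning
  odd <- ann_rows(ann_row(term = "aspirin", group = "DRUG",
                          section = "Made Up Section"))
  expect_warning(tab2 <- section_distribution(odd, build_concept_set(odd)),
                 "UNKNOWN")
  expect_equal(tab2$section, "UNKNOWN")
})

test_that("percentages render half-up at two decimals", {
  expect_equal(round_half_up(0.125, 2), 0.13) # banker's rounding would give 0.12
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(pct(19164, 60161), 31.85)
  expect_equal(pct(1, 3), 33.33)
})
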