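#' Specification for a synthetic annotation study
#'
#' Describes a complete synthetic referral cohort: how many patients, how
#' many unique concepts fall in each of the seven Venn regions of the
#' OMR/ICN/FCN decomposition, the semantic-group mixture, the note-section
#' mixture, the toy terminology, and the background-corpus frequency model.
#' The seed fully determines every emitted byte.
#'
#' Defaults emulate the reference cohort this pipeline was designed around:
#' 294 referred patients; region cardinalities A = 4793, B = 14,371,
#' C = 6745, D = 6050, E = 34,947, F = 23,660, G = 141,013 (166,922 OMR,
#' 60,161 ICN and 41,248 FCN unique concepts; 231,579 in total); the
#' overlap regions' per-group counts follow the observed semantic-group
#' table (FIND/PROC/DISO/ANAT/CHEM;DRUG/DRUG dominate, the small remainder
#' spread over ACTI/CHEM/CONC); sections concentrate in
#' "Impression/report/plan", "History of present illness" and
#' "Physical Exam".
#'
#' @param seed Integer seed.
#' @param n_patients Number of patients (> 0).
#' @param region_cardinalities Named non-negative integers for regions A–G.
#' @param semantic_group_weights Named probability vector over the eight
#'   atomic codes plus `"CHEM;DRUG"`; must sum to 1.
#' @param section_weights Named probability vector over the 12 consultant
#'   note sections; must sum to 1.
#' @param region_group_counts Optional named list region → named integer
#'   vector of per-semantic-group concept counts; each must sum to the
#'   region's cardinality. `NULL` plants the default mixture: the observed
#'   overlap-region table for A–C, largest-remainder apportionment of
#'   `semantic_group_weights` elsewhere.
#' @param mention_lambda Poisson mean for extra duplicate mentions per
#'   concept occurrence (duplicates never change concept sets).
#' @param others_fraction Fraction of extra mentions carrying experiencer
#'   `"Others"` (family history etc.); these use distinct terms so an
#'   unfiltered pipeline is detectably wrong.
#' @param n_terminology_concepts,terminology_branching Size and branching
#'   factor of the random is-a tree.
#' @param n_synonym_pairs Concepts given a second surface term.
#' @param near_match_fraction Fraction of OMR-only (region G) concepts
#'   whose term is mapped one is-a step away from a region-E concept's
#'   term, so flexible matching finds them at similarity 1/2.
#' @param map_exact_terms Map every overlap-region (A, B, C) term to its
#'   own terminology node? Path similarity is defined on the terminology,
#'   so an exact string match only attains similarity 1 — and the flexible
#'   ratio only dominates the exact one — when the shared terms are
#'   mapped. Requires `n_terminology_concepts` to be at least the number
#'   of distinct overlap terms plus the nodes claimed by near matches.
#' @param n_specialty_exclusive Concepts (taken from region E) planted as
#'   specialty-exclusive in the background profile (saliency 1).
#' @param unmapped_fraction Fraction of concepts absent from the background
#'   profile (they lower the coverage ratio).
#' @param background_frequency_scale Multiplier on background mention
#'   counts.
#' @param pdf_fallback_fraction Fraction of patients with no expert
#'   metadata dates, exercising the PDF-creation-date fallback.
#' @param reference_date Base calendar date for the cohort's referrals.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 20160301,
                           n_patients = 294,
                           region_cardinalities = c(
                             A = 4793, B = 14371, C = 6745, D = 6050,
                             E = 34947, F = 23660, G = 141013),
                           semantic_group_weights = default_group_weights(),
                           section_weights = default_section_weights(),
                           region_group_counts = NULL,
                           mention_lambda = 0.2,
                           others_fraction = 0.05,
                           n_terminology_concepts = 200,
                           terminology_branching = 3,
                           n_synonym_pairs = 10,
                           near_match_fraction = 0,
                           map_exact_terms = FALSE,
                           n_specialty_exclusive = 20,
                           unmapped_fraction = 0.01,
                           background_frequency_scale = 100,
                           pdf_fallback_fraction = 0.1,
                           reference_date = as.Date("2016-03-01")) {
  stopifnot(n_patients >= 1)
  region_cardinalities <- region_cardinalities[region_labels()]
  if (any(is.na(region_cardinalities)) || any(region_cardinalities < 0)) {
    stop("region_cardinalities must cover regions A-G with non-negative ",
         "counts", call. = FALSE)
  }
  if (sum(region_cardinalities) == 0) {
    stop("infeasible spec: no concepts to generate", call. = FALSE)
  }
  if (abs(sum(semantic_group_weights) - 1) > 1e-8) {
    stop("semantic_group_weights must sum to 1", call. = FALSE)
  }
  if (abs(sum(section_weights) - 1) > 1e-8) {
    stop("section_weights must sum to 1", call. = FALSE)
  }
  if (n_terminology_concepts < 1) {
    stop("invalid terminology size", call. = FALSE)
  }
  if (terminology_branching < 1) {
    stop("invalid terminology branching factor", call. = FALSE)
  }
  if (is.null(region_group_counts)) {
    region_group_counts <- default_region_group_counts(
      region_cardinalities, semantic_group_weights)
  }
  for (r in region_labels()) {
    counts <- region_group_counts[[r]]
    if (sum(counts) != region_cardinalities[[r]]) {
      stop("region_group_counts for region ", r, " sum to ", sum(counts),
           ", expected ", region_cardinalities[[r]], call. = FALSE)
    }
    bad <- setdiff(names(counts),
                   c(semantic_group_codes(), "CHEM;DRUG"))
    if (length(bad) > 0) {
      stop("unknown semantic group(s) in region_group_counts: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(
    seed = as.integer(seed),
    n_patients = as.integer(n_patients),
    region_cardinalities = region_cardinalities,
    semantic_group_weights = semantic_group_weights,
    section_weights = section_weights,
    region_group_counts = region_group_counts,
    mention_lambda = mention_lambda,
    others_fraction = others_fraction,
    n_terminology_concepts = as.integer(n_terminology_concepts),
    terminology_branching = as.integer(terminology_branching),
    n_synonym_pairs = as.integer(n_synonym_pairs),
    near_match_fraction = near_match_fraction,
    map_exact_terms = isTRUE(map_exact_terms),
    n_specialty_exclusive = as.integer(n_specialty_exclusive),
    unmapped_fraction = unmapped_fraction,
    background_frequency_scale = background_frequency_scale,
    pdf_fallback_fraction = pdf_fallback_fraction,
    reference_date = as.Date(reference_date)),
    class = "synthetic_spec")
}

#' Default semantic-group mixture of the overlap regions
#'
#' FIND 40.45%, PROC 21.75%, DISO 16.35%, ANAT 9.98%, CHEM;DRUG 7.51%,
#' DRUG 3.55%; the remaining 0.41% split over ACTI, CHEM and CONC.
#'
#' @return Named probability vector.
#' @export
default_group_weights <- function() {
  w <- c(FIND = 0.4045, PROC = 0.2175, DISO = 0.1635, ANAT = 0.0998,
         `CHEM;DRUG` = 0.0751, DRUG = 0.0355)
  rest <- (1 - sum(w)) / 3
  c(w, ACTI = rest, CHEM = rest, CONC = rest)
}

#' Default note-section mixture
#'
#' "Impression/report/plan" 31.88%, "History of present illness" 27.19%,
#' "Physical Exam" 11.89%; the remainder spread evenly over the other nine
#' sections.
#'
#' @return Named probability vector over the 12 sections.
#' @export
default_section_weights <- function() {
  major <- c("Impression/report/plan" = 0.3188,
             "History of present illness" = 0.2719,
             "Physical Exam" = 0.1189)
  others <- setdiff(setdiff(note_sections(), "UNKNOWN"), names(major))
  rest <- (1 - sum(major)) / length(others)
  w <- c(major, stats::setNames(rep(rest, length(others)), others))
  w[setdiff(note_sections(), "UNKNOWN")]
}

# Largest-remainder apportionment of `total` over `weights`; deterministic.
apportion <- function(total, weights) {
  q <- total * weights / sum(weights)
  base <- floor(q)
  rem <- as.integer(round(total - sum(base)))
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}

# Per-region per-group concept counts. Overlap regions A-C default to the
# observed table (major groups exact, remainder over ACTI/CHEM/CONC when it
# fits); other regions are apportioned from the weight vector.
default_region_group_counts <- function(region_cardinalities, weights) {
  observed <- list(
    A = c(FIND = 1825, PROC = 962, DISO = 860, ANAT = 408,
          `CHEM;DRUG` = 511, DRUG = 217),
    B = c(FIND = 5917, PROC = 3178, DISO = 2325, ANAT = 1364,
          `CHEM;DRUG` = 1022, DRUG = 504),
    C = c(FIND = 2737, PROC = 1495, DISO = 1052, ANAT = 813,
          `CHEM;DRUG` = 412, DRUG = 200))
  out <- list()
  for (r in region_labels()) {
    total <- region_cardinalities[[r]]
    if (r %in% names(observed) && total >= sum(observed[[r]])) {
      major <- observed[[r]]
      rest <- apportion(total - sum(major),
                        c(ACTI = 1, CHEM = 1, CONC = 1))
      out[[r]] <- c(major, rest)
    } else {
      out[[r]] <- apportion(total, weights)
    }
  }
  out
}

#' Generate a toy terminology graph
#'
#' A connected is-a tree over `n_terminology_concepts` nodes with
#' deterministic labels (`K000001`, ...), branching factor as specified.
#' Every concept gets one surface term equal to its preferred term; the
#' first `n_synonym_pairs` concepts get a second surface term (synonyms
#' mapping to the same node, like "structure of heart" / "cardiac").
#'
#' @param spec A [synthetic_spec()].
#' @return A [terminology_graph()].
#' @export
generate_terminology <- function(spec) {
  n <- spec$n_terminology_concepts
  b <- spec$terminology_branching
  ids <- sprintf("K%06d", seq_len(n))
  concepts <- tibble::tibble(id = ids,
                             preferred_term = sprintf("node term %06d", seq_len(n)))
  edges <- if (n > 1) {
    child <- 2:n
    parent <- ((child - 2L) %/% b) + 1L
    cbind(ids[child], ids[parent])
  } else NULL
  term_map <- stats::setNames(ids, concepts$preferred_term)
  n_syn <- min(spec$n_synonym_pairs, n)
  if (n_syn > 0) {
    syn <- stats::setNames(ids[seq_len(n_syn)],
                           sprintf("node synonym %06d", seq_len(n_syn)))
    term_map <- c(term_map, syn)
  }
  terminology_graph(concepts, term_map, edges)
}

region_membership <- function() {
  list(A = c("OMR", "ICN", "FCN"), B = c("OMR", "ICN"), C = c("OMR", "FCN"),
       D = c("ICN", "FCN"), E = "ICN", F = "FCN", G = "OMR")
}

#' Generate a complete synthetic study
#'
#' Emits, under `dir`: `annotations.tsv` (OMR and CN concept mentions, a
#' controlled fraction with experiencer `"Others"`), `metadata.tsv` (the
#' date sidecar, with PDF-creation fallbacks for some patients),
#' `terminology.tsv`, `background.tsv` (the frequency profile) and
#' `manifest.json`. By construction: after experiencer filtering, corpus
#' assignment and concept-set building, [partition_regions()] recovers
#' exactly the planted region cardinalities; distractor notes dated before
#' the reference date or after the follow-up window carry fresh terms, so
#' a pipeline with a broken window is detectably wrong; FCN notes include
#' the day-90 boundary; planted specialty-exclusive concepts have equal
#' specialty and overall background counts.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the file paths and the in-memory ground
#'   truth (`inventory`, `concept_keys` per region).
#' @export
generate_corpora <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(spec$seed)

  patients <- sprintf("P%04d", seq_len(spec$n_patients))
  reference <- spec$reference_date + (seq_len(spec$n_patients) %% 30L)
  initial <- reference + 7L

  ## --- concept inventory ------------------------------------------------
  inv <- vector("list", 7)
  names(inv) <- region_labels()
  for (r in region_labels()) {
    counts <- spec$region_group_counts[[r]]
    counts <- counts[counts > 0]
    if (length(counts) == 0) {
      inv[[r]] <- tibble::tibble(term = character(0), group = character(0),
                                 region = character(0))
      next
    }
    group <- rep(names(counts), counts)
    idx <- unlist(lapply(counts, seq_len), use.names = FALSE)
    slug <- tolower(gsub(";", " ", group, fixed = TRUE))
    inv[[r]] <- tibble::tibble(
      term = sprintf("region %s %s finding %06d", tolower(r), slug, idx),
      group = group, region = r)
  }
  inventory <- dplyr::bind_rows(inv)
  # Patient assignment is round-robin, with one constraint: a patient whose
  # notes contain FCN concepts must also have an ICN-dated note, or the
  # earliest follow-up note would itself resolve as the initial encounter.
  # So concepts from regions C and F may only go to patients that receive
  # at least one ICN-member concept (regions A, B, D, E).
  icn_regions <- c("A", "B", "D", "E")
  round_robin <- function(n, pool) pool[((seq_len(n) - 1L) %% length(pool)) + 1L]
  inventory$patient <- NA_character_
  has_icn <- inventory$region %in% icn_regions
  inventory$patient[has_icn] <- round_robin(sum(has_icn), patients)
  icn_pool <- unique(inventory$patient[has_icn])
  fcn_only <- inventory$region %in% c("C", "F")
  if (any(fcn_only)) {
    if (length(icn_pool) == 0) {
      stop("infeasible spec: regions C/F need at least one patient with an ",
           "initial-encounter note (regions A, B, D or E non-empty)",
           call. = FALSE)
    }
    inventory$patient[fcn_only] <- round_robin(sum(fcn_only), icn_pool)
  }
  g_only <- is.na(inventory$patient)
  inventory$patient[g_only] <- round_robin(sum(g_only), patients)
  inventory$key <- concept_key(inventory$term, inventory$group,
                               inventory$patient)

  ## --- documents --------------------------------------------------------
  # one OMR document per patient; 1 ICN doc (2 for every 7th patient);
  # 3 FCN docs on random days 1..window, patient 1 forced onto day 90.
  n_fcn_docs <- 3L
  fcn_days <- matrix(sample.int(90L, spec$n_patients * n_fcn_docs,
                                replace = TRUE),
                     nrow = spec$n_patients)
  fcn_days[1, 1] <- 90L
  two_icn <- (seq_len(spec$n_patients) %% 7L) == 0L

  omr_doc <- function(p) sprintf("OMR-%s-p1", patients[p])
  icn_doc <- function(p, alt) sprintf("ICN-%s-%d", patients[p],
                                      ifelse(two_icn[p] & alt, 2L, 1L))
  fcn_doc <- function(p, j) sprintf("FCN-%s-%d", patients[p], j)

  ## --- mention rows -----------------------------------------------------
  membership <- region_membership()
  rows <- list()
  sections <- names(spec$section_weights)

  emit <- function(sub, corpus) {
    p <- match(sub$patient, patients)
    if (corpus == "OMR") {
      tibble::tibble(
        patient_id = sub$patient, document_id = omr_doc(p),
        corpus_tag = "OMR", note_date = as.Date(NA), section = "UNKNOWN",
        term = sub$term, cui = "", semantic_group = sub$group,
        experiencer = "Patient", assertion = "Present")
    } else if (corpus == "ICN") {
      alt <- (seq_len(nrow(sub)) %% 2L) == 0L
      tibble::tibble(
        patient_id = sub$patient, document_id = icn_doc(p, alt),
        corpus_tag = "CN", note_date = initial[p],
        section = sample(sections, nrow(sub), replace = TRUE,
                         prob = spec$section_weights),
        term = sub$term, cui = "", semantic_group = sub$group,
        experiencer = "Patient", assertion = "Present")
    } else {
      j <- ((seq_len(nrow(sub)) - 1L) %% n_fcn_docs) + 1L
      tibble::tibble(
        patient_id = sub$patient, document_id = fcn_doc(p, j),
        corpus_tag = "CN", note_date = initial[p] + fcn_days[cbind(p, j)],
        section = sample(sections, nrow(sub), replace = TRUE,
                         prob = spec$section_weights),
        term = sub$term, cui = "", semantic_group = sub$group,
        experiencer = "Patient", assertion = "Present")
    }
  }

  for (r in region_labels()) {
    sub <- inventory[inventory$region == r, , drop = FALSE]
    if (nrow(sub) == 0) next
    for (corpus in membership[[r]]) {
      rows[[paste(r, corpus)]] <- emit(sub, corpus)
    }
  }
  records <- dplyr::bind_rows(rows)

  # duplicate mentions (set semantics must absorb them); duplicates of CN
  # rows resample their section, exercising multi-section concepts
  if (spec$mention_lambda > 0) {
    n_dup <- stats::rpois(nrow(records), spec$mention_lambda)
    dup <- records[rep(seq_len(nrow(records)), n_dup), , drop = FALSE]
    cn_dup <- dup$corpus_tag == "CN"
    dup$section[cn_dup] <- sample(sections, sum(cn_dup), replace = TRUE,
                                  prob = spec$section_weights)
    records <- dplyr::bind_rows(records, dup)
  }

  # experiencer = Others distractors: fresh family-history terms that would
  # corrupt every downstream set if the filter were skipped
  n_others <- ceiling(spec$others_fraction * nrow(records))
  if (n_others > 0) {
    src <- records[sample.int(nrow(records), n_others, replace = TRUE), ,
                   drop = FALSE]
    src$term <- sprintf("family history finding %06d", seq_len(n_others))
    src$semantic_group <- "DISO"
    src$experiencer <- "Others"
    records <- dplyr::bind_rows(records, src)
  }

  # unassignable-note distractors: a pre-referral note and a day-(window+1)
  # note for some patients, with fresh terms
  late_p <- which((seq_len(spec$n_patients) %% 13L) == 0L)
  if (length(late_p) > 0) {
    distract <- dplyr::bind_rows(
      tibble::tibble(
        patient_id = patients[late_p],
        document_id = sprintf("CN-%s-prior", patients[late_p]),
        corpus_tag = "CN", note_date = reference[late_p] - 5L,
        section = "History of present illness",
        term = sprintf("prior visit finding %04d", late_p), cui = "",
        semantic_group = "FIND", experiencer = "Patient",
        assertion = "Present"),
      tibble::tibble(
        patient_id = patients[late_p],
        document_id = sprintf("CN-%s-late", patients[late_p]),
        corpus_tag = "CN", note_date = initial[late_p] + 91L,
        section = "Impression/report/plan",
        term = sprintf("late visit finding %04d", late_p), cui = "",
        semantic_group = "FIND", experiencer = "Patient",
        assertion = "Present"))
    records <- dplyr::bind_rows(records, distract)
  }

  ## --- metadata sidecar -------------------------------------------------
  fallback <- stats::runif(spec$n_patients) < spec$pdf_fallback_fraction
  meta_expert <- tibble::tibble(
    patient_id = rep(patients[!fallback], each = 2),
    document_id = paste0(rep(omr_doc(which(!fallback)), each = 2),
                         c("", "-older")),
    source = "expert_metadata",
    date = as.Date(rep(reference[!fallback], each = 2)) - c(0L, 30L))
  meta_pdf <- tibble::tibble(
    patient_id = patients, document_id = omr_doc(seq_len(spec$n_patients)),
    source = "pdf_creation", date = reference)
  metadata <- dplyr::bind_rows(meta_expert, meta_pdf)
  metadata <- metadata[order(metadata$patient_id, metadata$source,
                             metadata$document_id), , drop = FALSE]

  ## --- terminology + near matches ---------------------------------------
  tg <- generate_terminology(spec)
  g_rows <- which(inventory$region == "G")
  e_rows <- which(inventory$region == "E")
  n_near <- min(floor(spec$near_match_fraction * length(g_rows)),
                length(e_rows))
  if (n_near > 0) {
    # each near pair gets a dedicated two-node spur hung off the tree root:
    # the region-G term sits on the spur's leaf, the region-E term on the
    # spur's inner node, so the planted pair is exactly one is-a step apart
    # (similarity 1/2) and no cross-pair or cross-term similarity reaches 1
    n0 <- spec$n_terminology_concepts
    inner <- sprintf("K%06d", n0 + 2L * seq_len(n_near) - 1L)
    leaf <- sprintf("K%06d", n0 + 2L * seq_len(n_near))
    concepts <- dplyr::bind_rows(
      tg$concepts,
      tibble::tibble(id = c(rbind(inner, leaf)),
                     preferred_term = paste("near node", c(rbind(inner, leaf)))))
    edges <- rbind(tg$edges,
                   cbind(inner, rep(tg$concepts$id[1], n_near)),
                   cbind(leaf, inner))
    extra <- c(stats::setNames(leaf, inventory$term[g_rows[seq_len(n_near)]]),
               stats::setNames(inner, inventory$term[e_rows[seq_len(n_near)]]))
    tg <- terminology_graph(concepts, c(tg$term_map, extra), edges)
  }
  if (spec$map_exact_terms) {
    # each overlap term gets its own tree node (allocated from the top of
    # the id range; near-match spurs live on appended nodes, so exact and
    # near similarities cannot interfere)
    overlap_terms <- unique(inventory$term[inventory$region %in%
                                             c("A", "B", "C")])
    if (spec$n_terminology_concepts < length(overlap_terms)) {
      stop("infeasible spec: map_exact_terms needs n_terminology_concepts ",
           ">= ", length(overlap_terms), call. = FALSE)
    }
    node_ids <- sprintf("K%06d",
                        spec$n_terminology_concepts -
                          seq_along(overlap_terms) + 1L)
    extra <- stats::setNames(node_ids, overlap_terms)
    extra <- extra[!(names(extra) %in% names(tg$term_map))]
    tg <- terminology_graph(tg$concepts, c(tg$term_map, extra), tg$edges)
  }

  ## --- background frequency profile -------------------------------------
  prof_key <- dplyr::distinct(inventory[c("term", "group")])
  keep <- stats::runif(nrow(prof_key)) >= spec$unmapped_fraction
  prof <- prof_key[keep, , drop = FALSE]
  overall <- spec$background_frequency_scale *
    (1L + sample.int(50L, nrow(prof), replace = TRUE))
  specialty <- round(overall * stats::rbeta(nrow(prof), 1, 9))
  exclusive <- character(0)
  e_terms <- dplyr::distinct(inventory[inventory$region == "E",
                                       c("term", "group")])
  n_excl <- min(spec$n_specialty_exclusive, nrow(e_terms))
  if (n_excl > 0) {
    exclusive <- paste(e_terms$term[seq_len(n_excl)],
                       e_terms$group[seq_len(n_excl)], sep = "::")
    is_excl <- paste(prof$term, prof$group, sep = "::") %in% exclusive
    specialty[is_excl] <- overall[is_excl]
  }
  profile <- frequency_profile(tibble::tibble(
    term = prof$term, semantic_group = prof$group,
    specialty_count = specialty, overall_count = overall))

  ## --- write ------------------------------------------------------------
  paths <- list(
    annotations = file.path(dir, "annotations.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    terminology = file.path(dir, "terminology.tsv"),
    background = file.path(dir, "background.tsv"),
    manifest = file.path(dir, "manifest.json"))
  write_annotations(records, paths$annotations)
  write_metadata(metadata, paths$metadata)
  write_terminology(tg, paths$terminology)
  write_frequency_profile(profile, paths$background)
  manifest <- spec
  manifest$reference_date <- format(spec$reference_date, "%Y-%m-%d")
  manifest$region_cardinalities <- as.list(spec$region_cardinalities)
  jsonlite::write_json(unclass(manifest), paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(
    paths = paths,
    inventory = inventory,
    concept_keys = split(inventory$key, inventory$region),
    specialty_exclusive = exclusive,
    terminology = tg,
    profile = profile))
}
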