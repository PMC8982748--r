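#' Round half-up
#'
#' Decimal rounding with ties going away from zero, as used when rendering
#' the printed percentage tables (base `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Render a share as a percentage
#'
#' @param num,den Numerator and denominator counts.
#' @param digits Decimal places (default 2, matching the printed tables).
#' @return Numeric percentage, rounded half-up.
#' @export
pct <- function(num, den, digits = 2) {
  round_half_up(100 * num / den, digits)
}

region_labels <- function() c("A", "B", "C", "D", "E", "F", "G")

#' Partition three concept sets into the seven Venn regions
#'
#' The OMR, ICN and FCN concept sets decompose into seven disjoint regions:
#' \describe{
#'   \item{A}{in all three corpora}
#'   \item{B}{OMR and ICN only — used at the initial encounter, dropped in
#'     follow-up}
#'   \item{C}{OMR and FCN only — overlooked initially, rediscovered in
#'     follow-up}
#'   \item{D}{ICN and FCN only — new at the specialty, carried forward}
#'   \item{E}{ICN only}
#'   \item{F}{FCN only}
#'   \item{G}{OMR only — never incorporated at the specialty}
#' }
#'
#' @param omr,icn,fcn Concept sets from [build_concept_set()].
#' @return A `region_partition`: list with `regions` (named list of key
#'   vectors A–G) and the three source key sets.
#' @export
partition_regions <- function(omr, icn, fcn) {
  o <- omr$key; i <- icn$key; f <- fcn$key
  in_o <- unique(o)
  in_i <- unique(i)
  in_f <- unique(f)
  all_keys <- unique(c(in_o, in_i, in_f))
  mo <- all_keys %in% in_o
  mi <- all_keys %in% in_i
  mf <- all_keys %in% in_f
  regions <- list(
    A = all_keys[mo & mi & mf],
    B = all_keys[mo & mi & !mf],
    C = all_keys[mo & !mi & mf],
    D = all_keys[!mo & mi & mf],
    E = all_keys[!mo & mi & !mf],
    F = all_keys[!mo & !mi & mf],
    G = all_keys[mo & !mi & !mf])
  structure(
    list(regions = regions, omr = in_o, icn = in_i, fcn = in_f),
    class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  n <- vapply(x$regions, length, integer(1))
  cat("<region_partition: |OMR| = ", length(x$omr),
      ", |ICN| = ", length(x$icn), ", |FCN| = ", length(x$fcn), ">\n",
      sep = "")
  print(n)
  invisible(x)
}

#' Summarise a region partition
#'
#' Region cardinalities plus the derived corpus-level shares: the OMR/CN
#' overlap (A ∪ B ∪ C) as a share of the overall union and of each corpus,
#' and each overlap region's share of the overlap.
#'
#' @param partition A [partition_regions()] result.
#' @return List of counts and percentages (2-decimal, half-up).
#' @export
region_summary <- function(partition) {
  n <- vapply(partition$regions, length, integer(1))
  n_overlap <- n[["A"]] + n[["B"]] + n[["C"]]
  n_union <- sum(n)
  n_cn_union <- n_union - n[["G"]]
  list(
    n_regions = n,
    n_omr = length(partition$omr),
    n_icn = length(partition$icn),
    n_fcn = length(partition$fcn),
    n_union = n_union,
    n_overlap = n_overlap,
    n_cn_union = n_cn_union,
    pct_overlap_of_union = pct(n_overlap, n_union),
    pct_overlap_of_omr = pct(n_overlap, length(partition$omr)),
    pct_overlap_of_cn_union = pct(n_overlap, n_cn_union),
    pct_omr_of_union = pct(length(partition$omr), n_union),
    pct_overlap_in_icn = pct(n[["A"]] + n[["B"]], n_overlap),
    pct_overlap_in_fcn = pct(n[["A"]] + n[["C"]], n_overlap),
    pct_region_of_overlap = stats::setNames(
      pct(n[c("A", "B", "C")], n_overlap), c("A", "B", "C")))
}

#' Exact intersection ratio
#'
#' `r_e = |C_OMR` \eqn{\cap} `C_CN| / |C_CN|`: the share of consultant-note
#' concepts that also appear, with identical key, in the OMRs.
#'
#' @param omr,cn Concept sets.
#' @return A number in \[0, 1\].
#' @export
exact_intersection_ratio <- function(omr, cn) {
  if (nrow(cn) == 0) {
    stop("undefined ratio: consultant-note concept set is empty", call. = FALSE)
  }
  length(intersect(unique(omr$key), unique(cn$key))) / length(unique(cn$key))
}

#' Best flexible match of OMR concepts into the consultant-note set
#'
#' For every OMR concept, evaluates the path-measure similarity of its term
#' against every consultant-note concept's term and records the best match
#' when its similarity exceeds `threshold`. Similarity is computed on
#' normalized terms only (semantic group and patient are dropped for the
#' terminology lookup); ties are broken by the lexicographically smallest
#' rendered CN key. `C_SIMILAR` is the set of distinct CN concepts chosen.
#'
#' @param omr,cn Concept sets.
#' @param tg A [terminology_graph()].
#' @param threshold Minimum similarity, in \[0, 1); a match must score
#'   strictly above it. The default 0 admits any mapped, connected pair.
#' @return A `match_result`: list with `matches` (tibble of `omr_key`,
#'   `cn_key`, `similarity`), `c_similar` (character vector of CN keys), and
#'   `threshold`.
#' @export
best_flexible_match <- function(omr, cn, tg, threshold = 0) {
  stopifnot(threshold >= 0, threshold < 1)
  omr_keys <- unique(omr$key)
  cn_tab <- dplyr::distinct(tibble::tibble(term = cn$term, key = cn$key))
  # order CN keys so that ties resolve to the lexicographically smallest key
  cn_tab <- cn_tab[order(cn_tab$key, method = "radix"), , drop = FALSE]
  omr_terms <- split_concept_key(omr_keys)$term

  u_omr_terms <- unique(omr_terms)
  u_cn_terms <- unique(cn_tab$term)
  sim <- term_similarity_matrix(tg, u_omr_terms, u_cn_terms)

  # per CN term, the smallest rendered key carrying it
  first_key <- tapply(cn_tab$key, cn_tab$term, `[[`, 1)

  rows <- match(omr_terms, u_omr_terms)
  best_col <- max.col(sim[rows, , drop = FALSE], ties.method = "first")
  best_sim <- sim[cbind(rows, best_col)]
  keep <- best_sim > threshold
  # among equally-similar CN terms, pick the lexicographically smallest key
  matches <- tibble::tibble(
    omr_key = omr_keys[keep],
    similarity = best_sim[keep])
  if (nrow(matches) > 0) {
    matches$cn_key <- vapply(which(keep), function(idx) {
      r <- rows[idx]
      tied_terms <- u_cn_terms[sim[r, ] == best_sim[idx]]
      min(unname(first_key[tied_terms]))
    }, character(1))
    matches <- matches[c("omr_key", "cn_key", "similarity")]
  } else {
    matches$cn_key <- character(0)
    matches <- matches[c("omr_key", "cn_key", "similarity")]
  }
  structure(
    list(matches = matches,
         c_similar = sort(unique(matches$cn_key)),
         threshold = threshold),
    class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result: ", nrow(x$matches), " OMR concepts matched, |C_SIMILAR| = ",
      length(x$c_similar), ", threshold > ", x$threshold, ">\n", sep = "")
  invisible(x)
}

#' Flexible intersection ratio
#'
#' `r_s = |C_SIMILAR| / |C_CN|`. Because `C_SIMILAR` counts distinct
#' consultant-note concepts chosen as best matches, `r_s` never exceeds 1,
#' and it dominates the exact ratio whenever every exact-overlap term is in
#' the terminology (an exact match scores 1 and is its own argmax).
#'
#' @param match A [best_flexible_match()] result.
#' @param cn The consultant-note concept set used in the match.
#' @return A number in \[0, 1\].
#' @export
flexible_intersection_ratio <- function(match, cn) {
  if (nrow(cn) == 0) {
    stop("undefined ratio: consultant-note concept set is empty", call. = FALSE)
  }
  length(match$c_similar) / length(unique(cn$key))
}

#' Semantic-group coverage of the OMR/CN overlap
#'
#' For the concepts shared between OMRs and consultant notes (regions A, B
#' and C), tabulates per semantic group how the group's concepts distribute
#' across the three regions, as frequencies and percentages of the group's
#' total in A ∪ B ∪ C. Groups absent from all three regions are omitted; a
#' grand-total row is appended.
#'
#' @param partition A [partition_regions()] result.
#' @return Tibble with columns `semantic_group`, then frequency and
#'   percentage per region (`freq_A`, `pct_A`, ...), and `total`.
#' @export
semtype_coverage_table <- function(partition) {
  per_region <- lapply(partition$regions[c("A", "B", "C")], function(keys) {
    if (length(keys) == 0) {
      return(tibble::tibble(semantic_group = character(0), n = integer(0)))
    }
    dplyr::count(split_concept_key(keys), .data$semantic_group)
  })
  groups <- sort(unique(unlist(lapply(per_region, `[[`, "semantic_group"))))
  tab <- tibble::tibble(semantic_group = groups)
  for (r in c("A", "B", "C")) {
    cnt <- per_region[[r]]
    tab[[paste0("freq_", r)]] <-
      ifelse(is.na(match(groups, cnt$semantic_group)), 0L,
             cnt$n[match(groups, cnt$semantic_group)])
  }
  tab$total <- tab$freq_A + tab$freq_B + tab$freq_C
  totals <- tibble::tibble(
    semantic_group = "Total",
    freq_A = sum(tab$freq_A), freq_B = sum(tab$freq_B),
    freq_C = sum(tab$freq_C), total = sum(tab$total))
  tab <- tab[order(-tab$total), , drop = FALSE]
  tab <- dplyr::bind_rows(tab, totals)
  for (r in c("A", "B", "C")) {
    tab[[paste0("pct_", r)]] <- pct(tab[[paste0("freq_", r)]], tab$total)
  }
  tab[c("semantic_group", "freq_A", "pct_A", "freq_B", "pct_B",
        "freq_C", "pct_C", "total")]
}

#' Per-group exact and flexible coverage of OMR concepts by each CN corpus
#'
#' For each semantic group, the share of that group's ICN (resp. FCN)
#' concepts that match an OMR concept: exactly (identical key), and — when a
#' terminology is supplied — flexibly via [best_flexible_match()]. The
#' denominator is the group's cardinality in the CN corpus, so the total row
#' reproduces the corpus-level ratios `r_e` and `r_s`.
#'
#' @param omr,icn,fcn Concept sets.
#' @param tg Optional [terminology_graph()]; when `NULL` the flexible
#'   columns are `NA`.
#' @param threshold Flexible-match threshold, as in [best_flexible_match()].
#' @return Tibble: `semantic_group`, `n_icn`, `exact_icn_pct`,
#'   `flexible_icn_pct`, `n_fcn`, `exact_fcn_pct`, `flexible_fcn_pct`,
#'   with a `"Total"` row.
#' @export
match_coverage_table <- function(omr, icn, fcn, tg = NULL, threshold = 0) {
  one_corpus <- function(cn) {
    cn_tab <- split_concept_key(unique(cn$key))
    cn_tab$exact <- cn_tab$key %in% omr$key
    if (!is.null(tg)) {
      m <- best_flexible_match(omr, cn, tg, threshold)
      cn_tab$flexible <- cn_tab$key %in% m$c_similar
    } else {
      cn_tab$flexible <- NA
    }
    cn_tab
  }
  summarise_corpus <- function(cn_tab) {
    by_group <- dplyr::group_by(cn_tab, .data$semantic_group)
    out <- dplyr::summarise(
      by_group, n = dplyr::n(), exact = sum(.data$exact),
      flexible = sum(.data$flexible), .groups = "drop")
    total <- tibble::tibble(
      semantic_group = "Total", n = sum(out$n), exact = sum(out$exact),
      flexible = sum(out$flexible))
    dplyr::bind_rows(out, total)
  }
  i_tab <- summarise_corpus(one_corpus(icn))
  f_tab <- summarise_corpus(one_corpus(fcn))
  groups <- union(i_tab$semantic_group, f_tab$semantic_group)
  groups <- c(setdiff(groups, "Total"), "Total")
  res <- tibble::tibble(semantic_group = groups)
  mi <- match(groups, i_tab$semantic_group)
  mf <- match(groups, f_tab$semantic_group)
  res$n_icn <- ifelse(is.na(mi), 0L, i_tab$n[mi])
  res$exact_icn_pct <- pct(ifelse(is.na(mi), 0L, i_tab$exact[mi]), res$n_icn)
  res$flexible_icn_pct <- pct(ifelse(is.na(mi), NA, i_tab$flexible[mi]), res$n_icn)
  res$n_fcn <- ifelse(is.na(mf), 0L, f_tab$n[mf])
  res$exact_fcn_pct <- pct(ifelse(is.na(mf), 0L, f_tab$exact[mf]), res$n_fcn)
  res$flexible_fcn_pct <- pct(ifelse(is.na(mf), NA, f_tab$flexible[mf]), res$n_fcn)
  res
}

#' Section incidence of a concept set in the consultant notes
#'
#' Counts distinct (concept, section) incidences: a concept appearing in
#' both "Diagnosis" and "Impression/report/plan" contributes 2, while a
#' concept repeated in one section across three documents contributes 1.
#' Records whose section is not a recognised label are counted under
#' `"UNKNOWN"` with a warning.
#'
#' @param records Annotation tibble restricted to the CN corpora.
#' @param concepts Concept set to restrict to.
#' @return Tibble `section`, `n`, sorted by decreasing `n`.
#' @export
section_distribution <- function(records, concepts) {
  if (nrow(records) == 0 || nrow(concepts) == 0) {
    return(tibble::tibble(section = character(0), n = integer(0)))
  }
  section <- records$section
  unknown <- !(section %in% note_sections())
  if (any(unknown)) {
    warning(sum(unknown), " record(s) with unrecognised section label(s) ",
            paste(unique(section[unknown]), collapse = ", "),
            " counted under UNKNOWN", call. = FALSE)
    section[unknown] <- "UNKNOWN"
  }
  keys <- concept_key(records$term, records$semantic_group, records$patient_id)
  keep <- keys %in% concepts$key
  incidences <- dplyr::distinct(
    tibble::tibble(key = keys[keep], section = section[keep]))
  out <- dplyr::count(incidences, .data$section)
  out[order(-out$n, out$section), , drop = FALSE]
}
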