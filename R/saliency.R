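#' Construct a background frequency profile
#'
#' Mention frequencies per (term, semantic group) — patient id is dropped
#' here: saliency is a population-level ratio of how often a concept is
#' mentioned in the specialty's notes versus across all practice settings.
#' Counts are raw mention frequencies, not per-patient indicators.
#'
#' @param df Tibble/data.frame with columns `term`, `semantic_group`,
#'   `specialty_count`, `overall_count`.
#' @return A validated `frequency_profile` tibble.
#' @export
frequency_profile <- function(df) {
  df <- tibble::as_tibble(df)
  needed <- c("term", "semantic_group", "specialty_count", "overall_count")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("frequency profile schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[needed]
  df$term <- normalize_term(df$term)
  df$semantic_group <- canonicalize_semgroup(df$semantic_group)
  df$specialty_count <- as.numeric(df$specialty_count)
  df$overall_count <- as.numeric(df$overall_count)
  if (anyDuplicated(paste(df$term, df$semantic_group, sep = "\r"))) {
    stop("frequency profile has duplicate (term, semantic_group) keys",
         call. = FALSE)
  }
  if (any(df$specialty_count > df$overall_count)) {
    stop("frequency profile invariant violated: specialty count exceeds ",
         "overall count for ",
         sum(df$specialty_count > df$overall_count), " concept(s)",
         call. = FALSE)
  }
  if (any(df$specialty_count < 0) || any(df$overall_count < 0)) {
    stop("frequency profile counts must be non-negative", call. = FALSE)
  }
  class(df) <- c("frequency_profile", class(tibble::tibble()))
  df
}

#' Read / write a frequency-profile file
#'
#' UTF-8 tab-separated with header columns `term`, `semantic_group`,
#' `specialty_count`, `overall_count`.
#'
#' @param path File path.
#' @return [frequency_profile()] tibble (read); `path` invisibly (write).
#' @export
read_frequency_profile <- function(path) {
  if (!file.exists(path)) {
    stop("frequency profile file not found: ", path, call. = FALSE)
  }
  df <- readr::read_tsv(path, col_types = readr::cols(
    term = readr::col_character(),
    semantic_group = readr::col_character(),
    specialty_count = readr::col_double(),
    overall_count = readr::col_double()), progress = FALSE)
  frequency_profile(df)
}

#' @rdname read_frequency_profile
#' @param profile A [frequency_profile()].
#' @export
write_frequency_profile <- function(profile, path) {
  readr::write_tsv(profile, path, progress = FALSE)
  invisible(path)
}

#' Saliency score of concepts against the background corpus
#'
#' `score = specialty mentions / overall mentions`. A score of 1 marks a
#' concept mentioned exclusively in the specialty's notes; near 0, a
#' concept common everywhere or rarely used in the specialty. Concepts
#' absent from the background corpus have no score (`NA`): they cannot be
#' mapped and reduce a region's coverage ratio instead.
#'
#' @param profile A [frequency_profile()].
#' @param term,semantic_group Concept coordinates, paired elementwise.
#' @return Numeric scores in \[0, 1\], `NA` where unmapped.
#' @export
concept_saliency <- function(profile, term, semantic_group) {
  idx <- match(paste(normalize_term(term),
                     canonicalize_semgroup(semantic_group), sep = "\r"),
               paste(profile$term, profile$semantic_group, sep = "\r"))
  score <- profile$specialty_count[idx] / profile$overall_count[idx]
  score[!is.na(idx) & profile$overall_count[idx] == 0] <- NA
  score
}

#' Aggregate saliency over one region
#'
#' Maps each regional concept key to its (term, semantic group) pair —
#' patient id is dropped, but each key still counts once, so a term shared
#' by several patients contributes once per patient, matching the region
#' cardinalities. Reports the mapped count (keys whose concept occurs in
#' the background corpus), the coverage ratio to the original region, the
#' score sum, and the average. The average divides by the number of
#' strictly positive scores; the variant dividing by the mapped count is
#' also returned (`average_mapped`) since the two differ only when mapped
#' concepts score exactly 0.
#'
#' @param profile A [frequency_profile()].
#' @param region_keys Character vector of concept keys for the region.
#' @return List: `n_original`, `n_mapped`, `coverage_pct` (2-decimal
#'   half-up), `sum_score`, `n_positive`, `average` (3-decimal half-up; 0
#'   with `all_zero = TRUE` when no score is positive), `average_mapped`.
#' @export
region_average_saliency <- function(profile, region_keys) {
  region_keys <- unique(region_keys)
  n_original <- length(region_keys)
  if (n_original == 0) {
    return(list(n_original = 0L, n_mapped = 0L, coverage_pct = NA_real_,
                sum_score = 0, n_positive = 0L, average = 0,
                average_mapped = 0, all_zero = TRUE))
  }
  parts <- split_concept_key(region_keys)
  score <- concept_saliency(profile, parts$term, parts$semantic_group)
  mapped <- !is.na(score)
  n_mapped <- sum(mapped)
  sum_score <- sum(score[mapped])
  n_positive <- sum(score[mapped] > 0)
  list(
    n_original = n_original,
    n_mapped = n_mapped,
    coverage_pct = pct(n_mapped, n_original),
    sum_score = sum_score,
    n_positive = n_positive,
    average = if (n_positive > 0) round_half_up(sum_score / n_positive, 3) else 0,
    average_mapped = if (n_mapped > 0)
      round_half_up(sum_score / n_mapped, 3) else 0,
    all_zero = n_positive == 0L)
}

#' Rank the most specialty-salient concepts of a region
#'
#' Concepts ordered by score descending; ties broken by higher overall
#' (background) mention frequency, then by lexicographic
#' `term::GROUP` key. Patient ids are dropped: the ranking is over distinct
#' (term, semantic group) concepts.
#'
#' @param profile A [frequency_profile()].
#' @param region_keys Character vector of concept keys for the region.
#' @param k Number of concepts to return; if larger than the region's
#'   mapped concept count the full list is returned.
#' @return Tibble `term`, `semantic_group`, `concept`, `score`,
#'   `overall_count`, at most `k` rows.
#' @export
rank_salient_concepts <- function(profile, region_keys, k = 5) {
  stopifnot(k >= 0)
  parts <- dplyr::distinct(
    split_concept_key(unique(region_keys))[c("term", "semantic_group")])
  score <- concept_saliency(profile, parts$term, parts$semantic_group)
  idx <- match(paste(parts$term, parts$semantic_group, sep = "\r"),
               paste(profile$term, profile$semantic_group, sep = "\r"))
  out <- tibble::tibble(
    term = parts$term,
    semantic_group = parts$semantic_group,
    concept = paste(parts$term, parts$semantic_group, sep = "::"),
    score = score,
    overall_count = profile$overall_count[idx])
  out <- out[!is.na(out$score), , drop = FALSE]
  ord <- order(-out$score, -out$overall_count, out$concept, method = "radix")
  utils::head(out[ord, , drop = FALSE], k)
}

#' Saliency report over all seven regions
#'
#' A region-by-region table of mapped concept counts, coverage to the
#' original region, score sums and averages, plus the top-`k` salient
#' concepts per region.
#'
#' @param profile A [frequency_profile()].
#' @param partition A [partition_regions()] result.
#' @param k Top concepts to list per region.
#' @return List with `table` (tibble, one row per region A–G) and `top`
#'   (named list of per-region ranking tibbles).
#' @export
saliency_table <- function(profile, partition, k = 5) {
  rows <- lapply(region_labels(), function(r) {
    s <- region_average_saliency(profile, partition$regions[[r]])
    tibble::tibble(
      region = r,
      n_original = s$n_original,
      n_mapped = s$n_mapped,
      coverage_pct = s$coverage_pct,
      sum_score = round_half_up(s$sum_score, 2),
      average = s$average,
      average_mapped = s$average_mapped,
      all_zero = s$all_zero)
  })
  top <- lapply(partition$regions, function(keys)
    rank_salient_concepts(profile, keys, k))
  list(table = dplyr::bind_rows(rows), top = top)
}
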