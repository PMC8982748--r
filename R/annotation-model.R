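#' @importFrom rlang .data
#' @importFrom stats setNames
NULL

#' Recognised semantic-group codes
#'
#' The coarse UMLS-style category codes an annotation's semantic group is
#' built from. A group may be compound: a single mention tagged with several
#' types (e.g. warfarin as both a chemical and a drug) carries the
#' semicolon-joined, sorted code set `"CHEM;DRUG"`.
#'
#' @return Character vector of the eight atomic codes.
#' @export
semantic_group_codes <- function() {
  c("ACTI", "ANAT", "CHEM", "CONC", "DISO", "DRUG", "FIND", "PROC")
}

#' Recognised note-section labels
#'
#' The twelve section names used in consultant notes, plus `"UNKNOWN"` for
#' records without section structure (all OMR pages fall here).
#'
#' @return Character vector of 13 section labels.
#' @export
note_sections <- function() {
  c("Allergy",
    "Chief Complaint and reason for visit",
    "Current Medications",
    "Diagnosis",
    "Family History",
    "History of present illness",
    "Impression/report/plan",
    "Past medical and surgical history",
    "Physical Exam",
    "Social History",
    "System Review",
    "Vital Signs",
    "UNKNOWN")
}

annotation_columns <- function() {
  c("patient_id", "document_id", "corpus_tag", "note_date", "section",
    "term", "cui", "semantic_group", "experiencer", "assertion")
}

#' Canonicalize semantic-group strings
#'
#' Splits each group on `";"`, trims, deduplicates and sorts the codes, and
#' rejoins, so `"DRUG;CHEM"` and `"CHEM;DRUG"` collapse to the single
#' canonical form `"CHEM;DRUG"`. Idempotent.
#'
#' @param x Character vector of semantic-group strings.
#' @param strict Validate codes against [semantic_group_codes()]?
#' @return Character vector of canonical group strings.
#' @export
canonicalize_semgroup <- function(x, strict = TRUE) {
  parts <- strsplit(as.character(x), ";", fixed = TRUE)
  out <- vapply(parts, function(p) {
    p <- trimws(p)
    p <- p[nzchar(p)]
    paste(sort(unique(p)), collapse = ";")
  }, character(1))
  if (strict) {
    codes <- unique(unlist(strsplit(out, ";", fixed = TRUE)))
    bad <- setdiff(codes, semantic_group_codes())
    if (length(bad) > 0) {
      offending <- which(vapply(
        strsplit(out, ";", fixed = TRUE),
        function(p) any(p %in% bad), logical(1)))
      stop("unknown semantic code(s) ", paste(bad, collapse = ", "),
           " in row(s) ", paste(utils::head(offending, 10), collapse = ", "),
           call. = FALSE)
    }
    if (any(!nzchar(out))) {
      stop("empty semantic_group in row(s) ",
           paste(utils::head(which(!nzchar(out)), 10), collapse = ", "),
           call. = FALSE)
    }
  }
  out
}

#' Normalize a surface term
#'
#' Case-folds and collapses internal whitespace. No stemming: the NER engine
#' already emits normalized preferred terms and the pipeline must not
#' re-normalize their semantics.
#'
#' @param x Character vector of terms.
#' @return Normalized terms.
#' @export
normalize_term <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Render concept keys
#'
#' A concept is unique per (normalized term, canonical semantic group,
#' patient); its rendered key is `"term::GROUP::patient"`, e.g.
#' `"chest xray::PROC::0000"`.
#'
#' @param term,semantic_group,patient_id Character vectors, recycled.
#' @return Character vector of rendered keys.
#' @export
concept_key <- function(term, semantic_group, patient_id) {
  if (length(term) == 0 || length(semantic_group) == 0 ||
      length(patient_id) == 0) {
    return(character(0))
  }
  paste(term, semantic_group, patient_id, sep = "::")
}

#' Split rendered concept keys back into their components
#'
#' @param key Character vector of `"term::GROUP::patient"` keys.
#' @return Tibble with columns `term`, `semantic_group`, `patient_id`, `key`.
#' @export
split_concept_key <- function(key) {
  if (length(key) == 0) {
    return(tibble::tibble(term = character(0), semantic_group = character(0),
                          patient_id = character(0), key = character(0)))
  }
  parts <- strsplit(key, "::", fixed = TRUE)
  n <- lengths(parts)
  if (any(n != 3)) {
    stop("malformed concept key(s): ",
         paste(utils::head(key[n != 3], 5), collapse = ", "), call. = FALSE)
  }
  m <- matrix(unlist(parts), ncol = 3, byrow = TRUE)
  tibble::tibble(term = m[, 1], semantic_group = m[, 2], patient_id = m[, 3],
                 key = key)
}

validate_annotations <- function(df) {
  missing_cols <- setdiff(annotation_columns(), names(df))
  if (length(missing_cols) > 0) {
    stop("annotation schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)[annotation_columns()]
  df$patient_id <- as.character(df$patient_id)
  df$document_id <- as.character(df$document_id)
  df$corpus_tag <- as.character(df$corpus_tag)
  bad_tag <- setdiff(unique(df$corpus_tag), c("OMR", "CN", "ECN", "ICN", "FCN"))
  if (length(bad_tag) > 0) {
    stop("unknown corpus_tag value(s): ", paste(bad_tag, collapse = ", "),
         call. = FALSE)
  }
  if (!inherits(df$note_date, "Date")) {
    df$note_date <- parse_date_lenient(df$note_date)
  }
  df$section <- as.character(df$section)
  df$section[is.na(df$section) | !nzchar(df$section)] <- "UNKNOWN"
  # OMR pages have no section structure
  df$section[df$corpus_tag == "OMR"] <- "UNKNOWN"
  df$term <- normalize_term(df$term)
  df$cui <- as.character(df$cui)
  df$semantic_group <- canonicalize_semgroup(df$semantic_group)
  df$experiencer <- as.character(df$experiencer)
  bad_exp <- setdiff(unique(df$experiencer), c("Patient", "Others"))
  if (length(bad_exp) > 0) {
    stop("unknown experiencer value(s): ", paste(bad_exp, collapse = ", "),
         call. = FALSE)
  }
  df$assertion <- as.character(df$assertion)
  df
}

# Unparseable dates become NA, never an error.
parse_date_lenient <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & !nzchar(x)] <- NA_character_
  suppressWarnings(as.Date(x, format = "%Y-%m-%d"))
}

#' Read an annotation file
#'
#' Two on-disk formats carry the same ten fields (`patient_id`,
#' `document_id`, `corpus_tag`, `note_date`, `section`, `term`, `cui`,
#' `semantic_group`, `experiencer`, `assertion`): a UTF-8 tab-separated file
#' with a header row, or a record stream with one JSON object per line.
#' Semantic groups are canonicalized on read; unparseable dates become `NA`.
#'
#' @param path File to read.
#' @param format `"tsv"` (default) or `"jsonl"`.
#' @return Tibble of annotation records, one row per concept mention.
#' @export
read_annotations <- function(path, format = c("tsv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  df <- if (format == "tsv") {
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, na = character())
  } else {
    jsonlite::stream_in(file(path), verbose = FALSE) |> tibble::as_tibble()
  }
  if (nrow(df) == 0 && format == "tsv") {
    missing_cols <- setdiff(annotation_columns(), names(df))
    if (length(missing_cols) > 0) {
      stop("annotation schema error: missing column(s) ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
  }
  validate_annotations(df)
}

#' Write an annotation file
#'
#' Inverse of [read_annotations()]; a write/read round trip reproduces the
#' records field for field.
#'
#' @param records Annotation tibble.
#' @param path Destination file.
#' @param format `"tsv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(records, path, format = c("tsv", "jsonl")) {
  format <- match.arg(format)
  records <- validate_annotations(records)
  if (format == "tsv") {
    out <- records
    out$note_date <- ifelse(is.na(out$note_date), "",
                            format(out$note_date, "%Y-%m-%d"))
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    out <- records
    out$note_date <- ifelse(is.na(out$note_date), NA_character_,
                            format(out$note_date, "%Y-%m-%d"))
    con <- file(path, open = "wb")
    on.exit(close(con))
    jsonlite::stream_out(as.data.frame(out), con, verbose = FALSE)
  }
  invisible(path)
}

#' Keep only mentions experienced by the patient
#'
#' The analysis describes the referred patient's own status, so mentions
#' attributed to anyone else (e.g. a father's history of heart attack,
#' experiencer `"Others"`) are dropped before concept sets are built.
#' Order is preserved.
#'
#' @param records Annotation tibble.
#' @return The subset with `experiencer == "Patient"`.
#' @export
filter_patient_experiencer <- function(records) {
  records[records$experiencer == "Patient", , drop = FALSE]
}

#' Build the unique concept set of a corpus
#'
#' Reduces mention records to the set of distinct
#' (term, semantic group, patient) triples. A mention repeated a hundred
#' times contributes one member; the same term tagged FIND in one sentence
#' and PROC in another contributes two members.
#'
#' @param records Annotation tibble (already experiencer-filtered).
#' @param label Corpus name, e.g. `"C_OMR"`.
#' @return A `concept_set`: tibble of distinct `term`, `semantic_group`,
#'   `patient_id`, `key` rows with a `label` attribute.
#' @export
build_concept_set <- function(records, label = "C") {
  members <- dplyr::distinct(
    tibble::tibble(
      term = records$term,
      semantic_group = records$semantic_group,
      patient_id = records$patient_id))
  members$key <- concept_key(members$term, members$semantic_group,
                             members$patient_id)
  new_concept_set(members, label)
}

new_concept_set <- function(members, label) {
  stopifnot(all(c("term", "semantic_group", "patient_id", "key") %in%
                  names(members)))
  structure(tibble::as_tibble(members),
            label = label,
            class = c("concept_set", class(tibble::tibble())))
}

#' Construct a concept set directly from rendered keys
#'
#' @param keys Character vector of `"term::GROUP::patient"` keys.
#' @param label Corpus name.
#' @return A `concept_set`.
#' @export
concept_set_from_keys <- function(keys, label = "C") {
  new_concept_set(split_concept_key(unique(keys)), label)
}

#' Union of two concept sets
#'
#' Used to form the combined consultant-note set
#' `C_CN = C_ICN` \eqn{\cup} `C_FCN`.
#'
#' @param a,b Concept sets.
#' @param label Label for the union.
#' @return A `concept_set`.
#' @export
concept_set_union <- function(a, b, label = "C_CN") {
  concept_set_from_keys(union(a$key, b$key), label)
}

#' @export
print.concept_set <- function(x, ...) {
  cat("<concept_set ", attr(x, "label"), ": ", nrow(x), " unique concepts>\n",
      sep = "")
  NextMethod()
}

concept_set_label <- function(x) attr(x, "label")
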