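#' Read a date-metadata sidecar file
#'
#' UTF-8 tab-separated with header columns `patient_id`, `document_id`,
#' `source`, `date`. `source` is `"expert_metadata"` for dates populated by
#' the experts who reviewed the OMR pages, `"pdf_creation"` for the fax/PDF
#' creation-date fallback.
#'
#' @param path File to read.
#' @return Tibble with parsed `date` column.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, na = character())
  needed <- c("patient_id", "document_id", "source", "date")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("metadata schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(df$source), c("expert_metadata", "pdf_creation"))
  if (length(bad) > 0) {
    stop("unknown metadata source value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df$date <- parse_date_lenient(df$date)
  tibble::as_tibble(df[needed])
}

#' Write a date-metadata sidecar file
#'
#' @param metadata Tibble as returned by [read_metadata()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  out <- metadata
  out$date <- format(out$date, "%Y-%m-%d")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Resolve a patient's reference date
#'
#' The reference date anchors the patient's referral: the latest
#' expert-curated OMR date when any exists, otherwise the latest PDF
#' creation date. It is the date the Mayo "initial encounter" must follow.
#'
#' @param omr_dates Dates from expert metadata (may be empty).
#' @param pdf_dates PDF creation dates (fallback; may be empty).
#' @return A `Date` of length 1.
#' @export
resolve_reference_date <- function(omr_dates, pdf_dates) {
  omr_dates <- omr_dates[!is.na(omr_dates)]
  pdf_dates <- pdf_dates[!is.na(pdf_dates)]
  if (length(omr_dates) > 0) return(max(omr_dates))
  if (length(pdf_dates) > 0) return(max(pdf_dates))
  stop("unresolvable patient: no OMR metadata dates and no PDF creation dates",
       call. = FALSE)
}

#' Resolve the initial encounter date
#'
#' The earliest consultant-note date strictly after the reference date; a
#' note written the same day as the latest OMR date does not qualify.
#' Returns `NA` when no note follows the reference (such patients are
#' excluded downstream with a logged count).
#'
#' @param mayo_dates Consultant-note dates for the patient.
#' @param reference Reference date from [resolve_reference_date()].
#' @return A `Date` of length 1, possibly `NA`.
#' @export
resolve_initial_encounter <- function(mayo_dates, reference) {
  mayo_dates <- mayo_dates[!is.na(mayo_dates)]
  after <- mayo_dates[mayo_dates > reference]
  if (length(after) == 0) return(as.Date(NA))
  min(after)
}

#' Assign consultant notes to the ICN / FCN corpora
#'
#' Notes dated exactly on the initial encounter form the ICN corpus
#' (several per patient are allowed: one patient may visit multiple
#' practice settings on the encounter day). Notes 1 to `window` days after
#' it form the FCN corpus. Anything earlier or later is left unassigned.
#'
#' @param notes Tibble with columns `document_id`, `date`.
#' @param initial Initial encounter date.
#' @param window Follow-up window length in days (default 90).
#' @return `notes` with an added `corpus` column in
#'   `{"ICN", "FCN", "unassigned"}`.
#' @export
assign_note_corpus <- function(notes, initial, window = 90) {
  stopifnot(window >= 1)
  offset <- as.integer(notes$date - initial)
  corpus <- rep("unassigned", nrow(notes))
  corpus[!is.na(offset) & offset == 0] <- "ICN"
  corpus[!is.na(offset) & offset >= 1 & offset <= window] <- "FCN"
  notes$corpus <- corpus
  notes
}

#' Split a cohort's consultant notes into ICN and FCN corpora
#'
#' For each patient: resolve the reference date from the metadata sidecar,
#' pick the initial encounter as the first consultant note strictly after
#' it, and label every CN record ICN / FCN / unassigned. Patients whose
#' initial encounter cannot be resolved are dropped and counted.
#'
#' @param records Annotation tibble; CN rows must carry valid `note_date`.
#' @param metadata Metadata tibble from [read_metadata()].
#' @param window Follow-up window in days (default 90).
#' @return List with elements:
#'   \describe{
#'     \item{records}{annotations with `corpus_tag` rewritten to
#'       `OMR`/`ICN`/`FCN`; unassigned CN rows removed}
#'     \item{assignments}{per-patient tibble: reference and initial dates,
#'       ICN/FCN note counts}
#'     \item{dropped}{list of counts: unresolvable patients, notes before
#'       the initial encounter, notes after the window}
#'   }
#' @export
assign_corpora <- function(records, metadata, window = 90) {
  cn <- records[records$corpus_tag == "CN", , drop = FALSE]
  other <- records[records$corpus_tag != "CN", , drop = FALSE]

  patients <- unique(cn$patient_id)
  assignments <- vector("list", length(patients))
  doc_corpus <- vector("list", length(patients))
  n_unresolvable <- 0L

  for (i in seq_along(patients)) {
    pid <- patients[[i]]
    meta <- metadata[metadata$patient_id == pid, , drop = FALSE]
    omr_dates <- meta$date[meta$source == "expert_metadata"]
    pdf_dates <- meta$date[meta$source == "pdf_creation"]
    if (length(c(omr_dates[!is.na(omr_dates)], pdf_dates[!is.na(pdf_dates)])) == 0) {
      n_unresolvable <- n_unresolvable + 1L
      next
    }
    reference <- resolve_reference_date(omr_dates, pdf_dates)
    notes <- dplyr::distinct(tibble::tibble(
      document_id = cn$document_id[cn$patient_id == pid],
      date = cn$note_date[cn$patient_id == pid]))
    initial <- resolve_initial_encounter(notes$date, reference)
    if (is.na(initial)) {
      n_unresolvable <- n_unresolvable + 1L
      next
    }
    notes <- assign_note_corpus(notes, initial, window)
    assignments[[i]] <- tibble::tibble(
      patient_id = pid, reference_date = reference,
      initial_encounter_date = initial,
      n_icn = sum(notes$corpus == "ICN"),
      n_fcn = sum(notes$corpus == "FCN"),
      n_unassigned = sum(notes$corpus == "unassigned"))
    doc_corpus[[i]] <- tibble::tibble(
      patient_id = pid, document_id = notes$document_id,
      corpus = notes$corpus)
  }

  assignments <- dplyr::bind_rows(assignments)
  doc_corpus <- dplyr::bind_rows(doc_corpus)

  if (nrow(cn) > 0 && nrow(doc_corpus) > 0) {
    cn <- dplyr::left_join(cn, doc_corpus,
                           by = c("patient_id", "document_id"))
    cn$corpus[is.na(cn$corpus)] <- "dropped" # unresolvable patients
  } else if (nrow(cn) > 0) {
    cn$corpus <- "dropped"
  }

  n_unassigned_notes <- if (nrow(doc_corpus) > 0)
    sum(doc_corpus$corpus == "unassigned") else 0L
  kept <- cn[cn$corpus %in% c("ICN", "FCN"), , drop = FALSE]
  kept$corpus_tag <- kept$corpus
  kept$corpus <- NULL

  list(
    records = dplyr::bind_rows(other, kept),
    assignments = assignments,
    dropped = list(
      unresolvable_patients = n_unresolvable,
      unassigned_notes = n_unassigned_notes,
      dropped_cn_records = sum(cn$corpus %in% c("unassigned", "dropped"))))
}
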