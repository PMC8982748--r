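#' Load a run configuration
#'
#' YAML key-value file; recognised keys are the arguments of
#' [run_pipeline()] (`annotations`, `metadata`, `terminology`,
#' `background`, `threshold`, `window`, `top_k`, `output_dir`). Relative
#' input paths are resolved against the config file's directory. Values in
#' `overrides` win over the file.
#'
#' @param path YAML file.
#' @param overrides Named list of values overriding the file's.
#' @return Named list of configuration values.
#' @export
load_run_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  cfg[names(overrides)] <- overrides
  base <- dirname(normalizePath(path))
  for (key in c("annotations", "metadata", "terminology", "background")) {
    if (!is.null(cfg[[key]]) && !grepl("^(/|[A-Za-z]:)", cfg[[key]])) {
      cfg[[key]] <- file.path(base, cfg[[key]])
    }
  }
  cfg
}

#' Run the full overlap-and-saliency pipeline
#'
#' Executes the stages in order: read annotations → keep patient-experienced
#' mentions → resolve reference/initial dates and split consultant notes
#' into ICN and FCN → build the unique concept sets → partition into the
#' seven regions → exact (and, with a terminology, flexible) intersection
#' ratios → semantic-group and note-section tables → (with a background
#' profile) the saliency report. Each stage failure aborts with the stage
#' name.
#'
#' @param annotations Path to the annotation file, or an annotation tibble.
#' @param metadata Path to the date-metadata sidecar, or its tibble.
#' @param terminology Optional path to a terminology file or a
#'   [terminology_graph()]; enables flexible matching.
#' @param background Optional path to a frequency-profile file or a
#'   [frequency_profile()]; enables the saliency report.
#' @param threshold Flexible-match similarity threshold in \[0, 1).
#' @param window Follow-up window in days (>= 1, default 90).
#' @param top_k Salient concepts listed per region.
#' @return A `pipeline_summary` list: concept sets, `partition`, `summary`
#'   (region counts and shares), `ratios` (r_e / r_s per corpus pair),
#'   `semtype_table`, `match_table`, `section_table`, `saliency` (or
#'   `NULL`), and `log` (dropped record/patient counts).
#' @export
run_pipeline <- function(annotations, metadata, terminology = NULL,
                         background = NULL, threshold = 0, window = 90,
                         top_k = 5) {
  stopifnot(window >= 1, threshold >= 0, threshold < 1)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  records <- stage("read_annotations", {
    if (is.character(annotations)) read_annotations(annotations)
    else validate_annotations(annotations)
  })
  meta <- stage("read_metadata", {
    if (is.character(metadata)) read_metadata(metadata) else metadata
  })
  tg <- stage("read_terminology", {
    if (is.character(terminology)) read_terminology(terminology)
    else terminology
  })
  profile <- stage("read_background", {
    if (is.character(background)) read_frequency_profile(background)
    else background
  })

  n_raw <- nrow(records)
  records <- stage("filter_experiencer", filter_patient_experiencer(records))
  n_others <- n_raw - nrow(records)

  assigned <- stage("assign_corpora", assign_corpora(records, meta, window))
  rec <- assigned$records

  sets <- stage("build_concept_sets", list(
    omr = build_concept_set(rec[rec$corpus_tag == "OMR", ], "C_OMR"),
    icn = build_concept_set(rec[rec$corpus_tag == "ICN", ], "C_ICN"),
    fcn = build_concept_set(rec[rec$corpus_tag == "FCN", ], "C_FCN")))
  sets$cn <- concept_set_union(sets$icn, sets$fcn, "C_CN")

  partition <- stage("partition_regions",
                     partition_regions(sets$omr, sets$icn, sets$fcn))
  summary <- region_summary(partition)

  ratios <- stage("intersection_ratios", {
    # an empty CN-side corpus leaves its ratio undefined (reported NA)
    # rather than aborting the run
    r_e <- function(cn) if (nrow(cn) == 0) NA_real_
      else exact_intersection_ratio(sets$omr, cn)
    out <- list(r_e_icn = r_e(sets$icn), r_e_fcn = r_e(sets$fcn),
                r_e_cn = r_e(sets$cn))
    if (!is.null(tg)) {
      r_s <- function(cn) {
        if (nrow(cn) == 0) return(list(ratio = NA_real_, match = NULL))
        m <- best_flexible_match(sets$omr, cn, tg, threshold)
        list(ratio = flexible_intersection_ratio(m, cn), match = m)
      }
      s_icn <- r_s(sets$icn); s_fcn <- r_s(sets$fcn); s_cn <- r_s(sets$cn)
      out$r_s_icn <- s_icn$ratio
      out$r_s_fcn <- s_fcn$ratio
      out$r_s_cn <- s_cn$ratio
      out$match_cn <- s_cn$match
    }
    out
  })

  semtype_table <- stage("semtype_coverage", semtype_coverage_table(partition))
  match_table <- stage("match_coverage",
                       match_coverage_table(sets$omr, sets$icn, sets$fcn,
                                            tg, threshold))
  overlap_keys <- unlist(partition$regions[c("A", "B", "C")],
                         use.names = FALSE)
  section_table <- stage("section_distribution", {
    cn_records <- rec[rec$corpus_tag %in% c("ICN", "FCN"), ]
    list(
      cn_union = section_distribution(cn_records, sets$cn),
      overlap = section_distribution(
        cn_records, concept_set_from_keys(overlap_keys, "overlap")))
  })

  saliency <- if (!is.null(profile)) {
    stage("saliency", saliency_table(profile, partition, top_k))
  } else NULL

  structure(list(
    sets = sets, partition = partition, summary = summary, ratios = ratios,
    semtype_table = semtype_table, match_table = match_table,
    section_table = section_table, saliency = saliency,
    threshold = threshold, window = window,
    log = c(list(records_read = n_raw, others_filtered = n_others),
            assigned$dropped)),
    class = "pipeline_summary")
}

fmt_pct <- function(x) ifelse(is.na(x), "-", sprintf("%.2f%%", x))

#' Render a human-readable run report
#'
#' Fixed-order sections: corpus sizes, region Venn counts, intersection
#' ratios, the semantic-group coverage table, the note-section
#' distribution, and (when computed) the saliency table. Percentages at 2
#' decimals, saliency averages at 3. Identical inputs render byte-identical
#' reports.
#'
#' @param x A [run_pipeline()] summary.
#' @return Character vector of report lines.
#' @export
render_report <- function(x) {
  s <- x$summary
  lines <- c(
    "== Corpus sizes ==",
    sprintf("  C_OMR %d | C_ICN %d | C_FCN %d | union %d",
            s$n_omr, s$n_icn, s$n_fcn, s$n_union),
    sprintf("  OMR/CN overlap (A+B+C): %d (%s of union, %s of C_OMR, %s of C_ICN u C_FCN)",
            s$n_overlap, fmt_pct(s$pct_overlap_of_union),
            fmt_pct(s$pct_overlap_of_omr), fmt_pct(s$pct_overlap_of_cn_union)),
    "",
    "== Region counts ==",
    vapply(region_labels(), function(r) {
      n <- s$n_regions[[r]]
      extra <- if (r %in% c("A", "B", "C"))
        paste0(" (", fmt_pct(s$pct_region_of_overlap[[r]]), " of overlap)")
      else ""
      sprintf("  Region %s: %d%s", r, n, extra)
    }, character(1), USE.NAMES = FALSE),
    "",
    "== Intersection ratios ==",
    sprintf("  exact    r_e: ICN %s | FCN %s | CN %s",
            fmt_pct(pct(x$ratios$r_e_icn, 1)), fmt_pct(pct(x$ratios$r_e_fcn, 1)),
            fmt_pct(pct(x$ratios$r_e_cn, 1))))
  if (!is.null(x$ratios$r_s_cn)) {
    lines <- c(lines, sprintf(
      "  flexible r_s: ICN %s | FCN %s | CN %s  (similarity > %g)",
      fmt_pct(pct(x$ratios$r_s_icn, 1)), fmt_pct(pct(x$ratios$r_s_fcn, 1)),
      fmt_pct(pct(x$ratios$r_s_cn, 1)), x$threshold))
  }
  lines <- c(lines, "", "== Semantic-group coverage of the overlap ==")
  tab <- x$semtype_table
  lines <- c(lines, sprintf(
    "  %-10s A %6d (%s)  B %6d (%s)  C %6d (%s)  total %6d",
    tab$semantic_group, tab$freq_A, fmt_pct(tab$pct_A), tab$freq_B,
    fmt_pct(tab$pct_B), tab$freq_C, fmt_pct(tab$pct_C), tab$total))
  lines <- c(lines, "", "== Note sections (overlap concepts, CN incidences) ==")
  sec <- x$section_table$overlap
  if (nrow(sec) == 0) {
    lines <- c(lines, "  (none)")
  } else {
    lines <- c(lines, sprintf("  %-40s %6d (%s)", sec$section, sec$n,
                              fmt_pct(pct(sec$n, sum(sec$n)))))
  }
  if (!is.null(x$saliency)) {
    lines <- c(lines, "", "== Saliency by region ==")
    st <- x$saliency$table
    lines <- c(lines, sprintf(
      "  Region %s: mapped %6d / %6d (%s)  sum %9.2f  avg %.3f%s",
      st$region, st$n_mapped, st$n_original, fmt_pct(st$coverage_pct),
      st$sum_score, st$average,
      ifelse(st$all_zero, " [no positive scores]", "")))
    for (r in region_labels()) {
      top <- x$saliency$top[[r]]
      if (nrow(top) == 0) next
      lines <- c(lines, sprintf("  top %s: %s", r,
                                paste(sprintf("%s (%.3f)", top$concept,
                                              top$score), collapse = ", ")))
    }
  }
  lines <- c(lines, "", "== Dropped ==",
             sprintf("  %s: %d", names(x$log), unlist(x$log)))
  lines
}

#' @export
print.pipeline_summary <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' Write the machine-readable outputs of a run
#'
#' Emits under `dir`: `report.txt` (the rendered report), `regions.tsv`,
#' `semtype_coverage.tsv`, `match_coverage.tsv`, `sections.tsv`,
#' `saliency.tsv` (when computed) and `summary.json` (region cardinalities,
#' ratios and log counts).
#'
#' @param x A [run_pipeline()] summary.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_run_outputs <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(report = file.path(dir, "report.txt"),
             regions = file.path(dir, "regions.tsv"),
             semtype = file.path(dir, "semtype_coverage.tsv"),
             match = file.path(dir, "match_coverage.tsv"),
             sections = file.path(dir, "sections.tsv"),
             summary = file.path(dir, "summary.json"))
  readr::write_lines(render_report(x), paths[["report"]])
  readr::write_tsv(tibble::tibble(
    region = region_labels(),
    n = unname(x$summary$n_regions[region_labels()])), paths[["regions"]],
    progress = FALSE)
  readr::write_tsv(x$semtype_table, paths[["semtype"]], progress = FALSE)
  readr::write_tsv(x$match_table, paths[["match"]], progress = FALSE)
  readr::write_tsv(x$section_table$overlap, paths[["sections"]],
                   progress = FALSE)
  if (!is.null(x$saliency)) {
    paths[["saliency"]] <- file.path(dir, "saliency.tsv")
    readr::write_tsv(x$saliency$table, paths[["saliency"]], progress = FALSE)
  }
  ratios <- x$ratios
  ratios$match_cn <- NULL
  jsonlite::write_json(
    list(n_regions = as.list(x$summary$n_regions),
         n_sets = list(omr = x$summary$n_omr, icn = x$summary$n_icn,
                       fcn = x$summary$n_fcn, union = x$summary$n_union),
         ratios = ratios, log = x$log),
    paths[["summary"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
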