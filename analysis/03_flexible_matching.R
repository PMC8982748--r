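#!/usr/bin/env Rscript

# Stage 3: flexible (terminology-path) matching demonstration.
#
# Pairwise path-measure matching over all OMR x CN terms is quadratic, so
# this stage runs on a reduced cohort (scaled region cardinalities, full
# term coverage, 20% of OMR-only concepts planted one is-a step away from
# a consultant-note concept) and sweeps the similarity threshold to show
# how the flexible ratio r_s collapses onto the exact ratio r_e once the
# threshold passes the planted pairs' similarity of 1/2.

suppressPackageStartupMessages(library(omroverlap))
library(tibble)

dir.create("results", showWarnings = FALSE)
study_dir <- "scratch/near-match-study"

spec <- synthetic_spec(
  seed = 20160301, n_patients = 40,
  region_cardinalities = c(A = 48, B = 144, C = 67, D = 60, E = 349,
                           F = 237, G = 1410),
  n_terminology_concepts = 400, near_match_fraction = 0.2,
  map_exact_terms = TRUE)
generate_corpora(spec, study_dir)

sweep <- lapply(c(0, 0.2, 0.4, 0.6, 0.8, 0.99), function(thr) {
  res <- run_pipeline(file.path(study_dir, "annotations.tsv"),
                      file.path(study_dir, "metadata.tsv"),
                      file.path(study_dir, "terminology.tsv"),
                      threshold = thr)
  tibble(threshold = thr,
         r_e_cn_pct = pct(res$ratios$r_e_cn, 1),
         r_s_cn_pct = pct(res$ratios$r_s_cn, 1),
         flexible_gain_pct = pct(res$ratios$r_s_cn - res$ratios$r_e_cn, 1))
})
sweep <- dplyr::bind_rows(sweep)
readr::write_tsv(sweep, "results/03_threshold_sweep.tsv")

cat("Threshold sweep on the near-match cohort (ratios vs C_CN):\n")
print(as.data.frame(sweep), row.names = FALSE)
cat("\nThe planted near matches sit at similarity 1/2: the flexible gain",
    "vanishes once the threshold crosses 0.5, and r_s >= r_e throughout.\n")
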