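#!/usr/bin/env Rscript

# Stage 4: specialty saliency of the reference study's regions.
#
# Scores every regional concept against the synthetic background corpus
# (specialty mention frequency over all-practice mention frequency),
# aggregates per region — coverage to the original region, score sum,
# average over positive-score concepts — and lists the top salient
# concepts. Planted specialty-exclusive concepts (region E) must surface
# at score 1.0.

suppressPackageStartupMessages(library(omroverlap))

study_dir <- "scratch/reference-study"
if (!file.exists(file.path(study_dir, "annotations.tsv"))) {
  stop("run analysis/01_generate_corpora.R first")
}
dir.create("results", showWarnings = FALSE)

res <- run_pipeline(file.path(study_dir, "annotations.tsv"),
                    file.path(study_dir, "metadata.tsv"),
                    background = file.path(study_dir, "background.tsv"))

st <- res$saliency$table
readr::write_tsv(st, "results/04_saliency_by_region.tsv")
top_all <- dplyr::bind_rows(lapply(names(res$saliency$top), function(r) {
  t <- res$saliency$top[[r]]
  if (nrow(t) == 0) return(NULL)
  cbind(region = r, t)
}))
readr::write_tsv(top_all, "results/04_top_salient_concepts.tsv")

cat("Saliency by region (average over positive-score concepts):\n")
print(as.data.frame(st[, c("region", "n_original", "n_mapped",
                           "coverage_pct", "sum_score", "average")]),
      row.names = FALSE)
cat("\nTop salient concepts in region E (ICN-only):\n")
print(as.data.frame(res$saliency$top$E), row.names = FALSE)
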