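#!/usr/bin/env Rscript
# Compare a small ensemble of models by element presence/absence: pairwise
# Hamming distances with directed decomposition, per-model average
# distances, heterogeneity degrees, and core/unique statistics.

suppressMessages(library(gutflux))
out <- "results"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

models <- list(make_toy_gem("chain"), make_toy_gem("diamond"),
               make_toy_gem("futile_cycle"), make_toy_gem("epithelium"))
sets <- lapply(models, element_sets)
report <- compare_ensemble(sets)

for (cl in names(report)) {
  r <- report[[cl]]
  write.table(r$distances$pairs,
              file.path(out, sprintf("ensemble_%s_distances.tsv", cl)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: union %d, core %d (%.1f%%), unique %d; heterogeneity %.3f\n",
              cl, r$core$union_count, r$core$core_count,
              r$core$core_percentage, r$core$unique_count,
              r$heterogeneity$heterogeneity_degree))
}
jsonlite::write_json(
  lapply(report, function(r) list(core = r$core,
                                  heterogeneity = r$heterogeneity)),
  file.path(out, "ensemble_report.json"), auto_unbox = TRUE, pretty = TRUE)
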