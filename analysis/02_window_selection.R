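#!/usr/bin/env Rscript
# Data-driven window-length selection: Q* variability across candidate
# window lengths relative to the half-scan reference, selection of the
# smallest reliable odd window, the module-count-versus-length curve, and
# the log-log extrapolation of the instantaneous 2-module proportion.
# Reads results/data/switching (from 01_simulate_cohort.R); writes
# results/window_selection/.

suppressPackageStartupMessages(library(dynmod))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1

manifest <- read_manifest("results/data/switching/manifest.tsv")
cohort <- lapply(seq_len(nrow(manifest)), function(i) {
  read_timeseries(manifest$path[i], subject_id = manifest$subject_id[i])
})
dir.create("results/window_selection", showWarnings = FALSE, recursive = TRUE)

lengths <- seq(9, 49, by = 2)
cat(sprintf("Q* variance curve over %d odd lengths (plus the 50-volume reference) ...\n",
            length(lengths)))
curve <- qstar_variance_curve(cohort, lengths, seed = seed)
write.table(curve, "results/window_selection/qstar_variance_curve.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

L <- select_window(curve, cutoff_pct = 10)
tr_s <- cohort[[1]]$tr_seconds
cat(sprintf("selected window: %d volumes (%g s at TR %g s)\n", L, L * tr_s, tr_s))

cat("module-count curve ...\n")
mc <- module_count_curve(cohort, lengths[lengths >= 11], seed = seed + 1)
write.table(mc, "results/window_selection/module_count_curve.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
p11 <- mc[mc$length == 11 & mc$proportion > 0, ]
cat("  at 11 volumes:",
    paste(sprintf("%s modules %.1f%%", p11$n_modules, 100 * p11$proportion),
          collapse = ", "), "\n")

intercept <- tryCatch(
  powerlaw_intercept(mc, seq(11, 49, by = 2)),
  error = function(e) {
    cat("  power-law fit not possible:", conditionMessage(e), "\n")
    NA_real_
  }
)
if (!is.na(intercept)) {
  cat(sprintf("  extrapolated instantaneous 2-module proportion: %.1f%%\n",
              intercept))
}

jsonlite::write_json(
  list(selected_window_volumes = L,
       selected_window_seconds = L * tr_s,
       cutoff_pct = 10,
       reference_length = attr(curve, "reference_length"),
       instantaneous_2module_pct = intercept),
  "results/window_selection/selection.json",
  auto_unbox = TRUE, digits = NA, pretty = TRUE
)
cat("written to results/window_selection/\n")
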