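#!/usr/bin/env Rscript
# Stage 2: the six-test statistical battery on each reconstructed delay
# table: RT1/RT2 ranges, Step Number and ISI effects with the averaged
# GG/HF sphericity correction, per-ISI post-hoc tests, and the RT2
# regressions over interfered ISIs.
#
# Reads:  results/delay_table_<condition>.csv   (from 02_reconstruct.R)
# Writes: results/stage2_<condition>.json, results/posthoc_<condition>.csv

suppressPackageStartupMessages(library(refractory))

files <- list.files("results", pattern = "^delay_table_.*\\.csv$",
                    full.names = TRUE)
if (!length(files)) stop("run analysis/02_reconstruct.R first")

for (f in files) {
  nm <- sub("^delay_table_(.*)\\.csv$", "\\1", basename(f))
  tab <- read.csv(f)
  if (length(unique(tab$participant)) < 3) {
    message(nm, ": fewer than 3 participants, skipping group statistics")
    next
  }
  s2 <- stage2_report(tab)
  print(s2)
  write.csv(s2$posthoc$table, sprintf("results/posthoc_%s.csv", nm),
            row.names = FALSE)
  out <- list(
    mean_rt1 = s2$mean_rt1,
    range_rt1 = mean(s2$ranges$range_rt1),
    range_rt2 = mean(s2$ranges$range_rt2),
    anova = s2$anova,
    metric_anova = s2$posthoc$metric_anova,
    metric_interp = s2$posthoc$metric_interp,
    interfered_isis = s2$interfered_isis,
    slope = s2$regression$slope,
    max_increase = s2$regression$max_increase,
    duration_constrained = s2$regression_constrained$duration,
    no_refractoriness = as.list(s2$no_refractoriness))
  jsonlite::write_json(out, sprintf("results/stage2_%s.json", nm),
                       auto_unbox = TRUE, digits = NA, na = "null")
  message(nm, ": stage-2 report written")
}
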