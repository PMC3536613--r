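#!/usr/bin/env Rscript
# Stage 1: set-point reconstruction of every simulated trial written by
# 01_simulate.R. For each condition, the per-trial target->joystick relation
# is fitted by the zero-delay ARX model and the per-step instants optimized;
# the resulting RT1/RT2 delay table is the input to the statistics stage.
#
# Writes: results/delay_table_<condition>.csv

suppressPackageStartupMessages(library(refractory))

in_root <- "scratch/trials"
if (!dir.exists(in_root))
  stop("run analysis/01_simulate.R first (no ", in_root, ")")

for (nm in list.dirs(in_root, recursive = FALSE, full.names = FALSE)) {
  tabs <- list()
  for (pd in list.dirs(file.path(in_root, nm), recursive = FALSE)) {
    p <- as.integer(sub(".*_", "", basename(pd)))
    files <- list.files(pd, pattern = "^trial_\\d+\\.csv$", full.names = TRUE)
    trials <- lapply(files, read_trial)
    tabs[[length(tabs) + 1]] <-
      suppressWarnings(reconstruct_session(trials, participant = p))
  }
  tab <- extract_rt_pairs(do.call(rbind, tabs))
  dir.create("results", showWarnings = FALSE)
  out <- sprintf("results/delay_table_%s.csv", nm)
  write.csv(tab, out, row.names = FALSE)
  message(sprintf("%s: %d pairs, mean RT1 %.0f ms, mean RT2 %.0f ms -> %s",
                  nm, nrow(tab), 1000 * mean(tab$rt1), 1000 * mean(tab$rt2),
                  out))
}
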