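#!/usr/bin/env Rscript
# Simulate the virtual participants whose recordings the later stages
# analyse: a noise-free externally triggered intermittent controller, an
# internally saturated variant, and a continuous controller, all tracking
# randomized double-step sessions on the zero-order system.
#
# Writes the bulky raw recordings under scratch/trials/ (one CSV per trial,
# ~4000 rows each); the tables the later stages produce go under results/.

suppressPackageStartupMessages(library(refractory))

out_root <- "scratch/trials"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

conditions <- list(
  external_noisefree = list(
    controller = "intermittent", participants = 1,
    params = ic_params(delta_ol = 0.35, feedback_delay = 0.14,
                       trigger_mode = "external")),
  internal_saturated = list(
    controller = "intermittent", participants = 2,
    params = ic_params(delta_ol = 0.35, feedback_delay = 0.14,
                       threshold = 0, trigger_mode = "internal",
                       noise_sd = 0.01)),
  continuous = list(
    controller = "continuous", participants = 3,
    params = ic_params(feedback_delay = 0.14, noise_sd = 0.02,
                       delay_jitter_sd = 0.02))
)

for (nm in names(conditions)) {
  cond <- conditions[[nm]]
  message("condition: ", nm)
  spec <- system_spec(0)
  set.seed(2024)
  seeds <- sample.int(1e6, 2 * cond$participants)
  dir.create(file.path(out_root, nm), showWarnings = FALSE)
  for (p in seq_len(cond$participants)) {
    set.seed(seeds[p])
    ses <- build_session(0, repetitions = 1,
                         patterns = c("rev_LR", "rev_RL"))
    if (p == 1)
      write.csv(session_table(ses),
                file.path(out_root, nm, "session_participant1.csv"),
                row.names = FALSE)
    trials <- run_virtual_participant(spec, ses, cond$controller,
                                      cond$params,
                                      seed = seeds[cond$participants + p])
    pd <- file.path(out_root, nm, sprintf("participant_%02d", p))
    dir.create(pd, showWarnings = FALSE)
    for (i in seq_along(trials))
      write_trial(trials[[i]], file.path(pd, sprintf("trial_%03d.csv", i)))
    message(sprintf("  participant %d: %d trials, %d control events total",
                    p, length(trials),
                    sum(lengths(lapply(trials, `[[`, "event_times")))))
  }
}
message("done; trial recordings under ", out_root)
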