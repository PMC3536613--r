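## Canonical virtual-experiment runs on the zero-order system: the
## deterministic externally triggered condition and the stochastic
## internally saturated condition, each pushed through the full
## simulate -> reconstruct -> regress chain.

#' Noise-free externally triggered double-step experiment
#'
#' One virtual participant tracks reversed double steps over the zero-order
#' ISI grid under externally triggered intermittent control with no noise.
#' Per-step delays are reconstructed and summarized: under one event per
#' step stimulus, RT2 = max(0, delta_ol - ISI) + t_d, so the mean-RT2
#' regression over interfered ISIs has slope -1 and the slope-constrained
#' line crosses the RT1 baseline at the configured open-loop interval.
#'
#' @param seed integer seed (trial order and recovery periods).
#' @param delta_ol minimum open-loop interval (s), default 0.35.
#' @param t_d feedback delay (s), default 0.14.
#' @param repetitions repetitions per ISI x pattern (default 1; the run is
#'   noise-free, so repetitions only average reconstruction quantization).
#' @param interfered_margin mean RT2 must exceed mean RT1 by this margin (s)
#'   for an ISI to count as interfered (default 0.01, half an
#'   identification step) — the deterministic single-participant analogue
#'   of the significance-based rule in [posthoc_by_isi()].
#' @return List: `delay_table`, `mean_rt1`, `mean_rt2_by_isi`,
#'   `interfered_isis`, `regression` (unconstrained fit over interfered
#'   ISIs), `regression_constrained` (slope -1), `duration_constrained`,
#'   `triggering_class`.
#' @export
external_timing_run <- function(seed = 1, delta_ol = 0.35, t_d = 0.14,
                                repetitions = 1, interfered_margin = 0.01) {
  spec <- system_spec(0)
  params <- ic_params(delta_ol = delta_ol, feedback_delay = t_d,
                      trigger_mode = "external")
  set.seed(seed)
  session <- build_session(0, repetitions = repetitions,
                           patterns = c("rev_LR", "rev_RL"))
  trials <- run_virtual_participant(spec, session, "intermittent", params,
                                    seed = seed)
  tab <- suppressWarnings(reconstruct_session(trials))
  mean_rt1 <- mean(tab$rt1)
  m2 <- stats::aggregate(rt2 ~ isi, data = tab, FUN = mean)
  interfered <- m2$isi[m2$rt2 > mean_rt1 + interfered_margin]
  m2i <- m2[m2$isi %in% interfered, ]
  reg <- fit_rt2_regression(m2i$isi, m2i$rt2, mean_rt1)
  regc <- fit_rt2_regression(m2i$isi, m2i$rt2, mean_rt1, constrain_slope = -1)
  list(delay_table = tab, mean_rt1 = mean_rt1, mean_rt2_by_isi = m2,
       interfered_isis = interfered, regression = reg,
       regression_constrained = regc,
       duration_constrained = regc$duration,
       triggering_class = classify_triggering(reg$slope, reg$slope_se,
                                              reg$df))
}

#' Internally saturated double-step experiment
#'
#' The zero-threshold internal-triggering condition: observation noise keeps
#' the error signal nonzero, so events fire at the maximum rate permitted by
#' the minimum open-loop interval, with the event-train phase randomized
#' relative to the steps by drawing the first-step time uniformly over one
#' open-loop interval. RT2 is reconstructed for trials in which the second
#' step received its own control event (an event fell between the two
#' steps); with uniform phase this gives E[RT2 | ISI] =
#' `delta_ol - ISI/2 + t_d`, a slope of -0.5 over ISIs below the open-loop
#' interval.
#'
#' @param seed integer seed.
#' @param repetitions stochastic repetitions per ISI (default 200).
#' @param delta_ol,t_d as in [external_timing_run()].
#' @param noise_sd observation noise keeping the trigger saturated
#'   (default 0.01 screen units).
#' @return List: `table` (per ISI: repetitions, distinct count, mean RT2),
#'   `slope` of mean RT2 on ISI, `slope_se`, and the fitted regression.
#' @export
internal_saturation_run <- function(seed = 1, repetitions = 200,
                                    delta_ol = 0.35, t_d = 0.14,
                                    noise_sd = 0.01) {
  spec <- system_spec(0)
  dp <- discretize_plant(make_plant(spec), 0.001)
  params <- ic_params(delta_ol = delta_ol, feedback_delay = t_d,
                      threshold = 0, trigger_mode = "internal",
                      noise_sd = noise_sd)
  isis <- isi_grid(0)
  isis <- isis[isis < delta_ol]
  set.seed(seed)
  rows <- lapply(isis, function(isi) {
    rt2 <- numeric(0)
    for (r in seq_len(repetitions)) {
      fst <- stats::runif(1, 1, 1 + delta_ol)   # uniform event-train phase
      sq <- make_step_sequence(if (r %% 2 == 0) "rev_LR" else "rev_RL",
                               first_step_time = fst, isi = isi,
                               arp = sample_arp(0))
      w <- render_target(sq, duration = max(sq$step_times) + 1)
      tr <- simulate_intermittent(dp, w, params,
                                  meta = list(sequence = sq, spec = spec))
      if (classify_double_response(tr, sq) == "distinct") {
        rec <- suppressWarnings(reconstruct_trial(tr, seq = sq))
        rt2 <- c(rt2, rec$rt[2])
      }
    }
    data.frame(isi = isi, repetitions = repetitions,
               n_distinct = length(rt2), mean_rt2 = mean(rt2))
  })
  tab <- do.call(rbind, rows)
  reg <- fit_rt2_regression(tab$isi, tab$mean_rt2, mean_rt1 = t_d)
  list(table = tab, slope = reg$slope, slope_se = reg$slope_se,
       regression = reg)
}

#' Cohort run: several virtual participants through the full analysis
#'
#' Simulates `n_participants` independent participants (each with their own
#' randomized session, noise and latency jitter), reconstructs all trials
#' and returns the pooled delay table — the input to [stage2_report()].
#'
#' @param controller `"intermittent"` or `"continuous"`.
#' @param params an [ic_params()]; cohort realism typically uses
#'   `noise_sd = 0.02` and `delay_jitter_sd = 0.02`.
#' @param n_participants number of virtual participants (default 6).
#' @param order system order (default 0).
#' @param repetitions repetitions per ISI x pattern (default 1).
#' @param patterns session patterns (default both reversed).
#' @param seed integer seed.
#' @return Delay table (data frame) across participants.
#' @export
cohort_run <- function(controller = c("continuous", "intermittent"),
                       params = ic_params(noise_sd = 0.02,
                                          delay_jitter_sd = 0.02),
                       n_participants = 6, order = 0, repetitions = 1,
                       patterns = c("rev_LR", "rev_RL"), seed = 1) {
  controller <- match.arg(controller)
  spec <- system_spec(order)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 2 * n_participants)
  tabs <- lapply(seq_len(n_participants), function(p) {
    set.seed(seeds[p])
    ses <- build_session(order, repetitions = repetitions,
                         patterns = patterns)
    trs <- run_virtual_participant(spec, ses, controller, params,
                                   seed = seeds[n_participants + p])
    suppressWarnings(reconstruct_session(trs, participant = p))
  })
  extract_rt_pairs(do.call(rbind, tabs))
}
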