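test_that("boxcar decimation and analytic step rendering are one operator", {
  sq <- make_step_sequence("uni_LLc", isi = 0.237, arp = 1.4)
  w <- render_target(sq, dt = 0.001, duration = 4)
  wd1 <- decimate_boxcar(w, dt = 0.001, dt_id = 0.02)
  wd2 <- render_steps_dec(sq$step_times, sq$step_levels, length(wd1), 0.02)
  # identical away from the sub-sample quantization of the 1 kHz rendering
  expect_lt(max(abs(wd1 - wd2)), 0.05 + 1e-12)   # <= one 1 ms sliver of 2A
  expect_lt(mean(abs(wd1 - wd2)), 1e-3)
})

test_that("an identity response recovers the identity ARX map", {
  set.seed(2)
  sq <- make_step_sequence("rev_RL", isi = 0.3, arp = 1.2)
  w <- render_steps_dec(sq$step_times, sq$step_levels, 150, 0.02)
  f <- fit_arx(w, w, order = 10)
  expect_equal(unname(f$b[1]), 1, tolerance = 1e-8)
  expect_lt(max(abs(f$a)), 1e-8)
  expect_lt(f$rss, 1e-20)
})

test_that("a response generated by the model family is recovered exactly", {
  set.seed(3)
  # rich multi-step target so the regression is well conditioned
  n_out <- 400
  w <- cumsum(rbinom(n_out, 1, 0.05) * sample(c(-1, 1), n_out, TRUE))
  a_true <- c(0.6, -0.2, 0.05, rep(0, 7))   # stable AR part
  b0 <- 0.8
  u <- as.numeric(stats::filter(b0 * w, filter = a_true[1:3],
                                method = "recursive"))
  f <- fit_arx(w, u, order = 10)
  expect_lt(f$rss, 1e-12)
  expect_equal(unname(f$a), a_true, tolerance = 1e-6)
  expect_equal(unname(f$b[1]), b0, tolerance = 1e-6)
})

test_that("the residual is non-increasing in model order on fixed data", {
  set.seed(4)
  n_out <- 300
  w <- cumsum(rbinom(n_out, 1, 0.05))
  u <- as.numeric(stats::filter(w, filter = c(0.9, -0.3),
                                method = "recursive")) + rnorm(n_out, 0, 0.05)
  rss <- vapply(1:11, function(k) {
    # nested regressions evaluated on the common sample span
    sum(.lm.fit(cbind(stats::embed(u, 12)[, 2:(k + 1), drop = FALSE],
                      stats::embed(w, 12)[, 1, drop = FALSE]),
                stats::embed(u, 12)[, 1])$residuals^2)
  }, numeric(1))
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("the AIC order check flags an overfit production order", {
  set.seed(5)
  n_out <- 250
  w <- cumsum(rbinom(n_out, 1, 0.06))
  u <- as.numeric(stats::filter(w, filter = 0.7, method = "recursive")) +
    rnorm(n_out, 0.0, 0.2)
  tab <- suppressWarnings(check_arx_order(w, u, chosen = 10))
  expect_equal(nrow(tab), 12)
  expect_true(attr(tab, "opt_order") %in% 1:12)
})

test_that("the common delay of a shifted LTI response is recovered", {
  sq <- make_step_sequence("rev_RL", isi = 0.4, arp = 1.5)
  n_out <- 200
  for (shift in c(0, 0.18)) {
    w_shift <- render_steps_dec(sq$step_times + shift, sq$step_levels,
                                n_out, 0.02)
    u <- as.numeric(stats::filter(0.5 * w_shift, filter = c(0.8, -0.3),
                                  method = "recursive"))
    est <- estimate_common_delay(sq, u)
    expect_equal(est$delta, shift, tolerance = 2e-3)
  }
})

test_that("coarse and refined common-delay searches agree to one coarse step", {
  sq <- make_step_sequence("rev_RL", isi = 0.4, arp = 1.5)
  w_shift <- render_steps_dec(sq$step_times + 0.171, sq$step_levels, 200, 0.02)
  u <- as.numeric(stats::filter(0.5 * w_shift, filter = c(0.8, -0.3),
                                method = "recursive"))
  coarse <- estimate_common_delay(sq, u, refine = FALSE)
  fine <- estimate_common_delay(sq, u, refine = TRUE)
  expect_lt(abs(coarse$delta - fine$delta), 0.02 + 1e-12)
  expect_equal(fine$delta, 0.171, tolerance = 2e-3)
})

test_that("injected per-step delays are recovered and match the joint search", {
  sq <- make_step_sequence("rev_RL", isi = 0.25, arp = 1.5)
  n_out <- 180
  injected <- c(0.15, 0.40)
  w_shift <- render_steps_dec(sq$step_times + injected, sq$step_levels,
                              n_out, 0.02)
  u <- as.numeric(stats::filter(0.6 * w_shift, filter = 0.5,
                                method = "recursive"))
  com <- estimate_common_delay(sq, u)
  ps <- reconstruct_step_delays(sq, u, init = com$delta)
  expect_equal(ps$delays, injected, tolerance = 0.02)

  # oracle equivalence on a shared small grid: sequential coordinate descent
  # reaches the exhaustive joint 2-D minimum
  grid <- seq(0, 0.6, by = 0.05)
  oracle <- oracle_joint_2d(sq, u, grid)
  seq_res <- reconstruct_step_delays(sq, u, init = 0, grid = grid,
                                     refine = FALSE, max_passes = 6,
                                     tol = 1e-15)
  expect_lt(abs(seq_res$rss - oracle$rss), 1e-9)
  expect_equal(seq_res$delays, oracle$delays)
})

test_that("equal injected delays reduce to the common-delay solution", {
  sq <- make_step_sequence("rev_RL", isi = 0.3, arp = 1.5)
  w_shift <- render_steps_dec(sq$step_times + 0.2, sq$step_levels, 180, 0.02)
  u <- as.numeric(stats::filter(0.6 * w_shift, filter = 0.5,
                                method = "recursive"))
  com <- estimate_common_delay(sq, u)
  ps <- reconstruct_step_delays(sq, u, init = com$delta)
  expect_equal(ps$delays, rep(com$delta, 2), tolerance = 2e-3)
})

test_that("noise never helps: the optimized residual grows with noise SD", {
  sq <- make_step_sequence("rev_RL", isi = 0.25, arp = 1.5)
  w_shift <- render_steps_dec(sq$step_times + c(0.15, 0.3), sq$step_levels,
                              180, 0.02)
  u0 <- as.numeric(stats::filter(0.6 * w_shift, filter = 0.5,
                                 method = "recursive"))
  mean_rss <- vapply(c(0, 0.03, 0.1), function(sig) {
    mean(vapply(1:5, function(i) {
      set.seed(100 + i)
      u <- u0 + rnorm(length(u0), 0, sig)
      com <- estimate_common_delay(sq, u)
      suppressWarnings(
        reconstruct_step_delays(sq, u, init = com$delta))$rss
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_rss) > 0))
})

test_that("simulated external trials reconstruct to the configured delays", {
  # ISI above the open-loop interval: both delays equal the feedback delay
  sim <- make_external_trial(0.50)
  rec <- reconstruct_trial(sim$trial, seq = sim$seq)
  expect_equal(rec$rt, c(0.14, 0.14), tolerance = 2e-3)
  # ISI below: the second response waits for the open-loop interval
  sim2 <- make_external_trial(0.20)
  rec2 <- reconstruct_trial(sim2$trial, seq = sim2$seq)
  expect_equal(rec2$rt, c(0.14, 0.35 - 0.20 + 0.14), tolerance = 2e-3)
})

test_that("session reconstruction yields one labelled pair per trial", {
  spec <- system_spec(0)
  set.seed(31)
  ses <- build_session(0, repetitions = 1,
                       patterns = c("rev_RL", "uni_LLc"))
  trs <- run_virtual_participant(spec, ses, "intermittent",
                                 ic_params(trigger_mode = "external"),
                                 seed = 31)
  tab <- suppressWarnings(reconstruct_session(trs, participant = 3))
  expect_equal(nrow(tab), 16)
  expect_setequal(unique(tab$pattern_class), c("reversed", "unidirectional"))
  expect_true(all(tab$participant == 3))
  pairs <- extract_rt_pairs(tab)
  expect_equal(nrow(pairs), 16)   # nothing dropped
  # a missing step delay drops the trial
  tab$rt2[3] <- NA
  expect_message(p2 <- extract_rt_pairs(tab), "dropping")
  expect_equal(nrow(p2), 15)
})
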