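test_that("the LQR design stabilizes every plant, including the unstable one", {
  for (spec in list(system_spec(1), system_spec(2, "marginally_stable"),
                    system_spec(2, "unstable"))) {
    dp <- discretize_plant(make_plant(spec), 0.001)
    des <- design_controller(dp)
    expect_true(all(des$cl_eig_mod < 1))
    # delay-free closed loop decays from a displaced state
    x <- c(0.1, numeric(dp$n - 1))
    for (i in 1:20000) x <- drop(des$Acl %*% x)
    expect_lt(abs(x[1]), 1e-3)
  }
  # zero-order plant: static tracking, output follows target after t_d
  dp0 <- discretize_plant(make_plant(system_spec(0)), 0.001)
  sq <- make_step_sequence("rev_RL", isi = 0.5, arp = 1)
  w <- render_target(sq, duration = 2.5)
  tr <- simulate_continuous(dp0, w, t_d = 0.14)
  d <- 140
  expect_equal(tr$y[(d + 1):2500], w[1:(2500 - d)])
})

test_that("externally triggered responses obey the single-channel timing law", {
  # oracle: second response onset = max(step2, step1 + delta_ol) + t_d
  delta_ol <- 0.35; t_d <- 0.14
  for (isi in isi_grid(0)) {
    sim <- make_external_trial(isi, delta_ol = delta_ol, t_d = t_d)
    tr <- sim$trial; s <- sim$seq$step_times
    expect_equal(tr$event_times[1], s[1], tolerance = 1e-9)
    expect_equal(tr$event_times[2], max(s[2], s[1] + delta_ol),
                 tolerance = 1e-9)
    onsets <- which(diff(tr$u_e) != 0) * tr$dt
    expect_equal(onsets[1], s[1] + t_d, tolerance = 1e-9)
    expect_equal(onsets[2], max(s[2], s[1] + delta_ol) + t_d,
                 tolerance = 1e-9)
  }
})

test_that("events cannot fire before the open-loop interval has elapsed", {
  set.seed(21)
  for (i in 1:8) {
    isi <- sample(isi_grid(0), 1)
    params <- ic_params(delta_ol = 0.35, trigger_mode = "internal",
                        threshold = 0, noise_sd = 0.01)
    sq <- make_step_sequence("rev_RL", isi = isi, arp = 1.2)
    dp <- discretize_plant(make_plant(system_spec(0)), 0.001)
    w <- render_target(sq, duration = max(sq$step_times) + 1)
    tr <- simulate_intermittent(dp, w, params)
    expect_true(all(diff(tr$event_times) >= 0.35 - 1e-9))
  }
})

test_that("zero-threshold internal triggering saturates at rate 1/delta_ol", {
  params <- ic_params(delta_ol = 0.25, trigger_mode = "internal",
                      threshold = 0, noise_sd = 0.01)
  dp <- discretize_plant(make_plant(system_spec(0)), 0.001)
  sq <- make_step_sequence("rev_RL", isi = 0.5, arp = 1.5)
  set.seed(4)
  tr <- simulate_intermittent(dp, render_target(sq, duration = 3), params)
  expect_equal(diff(tr$event_times), rep(0.25, length(tr$event_times) - 1),
               tolerance = 1e-9)
  expect_equal(length(tr$event_times), floor(3 / 0.25))
})

test_that("triggers within the sampling delay merge into a single event", {
  # two step onsets 0.1 s apart with a 0.2 s sampling delay: one event,
  # which samples the post-second-step target (unidirectional pattern so the
  # combined level differs from rest)
  sim <- make_external_trial(0.10, pattern = "uni_LLc", sampling_delay = 0.20)
  tr <- sim$trial
  expect_length(tr$event_times[tr$event_times < sim$seq$step_times[3]], 1)
  onsets <- which(diff(tr$u_e) != 0) * tr$dt
  expect_equal(onsets[1], sim$seq$step_times[1] + 0.20 + 0.14,
               tolerance = 1e-9)
  # the single combined response goes straight to the -2A level
  i1 <- round(onsets[1] / tr$dt) + 2
  expect_equal(tr$u_e[i1], -2)
  # with ISI > sampling delay the second step gets its own event
  sim2 <- make_external_trial(0.25, sampling_delay = 0.20)
  expect_length(sim2$trial$event_times, 2)
})

test_that("zero open-loop interval reproduces continuous control exactly", {
  dp <- discretize_plant(make_plant(system_spec(1)), 0.001)
  sq <- make_step_sequence("rev_RL", isi = 0.3, arp = 1.2)
  w <- render_target(sq)
  ti <- simulate_intermittent(dp, w, ic_params(delta_ol = 0,
                                               trigger_mode = "internal",
                                               threshold = 0))
  tc <- simulate_continuous(dp, w, t_d = 0.14)
  expect_lt(max(abs(ti$y - tc$y)), 1e-9)
  expect_length(tc$event_times, 0)
})

test_that("intermittent output approaches continuous as the interval shrinks", {
  dp <- discretize_plant(make_plant(system_spec(1)), 0.001)
  sq <- make_step_sequence("rev_RL", isi = 0.3, arp = 1.2)
  w <- render_target(sq)
  tc <- simulate_continuous(dp, w, t_d = 0.14)
  sups <- vapply(c(0.2, 0.05, 0.01), function(dol) {
    ti <- simulate_intermittent(dp, w, ic_params(delta_ol = dol,
                                                 trigger_mode = "internal",
                                                 threshold = 0))
    max(abs(ti$y - tc$y))
  }, numeric(1))
  expect_true(all(diff(sups) < 0))
})

test_that("continuous control keeps the unstable system on screen for 200 s", {
  spec <- system_spec(2, "unstable")
  dp <- discretize_plant(make_plant(spec), 0.001)
  sq <- make_step_sequence("rev_RL", isi = 0.55, arp = 4.5)
  w <- render_target(sq, duration = 200)
  set.seed(17)
  tr <- simulate_continuous(dp, w, t_d = 0.14, noise_sd = 0.02)
  expect_false(tr$meta$failed)
  expect_lt(max(abs(tr$y)), spec$display_limit)
})

test_that("virtual participants are reproducible and correctly sized", {
  spec <- system_spec(0)
  set.seed(8)
  ses <- build_session(0, repetitions = 1, patterns = c("rev_LR", "rev_RL"))
  p <- ic_params(trigger_mode = "external", noise_sd = 0.02)
  a <- run_virtual_participant(spec, ses, "intermittent", p, seed = 42)
  b <- run_virtual_participant(spec, ses, "intermittent", p, seed = 42)
  expect_length(a, 16)
  expect_identical(a, b)
  c2 <- run_virtual_participant(spec, ses, "intermittent", p, seed = 43)
  expect_false(identical(vapply(a, function(t) t$u_e[1000], numeric(1)),
                         vapply(c2, function(t) t$u_e[1000], numeric(1))))
})

test_that("double responses are classified from the event log", {
  # external mode: step1 always gets an event before step2 -> distinct
  sim <- make_external_trial(0.20)
  expect_equal(classify_double_response(sim$trial, sim$seq), "distinct")
  # one merged event (sampling delay covers both steps) -> combined
  sim2 <- make_external_trial(0.10, sampling_delay = 0.20)
  expect_equal(classify_double_response(sim2$trial, sim2$seq), "combined")
})

test_that("the trigger predicate enforces all three event conditions", {
  p <- ic_params(delta_ol = 0.35, sampling_delay = 0.05, threshold = 0.1,
                 trigger_mode = "internal")
  # error above threshold and interval elapsed: fire
  r <- event_trigger(0.5, now = 1.40, last_event_time = 1.00, params = p)
  expect_true(r$fire)
  # interval not yet elapsed: no fire regardless of error, but pending
  r <- event_trigger(0.5, now = 1.20, last_event_time = 1.00, params = p)
  expect_false(r$fire)
  expect_true(r$pending)
  # within the sampling delay of the previous event: merged, nothing queued
  r <- event_trigger(0.5, now = 1.01, last_event_time = 1.00, params = p)
  expect_false(r$fire)
  expect_false(r$pending)
  # below threshold: no candidate
  r <- event_trigger(0.05, now = 1.40, last_event_time = 1.00, params = p)
  expect_false(r$fire)
  # zero threshold internal mode: any nonzero error fires once allowed
  p0 <- ic_params(delta_ol = 0.35, threshold = 0, trigger_mode = "internal")
  expect_true(event_trigger(1e-9, 1.40, 1.00, p0)$fire)
  expect_false(event_trigger(0, 1.40, 1.00, p0)$fire)
  # a queued external step fires at the earliest permitted instant
  pe <- ic_params(delta_ol = 0.35, trigger_mode = "external")
  q <- event_trigger(0, 1.20, 1.00, pe, external_candidate = TRUE)
  expect_false(q$fire)
  expect_true(event_trigger(0, 1.35, 1.00, pe, pending = q$pending)$fire)
  expect_error(event_trigger(0, 0.5, 1.0, pe), "now")
})
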