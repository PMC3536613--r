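# Independent oracles used across the suite.

# matrix exponential by truncated Taylor series (independent of pracma)
expm_series <- function(M, terms = 40) {
  S <- diag(1, nrow(M))
  Tk <- diag(1, nrow(M))
  for (k in seq_len(terms)) {
    Tk <- Tk %*% M / k
    S <- S + Tk
  }
  S
}

# percentile by the linear-interpolation convention, written out from the
# h = (n - 1) p + 1 rule (independent of stats::quantile)
percentile_linear <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# least-squares residual of the zero-delay ARX map, written directly from the
# normal equations via qr (independent of the package's fit path)
oracle_arx_rss <- function(w, u, order, nb) {
  Eu <- stats::embed(u, order + 1)
  Ew <- stats::embed(w, order + 1)[, seq_len(nb), drop = FALSE]
  X <- cbind(Eu[, -1, drop = FALSE], Ew)
  yv <- Eu[, 1]
  sum(qr.resid(qr(X), yv)^2)
}

# exhaustive joint 2-D grid search over both step delays of a two-step trial
oracle_joint_2d <- function(seq, u_dec, grid, dt_id = 0.02, order = 10,
                            nb = 1) {
  n_out <- length(u_dec)
  best <- list(rss = Inf, delays = c(NA, NA))
  for (d1 in grid) for (d2 in grid) {
    st <- seq$step_times + c(d1, d2)
    wd <- render_steps_dec(st, seq$step_levels, n_out, dt_id)
    r <- oracle_arx_rss(wd, u_dec, order, nb)
    if (r < best$rss) best <- list(rss = r, delays = c(d1, d2))
  }
  best
}

# simulate one noise-free externally triggered double-step trial (order 0)
make_external_trial <- function(isi, pattern = "rev_RL", delta_ol = 0.35,
                                t_d = 0.14, sampling_delay = 0,
                                noise_sd = 0, arp = 1.5, lp_cutoff = Inf,
                                first_step_time = 0.5, dt = 0.001) {
  spec <- system_spec(0)
  dp <- discretize_plant(make_plant(spec), dt)
  sq <- make_step_sequence(pattern, first_step_time = first_step_time,
                           isi = isi, arp = arp)
  w <- render_target(sq, dt = dt, duration = max(sq$step_times) + 1)
  params <- ic_params(delta_ol = delta_ol, feedback_delay = t_d,
                      sampling_delay = sampling_delay,
                      trigger_mode = "external", lp_cutoff = lp_cutoff,
                      noise_sd = noise_sd)
  tr <- simulate_intermittent(dp, w, params,
                              meta = list(sequence = sq, spec = spec))
  list(trial = tr, seq = sq)
}

# reconstruct a cohort of virtual participants into a pairs table
simulate_cohort <- function(order = 0, controller = "continuous",
                            params = ic_params(), n_participants = 6,
                            repetitions = 1, patterns = c("rev_LR", "rev_RL"),
                            seed = 1) {
  spec <- system_spec(order)
  set.seed(seed)
  seeds <- sample.int(1e6, 2 * n_participants)
  tabs <- lapply(seq_len(n_participants), function(p) {
    set.seed(seeds[p])
    ses <- build_session(order, repetitions = repetitions, patterns = patterns)
    trs <- run_virtual_participant(spec, ses, controller, params,
                                   seed = seeds[n_participants + p])
    suppressWarnings(reconstruct_session(trs, participant = p))
  })
  do.call(rbind, tabs)
}
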