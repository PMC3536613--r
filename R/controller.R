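#' Intermittent-controller parameters
#'
#' Parameters of the event-triggered intermittent controller. An event (a
#' refresh of the open-loop control trajectory) requires three conditions:
#' (i) triggers within the sampling delay of an event are merged into it,
#' (ii) at least the minimum open-loop interval must have elapsed since the
#' previous event, and (iii) an error signal must exceed the threshold.
#' Between events the control signal is generated by a system-matched hold:
#' the sampled, delay-compensated state error evolves under the delay-free
#' closed-loop dynamics and is multiplied by the feedback gain.
#'
#' @param delta_ol minimum open-loop interval in seconds (default 0.35).
#' @param feedback_delay pure time delay t_d between sampling and actuation,
#'   seconds (default 0.14).
#' @param sampling_delay delay between event detection and sampling, seconds
#'   (default 0; the amplitude-transition variant uses a positive value).
#' @param threshold event threshold q on the absolute error signal, in
#'   screen units (default 0; with zero threshold, internal events fire as
#'   soon as the open-loop interval has elapsed and the error is nonzero).
#' @param trigger_mode `"external"` (one event per target step, fed by step
#'   onsets), `"internal"` (error-threshold crossings) or `"mixed"` (either).
#' @param lp_cutoff cutoff (Hz) of the first-order low-pass filter applied to
#'   the observed set-point before sampling; `Inf` disables it (default).
#' @param nms_time_constant first-order neuromuscular lag in seconds; 0
#'   (default) models the neuromuscular block as a pure gain.
#' @param noise_sd observation noise SD in screen units, applied
#'   independently to the observed system output and observed target.
#' @param delay_jitter_sd SD (s) of a per-trial Gaussian perturbation of the
#'   feedback delay, emulating the trial-to-trial variability of central
#'   processing delays; 0 (default) keeps the delay fixed.
#' @return An object of class `ic_params`.
#' @export
ic_params <- function(delta_ol = 0.35, feedback_delay = 0.14,
                      sampling_delay = 0, threshold = 0,
                      trigger_mode = c("external", "internal", "mixed"),
                      lp_cutoff = Inf, nms_time_constant = 0, noise_sd = 0,
                      delay_jitter_sd = 0) {
  trigger_mode <- match.arg(trigger_mode)
  for (nm in c("delta_ol", "feedback_delay", "sampling_delay", "threshold",
               "nms_time_constant", "noise_sd", "delay_jitter_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop("'", nm, "' must be a nonnegative scalar")
  }
  if (!(is.numeric(lp_cutoff) && length(lp_cutoff) == 1 && lp_cutoff > 0))
    stop("'lp_cutoff' must be positive (Hz) or Inf")
  structure(list(delta_ol = delta_ol, feedback_delay = feedback_delay,
                 sampling_delay = sampling_delay, threshold = threshold,
                 trigger_mode = trigger_mode, lp_cutoff = lp_cutoff,
                 nms_time_constant = nms_time_constant, noise_sd = noise_sd,
                 delay_jitter_sd = delay_jitter_sd),
            class = "ic_params")
}

## -- gain design ------------------------------------------------------------

# discrete-time LQR gain by Riccati fixed-point iteration
dlqr_gain <- function(Ad, Bd, Q = diag(nrow(Ad)), R = 1,
                      tol = 1e-12, max_iter = 100000L) {
  n <- nrow(Ad)
  if (n == 0L) return(matrix(0, 1, 0))
  P <- Q
  for (i in seq_len(max_iter)) {
    BtP <- crossprod(Bd, P)
    S <- drop(R + BtP %*% Bd)
    Kt <- (BtP %*% Ad) / S
    Pn <- Q + crossprod(Ad, P %*% Ad) - crossprod(Ad, P %*% Bd) %*% Kt
    Pn <- (Pn + t(Pn)) / 2
    if (max(abs(Pn - P)) < tol * max(1, max(abs(P)))) { P <- Pn; break }
    P <- Pn
  }
  BtP <- crossprod(Bd, P)
  matrix(drop(BtP %*% Ad) / drop(R + BtP %*% Bd), 1, n)
}

# steady-state Kalman-style observer gain (current-estimator form uses Ad %*% K)
dkalman_gain <- function(Ad, C, Qn, Rn, tol = 1e-12, max_iter = 100000L) {
  n <- nrow(Ad)
  if (n == 0L) return(matrix(0, 0, 1))
  P <- diag(n)
  for (i in seq_len(max_iter)) {
    S <- drop(C %*% P %*% t(C)) + Rn
    K <- (P %*% t(C)) / S
    Pn <- Ad %*% (P - K %*% C %*% P) %*% t(Ad) + Qn
    Pn <- (Pn + t(Pn)) / 2
    if (max(abs(Pn - P)) < tol * max(1, max(abs(P)))) { P <- Pn; break }
    P <- Pn
  }
  S <- drop(C %*% P %*% t(C)) + Rn
  Ad %*% ((P %*% t(C)) / S)
}

# steady-state (x*, u*) achieving output w: solve [Ad - I, Bd; C, D][x;u] = [0;w]
reference_map <- function(dplant) {
  n <- dplant$n
  M <- rbind(cbind(dplant$Ad - diag(1, n), dplant$Bd),
             cbind(dplant$C, dplant$D))
  Minv <- solve(M)
  rhs0 <- c(rep(0, n), 1)
  sol <- drop(Minv %*% rhs0)   # per unit of w; scale linearly
  list(xstar = sol[seq_len(n)], ustar = sol[n + 1])
}

#' Design stabilizing feedback and observer gains for a plant
#'
#' Linear-quadratic state feedback (unit weights by default) on the
#' zero-order-hold discretized plant, plus a steady-state Kalman-style
#' observer gain. The delay-free closed loop `Ad - Bd k` is asymptotically
#' stable (all eigenvalues strictly inside the unit circle) for every
#' stabilizable configuration, including the unstable second-order system.
#'
#' @param dplant a [discretize_plant()] result.
#' @param Q,R LQR state and input weights (defaults: identity and 1).
#' @param noise_sd assumed observation noise SD used for the observer gain.
#' @return List with feedback gain `k` (1 x n), observer gain `L` (n x 1),
#'   closed-loop matrix `Acl` and its eigenvalue moduli `cl_eig_mod`.
#' @export
design_controller <- function(dplant, Q = diag(1, dplant$n), R = 1,
                              noise_sd = 0) {
  n <- dplant$n
  k <- dlqr_gain(dplant$Ad, dplant$Bd, Q = Q, R = R)
  Rn <- max(noise_sd^2, 1e-10)
  L <- dkalman_gain(dplant$Ad, dplant$C, Qn = diag(1e-6, n), Rn = Rn)
  Acl <- dplant$Ad - dplant$Bd %*% k
  mods <- if (n > 0) Mod(eigen(Acl, only.values = TRUE)$values) else numeric(0)
  if (n > 0 && any(mods >= 1))
    stop("LQR design failed to stabilize the plant (closed-loop |eig| >= 1)")
  list(k = k, L = L, Acl = Acl, cl_eig_mod = mods)
}

# augment a continuous plant with a first-order neuromuscular lag (input side)
compose_nms <- function(plant, time_constant) {
  if (time_constant <= 0) return(plant)
  n <- plant$n
  A <- rbind(cbind(plant$A, plant$B), matrix(0, 1, n + 1))
  A[n + 1, n + 1] <- -1 / time_constant
  B <- rbind(matrix(0, n, 1), 1 / time_constant)
  C <- cbind(plant$C, plant$D)   # feedthrough now routed through the lag state
  D <- matrix(0, 1, 1)
  structure(list(A = A, B = B, C = C, D = D, n = n + 1L, spec = plant$spec),
            class = "plant")
}

## -- trial record -----------------------------------------------------------

new_trial_record <- function(dt, w, u, u_e, y, d, event_times, reset_times,
                             meta) {
  structure(list(dt = dt, w = w, u = u, u_e = u_e, y = y, d = d,
                 event_times = event_times, reset_times = reset_times,
                 meta = meta),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> %.2f s at dt = %g s, %d event(s), %d reset(s)\n",
              length(x$w) * x$dt, x$dt, length(x$event_times),
              length(x$reset_times)))
  invisible(x)
}

## -- simulators -------------------------------------------------------------

# per-trial realization of the feedback delay
draw_delay <- function(t_d, jitter_sd) {
  if (jitter_sd > 0) max(0, t_d + stats::rnorm(1, 0, jitter_sd)) else t_d
}

lp_filter <- function(x, cutoff, dt) {
  if (!is.finite(cutoff)) return(x)
  a <- exp(-2 * pi * cutoff * dt)
  as.numeric(stats::filter(x * (1 - a), filter = a, method = "recursive"))
}

# shared precomputation for both simulators
sim_setup <- function(dplant, target, params, t_d) {
  nT <- length(target)
  if (nT == 0L) stop("'target' must be non-empty")
  dt <- dplant$dt
  n <- dplant$n
  des <- design_controller(dplant, noise_sd = params$noise_sd)
  sig <- params$noise_sd
  eta_y <- if (sig > 0) stats::rnorm(nT, 0, sig) else numeric(nT)
  eta_w <- if (sig > 0) stats::rnorm(nT, 0, sig) else numeric(nT)
  wf <- lp_filter(target + eta_w, params$lp_cutoff, dt)
  ref <- reference_map(dplant)
  d <- as.integer(round(t_d / dt))
  # d-step-ahead prediction: x(t+d) = Ad^d x(t) + Pmat %*% u_cmd[(t-d)..(t-1)]
  # (computed fresh every use: a recursive predictor would carry the plant's
  # unstable mode as its own autonomous dynamics and amplify rounding error)
  if (n > 0 && d > 0) {
    Pmat <- matrix(0, n, d)
    col <- dplant$Bd
    for (j in d:1) { Pmat[, j] <- col; if (j > 1) col <- dplant$Ad %*% col }
    M <- diag(1, n); A <- dplant$Ad; e <- d
    while (e > 0) { if (e %% 2 == 1) M <- M %*% A; A <- A %*% A; e <- e %/% 2 }
    Add <- M
  } else {
    Pmat <- matrix(0, n, max(d, 0))
    Add <- diag(1, n)
  }
  list(nT = nT, dt = dt, n = n, des = des, eta_y = eta_y, wf = wf,
       ref = ref, d = d, Add = Add, Pmat = Pmat)
}

# prediction of x(t+d) given xo(t) and the command history ucmd[1..t-1]
predict_ahead <- function(t, d, Add, Pmat, xo, ucmd) {
  if (d == 0L) return(xo)
  v <- if (t > d) ucmd[(t - d):(t - 1)]
       else c(numeric(d - t + 1), if (t > 1) ucmd[seq_len(t - 1)] else numeric(0))
  drop(Add %*% xo) + drop(Pmat %*% v)
}

#' Simulate one trial under intermittent control
#'
#' Event-triggered control of the plant while tracking a sampled target.
#' At each event the delay-compensated predicted state error is sampled and
#' loaded into the system-matched hold; between events the hold evolves under
#' the delay-free closed-loop dynamics, so the response latency to an
#' isolated step equals the feedback delay (plus the sampling delay if set).
#'
#' @param dplant a [discretize_plant()] result (the controlled system, with
#'   any neuromuscular lag already composed in).
#' @param target target series sampled at `dplant$dt` (see [render_target()]).
#' @param params an [ic_params()] object.
#' @param disturbance optional input disturbance series (same length), added
#'   to the control signal at the plant input. Default zero.
#' @param reset_enabled if `TRUE`, zero the plant state when the output
#'   leaves the display (default `FALSE`).
#' @param meta optional list stored in the record's metadata.
#' @return A `trial_record` with target `w`, commanded control `u`, applied
#'   (externally observed) control `u_e`, disturbance `d`, output `y`, event
#'   times, and reset times. Uses the current RNG state when `noise_sd > 0`.
#' @export
simulate_intermittent <- function(dplant, target, params = ic_params(),
                                  disturbance = NULL, reset_enabled = FALSE,
                                  meta = list()) {
  if (!inherits(params, "ic_params")) stop("'params' must come from ic_params()")
  t_d <- draw_delay(params$feedback_delay, params$delay_jitter_sd)
  st <- sim_setup(dplant, target, params, t_d)
  nT <- st$nT; dt <- st$dt; n <- st$n; d <- st$d
  ds <- as.integer(round(params$sampling_delay / dt))
  dol <- as.integer(round(params$delta_ol / dt))
  q <- params$threshold
  mode <- params$trigger_mode
  dist <- if (is.null(disturbance)) numeric(nT) else disturbance
  if (length(dist) != nT) stop("'disturbance' must match the target length")

  Ad <- dplant$Ad; Bd <- dplant$Bd
  Cm <- drop(dplant$C); Dm <- drop(dplant$D)
  k <- drop(st$des$k); L <- drop(st$des$L); Acl <- st$des$Acl
  Add <- st$Add; Pmat <- st$Pmat
  xs1 <- st$ref$xstar; us1 <- st$ref$ustar
  wf <- st$wf; eta_y <- st$eta_y
  onset <- which(diff(target) != 0) + 1L
  is_onset <- logical(nT); is_onset[onset] <- TRUE
  limit <- dplant$spec$display_limit

  ucmd <- numeric(nT); ue_s <- numeric(nT); y <- numeric(nT)
  x <- numeric(n); xo <- numeric(n); e_h <- numeric(n)
  ustar_cur <- 0
  pending <- FALSE
  last_fire <- -1e9
  sample_due <- -1L
  events <- numeric(0); resets <- numeric(0)

  for (t in seq_len(nT)) {
    ue <- dist[t] + if (t > d) ucmd[t - d] else 0
    yt <- (if (n > 0) sum(Cm * x) else 0) + Dm * ue
    if (reset_enabled && abs(yt) > limit) {
      x <- numeric(n); resets <- c(resets, (t - 1) * dt)
      yt <- Dm * ue
    }
    y[t] <- yt; ue_s[t] <- ue
    yobs <- yt + eta_y[t]
    innov <- if (n > 0) yobs - sum(Cm * xo) - Dm * ue else 0

    # -- event trigger: (i) merge within sampling delay, (ii) open-loop
    #    interval elapsed, (iii) error exceeds threshold ----------------
    in_merge <- ds > 0L && (t - last_fire) <= ds && last_fire > 0
    if (!in_merge) {
      cand <- switch(mode,
        external = is_onset[t],
        internal = abs(wf[t] - yobs) > q,
        mixed    = is_onset[t] || abs(wf[t] - yobs) > q)
      if (cand) pending <- TRUE
    }
    if (pending && (t - last_fire) >= dol) {
      last_fire <- t
      events <- c(events, (t - 1) * dt)
      pending <- FALSE
      sample_due <- t + ds
    }
    if (t == sample_due) {
      w_i <- wf[t]
      if (n > 0) {
        z <- predict_ahead(t, d, Add, Pmat, xo, ucmd)
        e_h <- z - xs1 * w_i
      }
      ustar_cur <- us1 * w_i
    }
    ucmd[t] <- ustar_cur - if (n > 0) sum(k * e_h) else 0
    if (n > 0) {
      e_h <- drop(Acl %*% e_h)
      xo <- drop(Ad %*% xo) + drop(Bd) * ue + L * innov
      x <- drop(Ad %*% x) + drop(Bd) * ue
    }
  }
  failed <- any(!is.finite(y)) || max(abs(y[is.finite(y)]), 0) > 1e6
  if (failed) warning("simulated trial diverged; flagged as failed")
  meta$controller <- "intermittent"; meta$params <- params
  meta$spec <- dplant$spec; meta$failed <- failed
  new_trial_record(dt, target, ucmd, ue_s, y, dist, events, resets, meta)
}

#' Simulate one trial under continuous predictive control
#'
#' Predictor-based state feedback applied at every sample: the continuous
#' limit of the intermittent controller (zero open-loop interval). The event
#' log is empty by construction.
#'
#' @inheritParams simulate_intermittent
#' @param t_d feedback time delay in seconds.
#' @param noise_sd observation noise SD (screen units).
#' @param lp_cutoff optional set-point low-pass cutoff in Hz (default off).
#' @param delay_jitter_sd per-trial feedback-delay jitter SD (s), default 0.
#' @return A `trial_record` with an empty event log.
#' @export
simulate_continuous <- function(dplant, target, t_d = 0.14, noise_sd = 0,
                                lp_cutoff = Inf, delay_jitter_sd = 0,
                                disturbance = NULL,
                                reset_enabled = FALSE, meta = list()) {
  t_d <- draw_delay(t_d, delay_jitter_sd)
  params <- ic_params(delta_ol = 0, feedback_delay = t_d, threshold = 0,
                      trigger_mode = "internal", lp_cutoff = lp_cutoff,
                      noise_sd = noise_sd)
  st <- sim_setup(dplant, target, params, t_d)
  nT <- st$nT; dt <- st$dt; n <- st$n; d <- st$d
  dist <- if (is.null(disturbance)) numeric(nT) else disturbance
  if (length(dist) != nT) stop("'disturbance' must match the target length")
  Ad <- dplant$Ad; Bd <- dplant$Bd; Cm <- drop(dplant$C); Dm <- drop(dplant$D)
  k <- drop(st$des$k); L <- drop(st$des$L)
  Add <- st$Add; Pmat <- st$Pmat
  xs1 <- st$ref$xstar; us1 <- st$ref$ustar
  wf <- st$wf; eta_y <- st$eta_y
  limit <- dplant$spec$display_limit

  ucmd <- numeric(nT); ue_s <- numeric(nT); y <- numeric(nT)
  x <- numeric(n); xo <- numeric(n)
  for (t in seq_len(nT)) {
    ue <- dist[t] + if (t > d) ucmd[t - d] else 0
    yt <- (if (n > 0) sum(Cm * x) else 0) + Dm * ue
    if (reset_enabled && abs(yt) > limit) {
      x <- numeric(n); yt <- Dm * ue
    }
    y[t] <- yt; ue_s[t] <- ue
    innov <- if (n > 0) yt + eta_y[t] - sum(Cm * xo) - Dm * ue else 0
    w_i <- wf[t]
    if (n > 0) {
      z <- predict_ahead(t, d, Add, Pmat, xo, ucmd)
      ucmd[t] <- us1 * w_i - sum(k * (z - xs1 * w_i))
      xo <- drop(Ad %*% xo) + drop(Bd) * ue + L * innov
      x <- drop(Ad %*% x) + drop(Bd) * ue
    } else ucmd[t] <- us1 * w_i
  }
  failed <- any(!is.finite(y)) || max(abs(y[is.finite(y)]), 0) > 1e6
  if (failed) warning("simulated trial diverged; flagged as failed")
  meta$controller <- "continuous"; meta$t_d <- t_d
  meta$noise_sd <- noise_sd; meta$spec <- dplant$spec; meta$failed <- failed
  new_trial_record(dt, target, ucmd, ue_s, y, dist, numeric(0), numeric(0),
                   meta)
}

#' Simulate a virtual participant over a whole session
#'
#' Runs one trial per step sequence with independent noise streams; fully
#' reproducible given `seed`.
#'
#' @param spec a [system_spec()].
#' @param session a [build_session()] result (or any list of step sequences).
#' @param controller `"intermittent"` or `"continuous"`.
#' @param params [ic_params()] used for the intermittent controller and for
#'   the noise level / delay of the continuous controller.
#' @param seed integer seed for the participant's noise streams.
#' @param dt simulation step (default 0.001 s).
#' @param tail extra simulated time after the last step, seconds.
#' @return A list of `trial_record`s; each record's metadata carries the
#'   step sequence, trial id and seed.
#' @export
run_virtual_participant <- function(spec, session,
                                    controller = c("intermittent", "continuous"),
                                    params = ic_params(), seed = 1L,
                                    dt = 0.001, tail = 1.0) {
  controller <- match.arg(controller)
  plant <- compose_nms(make_plant(spec), params$nms_time_constant)
  dp <- discretize_plant(plant, dt)
  set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max, length(session))
  lapply(seq_along(session), function(i) {
    sq <- session[[i]]
    duration <- max(sq$duration, max(sq$step_times) + tail)
    w <- render_target(sq, dt = dt, duration = duration)
    set.seed(trial_seeds[i])
    meta <- list(sequence = sq, trial_id = if (!is.null(sq$trial_id)) sq$trial_id else i,
                 seed = trial_seeds[i])
    if (controller == "intermittent")
      simulate_intermittent(dp, w, params, meta = meta)
    else
      simulate_continuous(dp, w, t_d = params$feedback_delay,
                          noise_sd = params$noise_sd,
                          lp_cutoff = params$lp_cutoff,
                          delay_jitter_sd = params$delay_jitter_sd,
                          meta = meta)
  })
}

#' Classify whether the second step received its own control event
#'
#' For a double-step trial, the second response is *distinct* when a control
#' event fell between the two step onsets (so the first event sampled only
#' the first step); otherwise a single event sampled the post-second-step
#' target and the two responses were *combined*. Used when summarizing RT2
#' under internally triggered (saturated) control, where RT2 is only defined
#' by trials with a distinct second response.
#'
#' @param trial a `trial_record` whose metadata carries the step sequence.
#' @param seq optionally, the step sequence (defaults to the one in `trial`).
#' @return `"distinct"`, `"combined"`, or `"none"` (no event at or after the
#'   first step).
#' @export
classify_double_response <- function(trial, seq = trial$meta$sequence) {
  if (is.null(seq)) stop("no step sequence available for this trial")
  s <- seq$step_times
  if (length(s) < 2) stop("classification needs at least two steps")
  ev <- trial$event_times
  if (!length(ev) || !any(ev >= s[1])) return("none")
  if (any(ev >= s[1] & ev < s[2]) && any(ev >= s[2])) "distinct" else "combined"
}

#' Event-trigger predicate
#'
#' The three-condition rule deciding whether a control event fires at time
#' `now`: (i) candidates within the sampling delay of the previous event
#' are merged into it (no new event), (ii) the minimum open-loop interval
#' must have elapsed since the previous event, and (iii) the error signal
#' must exceed the threshold — in internal mode with a zero threshold any
#' nonzero error qualifies, so events fire as soon as the open-loop
#' interval has elapsed. External candidates (step onsets) that arrive
#' while the open-loop interval is still running stay pending and fire at
#' the earliest permitted time; `pending` carries that state.
#'
#' [simulate_intermittent()] applies this same rule sample by sample; the
#' predicate is exposed for direct inspection and testing.
#'
#' @param error current error-signal value (screen units).
#' @param now current time (s).
#' @param last_event_time time of the previous event (s); `-Inf` if none.
#' @param params an [ic_params()].
#' @param pending `TRUE` when an external candidate is queued from earlier.
#' @param external_candidate `TRUE` when a step onset occurs at `now`.
#' @return List with `fire` (logical) and the updated `pending` flag.
#' @export
event_trigger <- function(error, now, last_event_time, params,
                          pending = FALSE, external_candidate = FALSE) {
  if (now < last_event_time) stop("'now' must be >= 'last_event_time'")
  elapsed <- now - last_event_time
  in_merge <- is.finite(last_event_time) &&
    params$sampling_delay > 0 && elapsed <= params$sampling_delay
  if (!in_merge) {
    cand <- switch(params$trigger_mode,
      external = external_candidate,
      internal = abs(error) > params$threshold,
      mixed    = external_candidate || abs(error) > params$threshold)
    if (cand) pending <- TRUE
  }
  fire <- pending && elapsed >= params$delta_ol
  if (fire) pending <- FALSE
  list(fire = fire, pending = pending)
}
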