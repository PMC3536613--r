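## Stage 1: set-point reconstruction.
## The closed-loop target -> joystick relation is modelled as a low-order,
## zero-dead-time ARX map at a reduced identification rate; per-step response
## delays are the step-instant shifts that minimize its residual.

#' Decimate a series with a centered boxcar anti-alias filter
#'
#' Sample k of the output is the mean of the input over a window of width
#' `dt_id` centered on time `(k-1) * dt_id`. The boxcar is zero-phase, and
#' the identical operator has a closed form for piecewise-constant targets
#' ([render_steps_dec()]), which keeps delay estimates unbiased.
#'
#' @param x input series sampled at `dt`.
#' @param dt input sampling interval (s).
#' @param dt_id identification sampling interval (s), default 0.02 (50 Hz).
#' @return Decimated numeric vector.
#' @export
decimate_boxcar <- function(x, dt = 0.001, dt_id = 0.02) {
  f <- round(dt_id / dt)
  if (f < 1 || abs(f * dt - dt_id) > 1e-9)
    stop("'dt_id' must be an integer multiple of 'dt'")
  if (f == 1) return(as.numeric(x))
  nT <- length(x)
  K <- (nT - 1) %/% f + 1
  half <- f %/% 2
  cs <- c(0, cumsum(x))
  j1 <- pmax((seq_len(K) - 1) * f - half + 1, 1)
  j2 <- pmin((seq_len(K) - 1) * f + (f - half), nT)
  (cs[j2 + 1] - cs[j1]) / (j2 - j1 + 1)
}

#' Render step instants directly on the identification grid
#'
#' Closed-form area sampling of a piecewise-constant target through the same
#' centered boxcar used by [decimate_boxcar()]: the window average of a unit
#' step at `s` is `clamp((b_k - s) / dt_id, 0, 1)` with `b_k` the window's
#' right edge.
#'
#' @param step_times step instants (s), any order.
#' @param step_levels target level after each step.
#' @param n_out number of output samples.
#' @param dt_id identification sampling interval (s).
#' @return Numeric vector of length `n_out`.
#' @export
render_steps_dec <- function(step_times, step_levels, n_out, dt_id = 0.02) {
  o <- order(step_times)
  s <- step_times[o]
  incr <- diff(c(0, step_levels[o]))
  b <- (seq_len(n_out) - 1) * dt_id + dt_id / 2
  w <- numeric(n_out)
  for (j in seq_along(s)) {
    frac <- (b - s[j]) / dt_id
    w <- w + incr[j] * pmin(pmax(frac, 0), 1)
  }
  w
}

#' Fit a zero-delay ARX map from target to response
#'
#' Least-squares fit of `u[t] = sum a_i u[t-i] + sum b_j w[t-j] + e[t]`
#' (i = 1..order, j = 0..nb-1): a rational input-output model with zero
#' dead time, the Stage-1 closed-loop approximant. By default the numerator
#' is a single instantaneous feedthrough coefficient (`nb = 1`): delayed
#' numerator taps at the identification rate could otherwise represent a
#' pure transport delay of up to `order * dt_id` and silently absorb the
#' response delay that the step-instant optimization is meant to recover.
#' With `nb = 1` the model's dynamics live entirely in the autoregressive
#' part, so any delay must be carried by the reconstructed step instants.
#'
#' @param w target series on the identification grid.
#' @param u response (joystick) series, same length.
#' @param order autoregressive model order (default 10).
#' @param nb number of numerator taps `b[0..nb-1]` (default 1).
#' @param dt_id identification sampling interval, stored for reference.
#' @return List of class `lti_fit`: `a`, `b`, `rss`, `residual_variance`,
#'   `aic`, `n_eff`, `order`, `rank`, `dt_id`.
#' @export
fit_arx <- function(w, u, order = 10, nb = 1, dt_id = 0.02) {
  if (length(w) != length(u)) stop("'w' and 'u' must have equal length")
  if (nb < 1 || nb > order + 1) stop("'nb' must be in 1..order+1")
  if (length(u) < 3 * (order + 1))
    stop("series too short for an order-", order, " fit")
  Eu <- stats::embed(u, order + 1)
  Ew <- stats::embed(w, order + 1)[, seq_len(nb), drop = FALSE]
  X <- cbind(Eu[, -1, drop = FALSE], Ew)
  yv <- Eu[, 1]
  fit <- .lm.fit(X, yv)
  if (fit$rank < ncol(X))
    stop("singular ARX regression (rank ", fit$rank, " < ", ncol(X),
         " columns); the target may carry too few transitions")
  rss <- sum(fit$residuals^2)
  n_eff <- length(yv)
  cf <- fit$coefficients
  structure(list(a = cf[seq_len(order)], b = cf[order + seq_len(nb)],
                 rss = rss, residual_variance = rss / n_eff,
                 aic = n_eff * log(max(rss, 1e-300) / n_eff) + 2 * (order + nb),
                 n_eff = n_eff, order = order, nb = nb, rank = fit$rank,
                 dt_id = dt_id),
            class = "lti_fit")
}

# fast residual-only path used inside the delay searches (tolerates
# rank deficiency: pivoted QR still yields the least-squares residual)
arx_rss <- function(Ew, Eu_lags, yv) {
  sum(.lm.fit(cbind(Eu_lags, Ew), yv)$residuals^2)
}

#' AIC check of the ARX model order
#'
#' Fits orders `1..max_order` and reports AIC; warns when the chosen order
#' exceeds the AIC-optimal order by more than `slack`.
#'
#' @param w,u series on the identification grid.
#' @param chosen the production order (default 10).
#' @param max_order largest order fitted (default 12).
#' @param slack allowed excess over the AIC-optimal order (default 2).
#' @return Data frame with columns `order`, `rss`, `aic`, plus attributes
#'   `opt_order` and `ok`.
#' @export
check_arx_order <- function(w, u, chosen = 10, max_order = 12, slack = 2) {
  tab <- do.call(rbind, lapply(seq_len(max_order), function(n) {
    f <- fit_arx(w, u, order = n, nb = 1)
    data.frame(order = n, rss = f$rss, aic = f$aic)
  }))
  opt <- tab$order[which.min(tab$aic)]
  ok <- chosen <= opt + slack
  if (!ok)
    warning("ARX order ", chosen, " exceeds the AIC-optimal order (", opt,
            ") by more than ", slack)
  attr(tab, "opt_order") <- opt
  attr(tab, "ok") <- ok
  tab
}

# residuals over a set of candidate shifts of selected steps
shift_search <- function(deltas, base_times, move, levels, Eu_lags, yv,
                         n_out, dt_id, order, nb) {
  vapply(deltas, function(d) {
    st <- base_times
    st[move] <- st[move] + d
    wd <- render_steps_dec(st, levels, n_out, dt_id)
    arx_rss(stats::embed(wd, order + 1)[, seq_len(nb), drop = FALSE],
            Eu_lags, yv)
  }, numeric(1))
}

# coarse grid + local 1 ms grid + parabolic vertex; smallest delay wins ties
refine_min <- function(deltas, rss, eval_fn, fine_step, lo = 0, refine = TRUE) {
  i <- which.min(rss)
  d0 <- deltas[i]
  if (!refine || length(deltas) < 2) return(list(delta = d0, rss = rss[i]))
  h <- if (length(deltas) >= 2) min(diff(sort(deltas))) else 0
  fine <- seq(max(lo, d0 - h), d0 + h, by = fine_step)
  fr <- eval_fn(fine)
  j <- which.min(fr)
  d1 <- fine[j]; r1 <- fr[j]
  # parabolic vertex through the fine minimum and neighbours (sub-grid tweak)
  if (j > 1 && j < length(fine)) {
    den <- fr[j - 1] - 2 * fr[j] + fr[j + 1]
    if (is.finite(den) && den > 0) {
      dv <- d1 + fine_step * (fr[j - 1] - fr[j + 1]) / (2 * den)
      if (abs(dv - d1) < fine_step && dv >= lo) d1 <- dv
    }
  }
  list(delta = d1, rss = r1)
}

#' Time-invariant delay: equal shift of every step instant
#'
#' Finds the common delay that, applied to all step instants of the
#' sequence, minimizes the ARX residual — the time-invariant optimization
#' that determines the overall delay of the closed-loop model.
#'
#' @param seq a [make_step_sequence()] object (or list with `step_times`,
#'   `step_levels`).
#' @param u_dec decimated response series (see [decimate_boxcar()]).
#' @param dt_id identification sampling interval (s).
#' @param order ARX order.
#' @param max_delay largest delay searched, seconds (default 1.5; responses
#'   cannot precede stimuli, so negative delays are excluded).
#' @param grid optional explicit candidate-delay grid; default: a coarse grid
#'   at `dt_id` refined locally to `fine_step`.
#' @param fine_step local refinement step (s), default 0.001.
#' @param refine logical; disable to search the coarse/explicit grid only.
#' @return List with `delta` (s), `rss`, and the coarse residual curve
#'   (`grid`, `rss_curve`).
#' @export
estimate_common_delay <- function(seq, u_dec, dt_id = 0.02, order = 10,
                                  nb = 1, max_delay = 1.5, grid = NULL,
                                  fine_step = 0.001, refine = TRUE) {
  if (is.null(grid)) grid <- seq(0, max_delay, by = dt_id)
  if (!length(grid)) stop("empty delay grid")
  n_out <- length(u_dec)
  Eu <- stats::embed(u_dec, order + 1)
  yv <- Eu[, 1]
  Eu_lags <- Eu[, -1, drop = FALSE]
  move <- seq_along(seq$step_times)
  ev <- function(ds) shift_search(ds, seq$step_times, move, seq$step_levels,
                                  Eu_lags, yv, n_out, dt_id, order, nb)
  rss <- ev(grid)
  res <- refine_min(grid, rss, ev, fine_step, lo = 0, refine = refine)
  list(delta = res$delta, rss = res$rss, grid = grid, rss_curve = rss)
}

#' Non-time-invariant optimization: per-step response delays
#'
#' Sequentially and individually adjusts the instant of each step (in
#' temporal order, repeated passes) to minimize the ARX residual, starting
#' from the common-delay solution. The per-step delay is the optimized minus
#' the actual step instant.
#'
#' @inheritParams estimate_common_delay
#' @param init initial delay applied to every step (typically the
#'   [estimate_common_delay()] result).
#' @param max_passes maximum number of sequential passes (default 4).
#' @param tol relative residual improvement below which a pass stops.
#' @return List with `delays` (per step, s), `rss`, `converged`, `passes`.
#' @export
reconstruct_step_delays <- function(seq, u_dec, dt_id = 0.02, order = 10,
                                    nb = 1, init = 0, max_delay = 1.5,
                                    grid = NULL, fine_step = 0.001,
                                    refine = TRUE, max_passes = 4,
                                    tol = 1e-4) {
  base_grid <- if (is.null(grid)) seq(0, max_delay, by = dt_id) else grid
  if (!length(base_grid)) stop("empty delay grid")
  n_out <- length(u_dec)
  Eu <- stats::embed(u_dec, order + 1)
  yv <- Eu[, 1]
  Eu_lags <- Eu[, -1, drop = FALSE]
  p <- length(seq$step_times)
  delays <- rep(init, p)
  cur <- function(times) arx_rss(stats::embed(
    render_steps_dec(times, seq$step_levels, n_out, dt_id),
    order + 1)[, seq_len(nb), drop = FALSE], Eu_lags, yv)
  rss_now <- cur(seq$step_times + delays)
  converged <- FALSE
  pass <- 0L
  while (pass < max_passes) {
    pass <- pass + 1L
    rss_before <- rss_now
    for (j in seq_len(p)) {
      times_o <- seq$step_times + delays
      ev <- function(ds) shift_search(ds, `[<-`(times_o, j, seq$step_times[j]),
                                      j, seq$step_levels, Eu_lags, yv,
                                      n_out, dt_id, order, nb)
      rss_g <- ev(base_grid)
      best <- refine_min(base_grid, rss_g, ev, fine_step, lo = 0,
                         refine = refine && pass > 1)
      if (best$rss < rss_now - 1e-15) {
        delays[j] <- best$delta
        rss_now <- best$rss
      }
    }
    if (rss_before - rss_now <= tol * (1 + rss_before)) { converged <- TRUE; break }
  }
  # final local refinement of each step at the fine grid
  if (refine) {
    for (j in seq_len(p)) {
      times_o <- seq$step_times + delays
      ev <- function(ds) shift_search(ds, `[<-`(times_o, j, seq$step_times[j]),
                                      j, seq$step_levels, Eu_lags, yv,
                                      n_out, dt_id, order, nb)
      loc <- seq(max(0, delays[j] - dt_id), delays[j] + dt_id, by = fine_step)
      rss_l <- ev(loc)
      best <- refine_min(loc, rss_l, ev, fine_step, lo = 0, refine = FALSE)
      if (best$rss <= rss_now + 1e-15) {
        # parabolic vertex around the fine minimum
        jj <- which.min(rss_l)
        dv <- loc[jj]
        if (jj > 1 && jj < length(loc)) {
          den <- rss_l[jj - 1] - 2 * rss_l[jj] + rss_l[jj + 1]
          if (is.finite(den) && den > 0) {
            cand <- dv + fine_step * (rss_l[jj - 1] - rss_l[jj + 1]) / (2 * den)
            if (abs(cand - dv) < fine_step && cand >= 0) dv <- cand
          }
        }
        delays[j] <- dv
        rss_now <- min(rss_now, best$rss)
      }
    }
  }
  if (!converged)
    warning("per-step delay optimization did not converge in ", max_passes,
            " passes; returning best found")
  list(delays = delays, rss = rss_now, converged = converged, passes = pass)
}

#' Reconstruct RT1/RT2 for one simulated or recorded trial
#'
#' Runs the full Stage-1 chain on a trial: decimate the response to the
#' identification rate, estimate the time-invariant common delay, then
#' optimize per-step delays.
#'
#' @param trial a `trial_record` (its metadata must carry the step sequence),
#'   or a list with elements `w`-independent: use `seq`, `response`, `dt`.
#' @param seq step sequence; defaults to the one stored in the trial.
#' @param response which series to treat as the joystick response: `"u_e"`
#'   (externally observed control, default), `"u"` or `"y"`.
#' @param dt_id identification sampling interval (s), default 0.02.
#' @param order ARX order, default 10.
#' @param nb numerator taps; `NULL` (default) matches the controlled
#'   system's order recorded in the trial metadata (`system order + 1`, the
#'   numerator degree of the closed-loop target-to-joystick map), falling
#'   back to 1. A larger `nb` lets the taps absorb part of the response
#'   delay; a smaller one cannot represent the map's feedthrough structure.
#' @param max_delay delay search range upper limit (s), default 1.5.
#' @param refine logical, local fine-grid refinement (default TRUE).
#' @return List with `rt` (per-step delays, s), `delta_common`, `rss`,
#'   `converged`.
#' @export
reconstruct_trial <- function(trial, seq = trial$meta$sequence,
                              response = c("u_e", "u", "y"),
                              dt_id = 0.02, order = 10, nb = NULL,
                              max_delay = 1.5, refine = TRUE) {
  response <- match.arg(response)
  if (is.null(seq)) stop("no step sequence available for this trial")
  if (is.null(nb))
    nb <- if (!is.null(trial$meta$spec$order)) trial$meta$spec$order + 1L else 1L
  u_dec <- decimate_boxcar(trial[[response]], dt = trial$dt, dt_id = dt_id)
  com <- estimate_common_delay(seq, u_dec, dt_id = dt_id, order = order,
                               nb = nb, max_delay = max_delay, refine = refine)
  # multi-start: the common-delay init can trap very short first steps in a
  # local minimum where both instants map onto the second response; a zero
  # init explores the other basin, and the lower residual wins
  ps <- NULL
  for (init in unique(c(com$delta, 0))) {
    cand <- suppressWarnings(
      reconstruct_step_delays(seq, u_dec, dt_id = dt_id, order = order,
                              nb = nb, init = init,
                              max_delay = max_delay, refine = refine))
    if (is.null(ps) || cand$rss < ps$rss) ps <- cand
  }
  if (!ps$converged)
    warning("per-step delay optimization did not converge; returning best found")
  list(rt = ps$delays, delta_common = com$delta, rss = ps$rss,
       converged = ps$converged)
}

#' Reconstruct a whole session into a delay table
#'
#' @param trials list of `trial_record`s (one participant's session).
#' @param participant participant identifier stored in the table.
#' @param ... passed to [reconstruct_trial()].
#' @return Data frame: `participant`, `trial_id`, `pattern`, `pattern_class`,
#'   `isi`, `rt1`, `rt2`, `residual`, `converged` (one row per trial; the
#'   return-to-centre step of unidirectional trials is excluded from the
#'   pair by construction).
#' @export
reconstruct_session <- function(trials, participant = 1L, ...) {
  rows <- lapply(trials, function(tr) {
    sq <- tr$meta$sequence
    rec <- reconstruct_trial(tr, ...)
    data.frame(participant = participant,
               trial_id = if (!is.null(tr$meta$trial_id)) tr$meta$trial_id else NA_integer_,
               pattern = sq$pattern, pattern_class = sq$pattern_class,
               isi = sq$isi, rt1 = rec$rt[1], rt2 = rec$rt[2],
               residual = rec$rss, converged = rec$converged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Label reconstructed step pairs
#'
#' Turns per-trial reconstruction output into labelled (RT1, RT2) pairs; in
#' unidirectional trials only steps 1-2 form the pair (the return-to-centre
#' step is excluded). Trials with a missing step delay are dropped with a
#' message.
#'
#' @param delays data frame as returned by [reconstruct_session()] (possibly
#'   several participants row-bound together).
#' @return The data frame restricted to complete pairs.
#' @export
extract_rt_pairs <- function(delays) {
  ok <- is.finite(delays$rt1) & is.finite(delays$rt2)
  if (any(!ok))
    message("dropping ", sum(!ok), " trial(s) with missing step delays")
  delays[ok, , drop = FALSE]
}
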