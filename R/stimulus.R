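#' Inter-step-interval grid for a system order
#'
#' The eight ISIs used for each system order. The two largest values lie
#' beyond the recovery period and serve as the interference-free baseline.
#'
#' @param order 0, 1 or 2.
#' @return Numeric vector of eight ISIs in seconds.
#' @export
isi_grid <- function(order) {
  switch(as.character(order),
         "0" = c(0.05, 0.10, 0.15, 0.20, 0.25, 0.30, 0.50, 1.00),
         "1" = c(0.10, 0.15, 0.20, 0.25, 0.35, 0.50, 1.00, 2.50),
         "2" = c(0.15, 0.25, 0.35, 0.45, 0.55, 0.65, 1.50, 4.00),
         stop("'order' must be 0, 1 or 2"))
}

#' Approximate-recovery-period range for a system order
#'
#' @param order 0, 1 or 2.
#' @return `c(lo, hi)` in seconds: 1-2 s, 2-3 s, 4-5 s for orders 0/1/2.
#' @export
arp_range <- function(order) {
  switch(as.character(order),
         "0" = c(1, 2), "1" = c(2, 3), "2" = c(4, 5),
         stop("'order' must be 0, 1 or 2"))
}

#' Draw an approximate recovery period
#'
#' Uniform draw within the one-second range specific to the system order.
#' Uses the current RNG state; seed with [set.seed()] for reproducibility.
#'
#' @param order 0, 1 or 2.
#' @return ARP in seconds.
#' @export
sample_arp <- function(order) {
  r <- arp_range(order)
  stats::runif(1, r[1], r[2])
}

STEP_PATTERNS <- c("rev_LR", "rev_RL", "uni_LLc", "uni_RRc")

#' Construct a double- or triple-step target sequence
#'
#' Direction convention: left is negative screen units. The reversed patterns
#' step away from centre and back (`rev_LR`: 0 to -A to 0; `rev_RL`: 0 to +A
#' to 0). The unidirectional patterns step twice in one direction and return
#' to centre one approximate recovery period after the second step
#' (`uni_LLc`: 0 to -A to -2A to 0; `uni_RRc` mirrored).
#'
#' @param pattern one of `"rev_LR"`, `"rev_RL"`, `"uni_LLc"`, `"uni_RRc"`.
#' @param amplitude step amplitude A in screen units (default 1).
#' @param first_step_time onset of the first step, seconds.
#' @param isi inter-step interval (first to second step onset), seconds, > 0.
#' @param arp approximate recovery period, seconds, > 0; places the
#'   return-to-centre step of unidirectional patterns and sets the trial tail.
#' @return An object of class `step_sequence` with `step_times`,
#'   `step_levels` (target level after each step), `pattern`, `pattern_class`
#'   (`"reversed"` or `"unidirectional"`), `amplitude`, `isi`, `arp`,
#'   `first_step_time` and `duration` (trial length implied by ISI + ARP).
#' @export
make_step_sequence <- function(pattern, amplitude = 1, first_step_time = 0.5,
                               isi, arp) {
  if (!is.character(pattern) || length(pattern) != 1 || !(pattern %in% STEP_PATTERNS))
    stop("unknown pattern '", paste(pattern, collapse = ","),
         "'; expected one of ", paste(STEP_PATTERNS, collapse = ", "))
  if (!is.finite(isi) || isi <= 0) stop("'isi' must be > 0")
  if (!is.finite(arp) || arp <= 0) stop("'arp' must be > 0")
  if (!is.finite(amplitude) || amplitude <= 0) stop("'amplitude' must be > 0")
  if (!is.finite(first_step_time) || first_step_time < 0)
    stop("'first_step_time' must be >= 0")
  A <- amplitude
  t1 <- first_step_time
  if (pattern == "rev_LR") {
    times <- c(t1, t1 + isi);            levels <- c(-A, 0)
  } else if (pattern == "rev_RL") {
    times <- c(t1, t1 + isi);            levels <- c(A, 0)
  } else if (pattern == "uni_LLc") {
    times <- c(t1, t1 + isi, t1 + isi + arp); levels <- c(-A, -2 * A, 0)
  } else {
    times <- c(t1, t1 + isi, t1 + isi + arp); levels <- c(A, 2 * A, 0)
  }
  structure(list(pattern = pattern,
                 pattern_class = if (startsWith(pattern, "rev")) "reversed" else "unidirectional",
                 amplitude = A, first_step_time = t1, isi = isi, arp = arp,
                 step_times = times, step_levels = levels,
                 duration = t1 + isi + arp),
            class = "step_sequence")
}

#' @export
print.step_sequence <- function(x, ...) {
  cat(sprintf("<step_sequence> %s (%s), A = %g, ISI = %g s, ARP = %.3g s\n",
              x$pattern, x$pattern_class, x$amplitude, x$isi, x$arp))
  cat("  steps at ", paste(sprintf("%.3f", x$step_times), collapse = ", "),
      " s -> levels ", paste(x$step_levels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Build a randomized session of step-sequence trials
#'
#' Crosses the eight order-specific ISIs with the step patterns, repeats each
#' combination `repetitions` times, draws a fresh ARP per trial, and shuffles
#' the trial order. Uses the current RNG state; seed with [set.seed()].
#'
#' @param order system order (0, 1 or 2): selects the ISI grid and ARP range.
#' @param amplitude step amplitude in screen units.
#' @param repetitions repetitions per ISI x pattern combination (>= 1).
#' @param patterns which patterns to include; defaults to all four.
#' @param first_step_time onset of the first step in every trial.
#' @return A list of [make_step_sequence()] objects with attribute `order`.
#' @examples
#' set.seed(1)
#' length(build_session(0, repetitions = 4))  # 8 ISIs x 4 patterns x 4 = 128
#' @export
build_session <- function(order, amplitude = 1, repetitions = 4,
                          patterns = STEP_PATTERNS, first_step_time = 0.5) {
  if (!(order %in% 0:2)) stop("'order' must be 0, 1 or 2")
  if (!is.numeric(repetitions) || repetitions < 1) stop("'repetitions' must be >= 1")
  patterns <- match.arg(patterns, STEP_PATTERNS, several.ok = TRUE)
  grid <- expand.grid(isi = isi_grid(order), pattern = patterns,
                      rep = seq_len(repetitions), stringsAsFactors = FALSE)
  grid <- grid[sample.int(nrow(grid)), , drop = FALSE]
  trials <- lapply(seq_len(nrow(grid)), function(i) {
    sq <- make_step_sequence(grid$pattern[i], amplitude = amplitude,
                             first_step_time = first_step_time,
                             isi = grid$isi[i], arp = sample_arp(order))
    sq$trial_id <- i
    sq$repetition <- grid$rep[i]
    sq
  })
  attr(trials, "order") <- as.integer(order)
  trials
}

#' Render a step sequence as a sampled target series
#'
#' Piecewise-constant rendering on the simulation grid: the value is 0 before
#' the first step and changes at sample `round(step_time / dt)`.
#'
#' @param seq a [make_step_sequence()] object.
#' @param dt sampling interval in seconds (default 0.001).
#' @param duration series length in seconds; must cover all step times.
#'   Defaults to the sequence's own `duration`.
#' @return Numeric vector `w` of length `round(duration / dt)`.
#' @export
render_target <- function(seq, dt = 0.001, duration = seq$duration) {
  if (!inherits(seq, "step_sequence")) stop("'seq' must be a step_sequence")
  if (duration < max(seq$step_times))
    stop("'duration' (", duration, " s) does not cover the last step at ",
         max(seq$step_times), " s")
  nT <- round(duration / dt)
  w <- numeric(nT)
  idx <- round(seq$step_times / dt) + 1L   # sample holding the new level
  for (k in seq_along(idx)) {
    if (idx[k] <= nT) w[idx[k]:nT] <- seq$step_levels[k]
  }
  w
}

#' Summarize a session as a data frame
#'
#' One row per trial: `trial_id`, `pattern`, `pattern_class`, `isi_s`,
#' `arp_s`, `step_times` and `step_levels` (semicolon-separated), matching
#' the session CSV layout written by [run_experiment()].
#'
#' @param session a [build_session()] result.
#' @return A data frame.
#' @export
session_table <- function(session) {
  do.call(rbind, lapply(session, function(sq) {
    data.frame(trial_id = sq$trial_id, pattern = sq$pattern,
               pattern_class = sq$pattern_class, isi_s = sq$isi,
               arp_s = sq$arp,
               step_times = paste(sprintf("%.6f", sq$step_times), collapse = ";"),
               step_levels = paste(sprintf("%.6f", sq$step_levels), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}
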