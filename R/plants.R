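#' Specify a virtual controlled system
#'
#' Describes one of the virtual systems driven by the joystick signal: a
#' zero-order (pure position) map, a first-order (velocity) integrator, or a
#' second-order (acceleration) system that is either marginally stable (a pure
#' mass) or unstable with divergence time constant `tau` (mimicking the load
#' experienced during quiet standing).
#'
#' @param order integer, 0, 1 or 2: the number of integrations between
#'   joystick and displayed position.
#' @param stability `"not_applicable"` (orders 0 and 1), `"marginally_stable"`
#'   or `"unstable"` (order 2 only).
#' @param tau unstable time constant in seconds (`y'' = y / tau^2 + G u`);
#'   only meaningful when `stability = "unstable"`. Default 0.92 s.
#' @param gain input gain `G` in screen units per joystick unit per s^order.
#' @param display_limit half-width of the display in screen units; exceeding
#'   it can trigger a reset (see [simulate_plant()]).
#' @return An object of class `system_spec`.
#' @examples
#' system_spec(2, "unstable")
#' @export
system_spec <- function(order,
                        stability = if (order == 2) "marginally_stable" else "not_applicable",
                        tau = 0.92, gain = 1, display_limit = 1.5) {
  if (!is.numeric(order) || length(order) != 1 || !(order %in% 0:2))
    stop("'order' must be 0, 1 or 2")
  stability <- match.arg(stability,
                         c("not_applicable", "marginally_stable", "unstable"))
  if (order == 2 && stability == "not_applicable")
    stop("a second-order system must be 'marginally_stable' or 'unstable'")
  if (order != 2 && stability != "not_applicable")
    stop("'stability' only applies to second-order systems (got order ",
         order, ", stability '", stability, "')")
  if (stability == "unstable" && (!is.finite(tau) || tau <= 0))
    stop("'tau' must be a positive time constant (seconds)")
  if (!is.finite(gain) || gain == 0) stop("'gain' must be nonzero and finite")
  if (!is.finite(display_limit) || display_limit <= 0)
    stop("'display_limit' must be positive")
  structure(list(order = as.integer(order), stability = stability,
                 tau = tau, gain = gain, display_limit = display_limit),
            class = "system_spec")
}

#' @export
print.system_spec <- function(x, ...) {
  cat(sprintf("<system_spec> order %d (%s), gain %g, display limit %g\n",
              x$order, x$stability, x$gain, x$display_limit))
  if (x$stability == "unstable")
    cat(sprintf("  unstable time constant tau = %g s (pole at +%.4g 1/s)\n",
                x$tau, 1 / x$tau))
  invisible(x)
}

#' Continuous-time state-space realization of a system specification
#'
#' State coordinates are position (and velocity for order 2); the output is
#' the displayed position. Order 0 is a pure feedthrough `y = G u`.
#'
#' @param spec a [system_spec()].
#' @return A list with matrices `A`, `B`, `C`, `D`, the state dimension `n`
#'   and the originating `spec`, of class `plant`.
#' @export
make_plant <- function(spec) {
  if (!inherits(spec, "system_spec")) stop("'spec' must be a system_spec")
  G <- spec$gain
  if (spec$order == 0) {
    A <- matrix(0, 0, 0); B <- matrix(0, 0, 1)
    C <- matrix(0, 1, 0); D <- matrix(G, 1, 1)
  } else if (spec$order == 1) {
    A <- matrix(0, 1, 1); B <- matrix(G, 1, 1)
    C <- matrix(1, 1, 1); D <- matrix(0, 1, 1)
  } else {
    a21 <- if (spec$stability == "unstable") 1 / spec$tau^2 else 0
    A <- matrix(c(0, a21, 1, 0), 2, 2)   # column-major: [[0,1],[a21,0]]
    B <- matrix(c(0, G), 2, 1)
    C <- matrix(c(1, 0), 1, 2)
    D <- matrix(0, 1, 1)
  }
  structure(list(A = A, B = B, C = C, D = D, n = nrow(A), spec = spec),
            class = "plant")
}

#' Exact zero-order-hold discretization
#'
#' Discretizes a continuous plant at sampling interval `dt` under a
#' zero-order hold on the input, using the augmented matrix exponential
#' `expm([[A, B], [0, 0]] dt)`.
#'
#' @param plant a [make_plant()] result.
#' @param dt sampling interval in seconds (default 0.001, i.e. 1 kHz).
#' @return A list of class `dplant` with `Ad`, `Bd`, `C`, `D`, `dt`, `n`, `spec`.
#' @export
discretize_plant <- function(plant, dt = 0.001) {
  if (!inherits(plant, "plant")) stop("'plant' must come from make_plant()")
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a positive sampling interval in seconds")
  n <- plant$n
  if (n == 0L) {
    Ad <- plant$A; Bd <- plant$B
  } else {
    M <- rbind(cbind(plant$A, plant$B), matrix(0, 1, n + 1))
    E <- as.matrix(Matrix::expm(M * dt))
    if (any(!is.finite(E))) stop("discretization produced non-finite matrices")
    Ad <- E[seq_len(n), seq_len(n), drop = FALSE]
    Bd <- E[seq_len(n), n + 1, drop = FALSE]
  }
  structure(list(Ad = Ad, Bd = Bd, C = plant$C, D = plant$D,
                 dt = dt, n = n, spec = plant$spec),
            class = "dplant")
}

#' Simulate a discrete plant on an input series
#'
#' Propagates the zero-order-hold discretized system sample by sample. When
#' `reset_enabled` is `TRUE` and the output magnitude exceeds
#' `display_limit`, the full state (position, velocity) is zeroed at that
#' sample and the instant is logged, mirroring the experimental rule that an
#' off-screen system is swiftly returned to centre with velocity and
#' acceleration reset.
#'
#' @param dplant a [discretize_plant()] result.
#' @param u input series (joystick units), sampled at `dplant$dt`.
#' @param display_limit screen half-width; defaults to the spec's limit.
#' @param reset_enabled logical; default `FALSE` (trajectories stay analytic).
#' @param x0 initial state (length `dplant$n`), default zero.
#' @return A list with the output series `y` (same length as `u`), the final
#'   state `x`, and `reset_times` (seconds).
#' @export
simulate_plant <- function(dplant, u, display_limit = dplant$spec$display_limit,
                           reset_enabled = FALSE, x0 = numeric(dplant$n)) {
  if (!inherits(dplant, "dplant")) stop("'dplant' must come from discretize_plant()")
  if (length(u) == 0L) stop("input series must be non-empty")
  n <- dplant$n
  if (length(x0) != n) stop("'x0' must have length ", n)
  Ad <- dplant$Ad; Bd <- drop(dplant$Bd); C <- drop(dplant$C); D <- drop(dplant$D)
  nT <- length(u)
  y <- numeric(nT)
  x <- as.numeric(x0)
  reset <- numeric(0)
  for (t in seq_len(nT)) {
    yt <- (if (n > 0) sum(C * x) else 0) + D * u[t]
    if (reset_enabled && abs(yt) > display_limit) {
      x <- numeric(n)
      reset <- c(reset, (t - 1) * dplant$dt)
      yt <- D * u[t]
    }
    y[t] <- yt
    if (n > 0) x <- drop(Ad %*% x) + Bd * u[t]
  }
  list(y = y, x = x, reset_times = reset)
}
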