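#' Fast map nonlinearity
#'
#' Evaluates the piecewise function `f` that advances the membrane potential
#' of the modified Rulkov map. The three branches mimic the upstroke, peak,
#' and reset of an action potential:
#'
#' * `x1 < 0`: `(2500 + 150 x1) / (50 - x1) + 50 x3` (depolarizing branch),
#' * `0 <= x1 < 50 + 50 x3` and `x2 < 0`: `50 + 50 x3` (spike peak),
#' * otherwise: `-50` (reset).
#'
#' Branch comparisons are exact (no tolerance): the map is piecewise-defined
#' and limit-cycle periods rely on the literal branch logic. All arguments are
#' vectorized to a common length.
#'
#' @param x1 Membrane potential at the current step.
#' @param x2 Membrane potential at the previous step.
#' @param x3 Effective drive `kappa * u - a - theta`.
#'
#' @return The next membrane potential value(s).
#' @examples
#' evaluate_f(-50, -50, 0)   # fixed at the saddle-node point: -50
#' evaluate_f(0, -50, -0.1)  # spike peak branch: 45
#' evaluate_f(100, 0, 0)     # reset branch: -50
#' @export
evaluate_f <- function(x1, x2, x3) {
  n <- max(length(x1), length(x2), length(x3))
  x1 <- rep_len(x1, n); x2 <- rep_len(x2, n); x3 <- rep_len(x3, n)
  if (!all(is.finite(x1), is.finite(x2), is.finite(x3))) {
    stop("evaluate_f: all inputs must be finite", call. = FALSE)
  }
  out <- rep.int(-50, n)
  left <- x1 < 0
  mid <- !left & x1 < 50 + 50 * x3 & x2 < 0
  out[left] <- (2500 + 150 * x1[left]) / (50 - x1[left]) + 50 * x3[left]
  out[mid] <- 50 + 50 * x3[mid]
  out
}

#' Spike condition of the modified Rulkov map
#'
#' A neuron spikes at iteration `n` exactly when its membrane potential is
#' about to be reset to -50, i.e. when
#' `v_n >= 0` and (`v_n >= 50 + 50 * drive` or `v_{n-1} >= 0`).
#' The second disjunct means a neuron always spikes if its potential is
#' non-negative for two consecutive iterations, independent of the input.
#'
#' @param v_curr Membrane potential at the current iteration.
#' @param v_prev Membrane potential at the previous iteration.
#' @param drive Effective drive `kappa * u - a - theta` at the current
#'   iteration.
#'
#' @return Logical vector: `TRUE` where the spike condition holds.
#' @examples
#' spike_condition(10, 5, -100)   # TRUE: non-negative twice in a row
#' spike_condition(-10, 100, 0)   # FALSE
#' @export
spike_condition <- function(v_curr, v_prev, drive) {
  v_curr >= 0 & (v_curr >= 50 + 50 * drive | v_prev >= 0)
}

#' Map state constructor
#'
#' State of one modified Rulkov neuron between iterations: the current and
#' previous membrane potential, the adaptation variable, and the spike flag of
#' the most recent completed iteration. The default is the reset point
#' `v = v_prev = -50`, `a = 0`, which is always a valid state.
#'
#' @param v_curr Membrane potential at the current iteration.
#' @param v_prev Membrane potential at the previous iteration (the very first
#'   iteration needs one; it defaults to `v_curr`).
#' @param a Adaptation variable.
#' @param s Spike flag (0 or 1) of the last completed iteration.
#'
#' @return An object of class `map_state`.
#' @export
map_state <- function(v_curr = -50, v_prev = v_curr, a = 0, s = 0L) {
  stopifnot(is.finite(v_curr), is.finite(v_prev), is.finite(a), s %in% c(0L, 1L))
  structure(
    list(v_curr = v_curr, v_prev = v_prev, a = a, s = as.integer(s)),
    class = "map_state"
  )
}

#' Advance the modified Rulkov map by one iteration
#'
#' Performs one step of the coupled fast/slow map. With the state holding
#' `(v_n, v_{n-1}, a_n)` and input `u_n`, the step computes the drive
#' `kappa * u_n - a_n - theta`, the spike flag `s_n` from the current
#' potential pair, then
#' `v_{n+1} = f(v_n, v_{n-1}, drive)` and
#' `a_{n+1} = a_n - epsilon * (a_n + (1 - kappa) * u_n - gamma * s_n)`.
#' The spike flag `s_n` of the iteration just consumed is stored in the
#' returned state: it marks the iteration whose successor is the reset, and it
#' is the flag entering the adaptation update that produced `a_{n+1}`.
#'
#' @param state A [map_state()].
#' @param u_n External (synaptic) input at the current iteration.
#' @param params A [neuron_params()] object.
#'
#' @return The updated `map_state` (with `s` = spike flag of the consumed
#'   iteration).
#' @export
step_neuron <- function(state, u_n, params) {
  stopifnot(inherits(state, "map_state"), inherits(params, "neuron_params"),
            is.finite(u_n))
  drive <- params$kappa * u_n - state$a - params$theta
  s_n <- as.integer(spike_condition(state$v_curr, state$v_prev, drive))
  v_next <- evaluate_f(state$v_curr, state$v_prev, drive)
  a_next <- state$a - params$epsilon *
    (state$a + (1 - params$kappa) * u_n - params$gamma * s_n)
  map_state(v_curr = v_next, v_prev = state$v_curr, a = a_next, s = s_n)
}

#' Simulate a single modified Rulkov neuron
#'
#' Iterates the map over a full stimulus series and records membrane
#' potential, adaptation, spike flags, and the echoed input. One map iteration
#' corresponds to approximately 0.5 ms of time; all bookkeeping here is in
#' iteration units.
#'
#' The returned trace is aligned so that row `n` (iteration `n - 1`,
#' zero-based column `n`) holds `u_n`, `v_n`, `a_n` and the spike flag `s_n`
#' of that same iteration. Whenever `s = 1` at a row, the membrane potential
#' of the following row is exactly -50 (the reset contract).
#'
#' @param params A [neuron_params()] object.
#' @param stimulus Numeric vector of inputs `u_0, ..., u_{T-1}` (a
#'   [make_stimulus()] result or any finite numeric vector).
#' @param init Initial [map_state()]; defaults to the reset point.
#'
#' @return A `map_trace`: a data frame with columns `n` (iteration, from 0),
#'   `u`, `v`, `a`, `s`.
#' @examples
#' p <- neuron_params(1/10, 1/2, 1/2, 1/2)
#' tr <- simulate_neuron(p, make_stimulus("constant", phi = 0.3, length = 200))
#' sum(tr$s)  # persistent spiking since 0.3 > theta
#' @export
simulate_neuron <- function(params, stimulus, init = map_state()) {
  stopifnot(inherits(params, "neuron_params"), inherits(init, "map_state"))
  u <- as.numeric(stimulus)
  T_len <- length(u)
  if (T_len == 0L) stop("simulate_neuron: empty stimulus", call. = FALSE)
  if (!all(is.finite(u))) stop("simulate_neuron: stimulus must be finite", call. = FALSE)

  theta <- params$theta; kappa <- params$kappa
  eps <- params$epsilon; gam <- params$gamma

  v <- numeric(T_len); a <- numeric(T_len); s <- integer(T_len)
  v_curr <- init$v_curr; v_prev <- init$v_prev; a_curr <- init$a

  for (n in seq_len(T_len)) {
    v[n] <- v_curr; a[n] <- a_curr
    drive <- kappa * u[n] - a_curr - theta
    s_n <- if (v_curr >= 0 && (v_curr >= 50 + 50 * drive || v_prev >= 0)) 1L else 0L
    s[n] <- s_n
    v_next <- if (v_curr < 0) {
      (2500 + 150 * v_curr) / (50 - v_curr) + 50 * drive
    } else if (v_curr < 50 + 50 * drive && v_prev < 0) {
      50 + 50 * drive
    } else {
      -50
    }
    a_curr <- a_curr - eps * (a_curr + (1 - kappa) * u[n] - gam * s_n)
    v_prev <- v_curr
    v_curr <- v_next
  }

  structure(
    data.frame(n = seq_len(T_len) - 1L, u = u, v = v, a = a, s = s),
    class = c("map_trace", "data.frame")
  )
}

#' Stimulus generator
#'
#' Builds deterministic input series in iteration units (`n = 0, ...,
#' length - 1`). Available kinds:
#'
#' * `constant`: `phi` everywhere.
#' * `step`: 0, then `phi` for `onset <= n < offset`.
#' * `pulse`: like `step` with `offset = onset + duration`.
#' * `ramp`: 0 before `onset`, linear from 0 to `phi` over `rise` iterations,
#'   then held at `phi` until `offset`, 0 afterwards.
#' * `harmonic`: `phi * cos(omega * pi * n / 1000 + vartheta)`, where `omega`
#'   is the input frequency in Hz under the convention that one iteration is
#'   0.5 ms (so `omega` ranges over \[0, 1000\] up to the Nyquist frequency).
#'
#' @param kind One of `"constant"`, `"step"`, `"pulse"`, `"ramp"`,
#'   `"harmonic"`.
#' @param phi Amplitude.
#' @param length Number of iterations (> 0).
#' @param onset,offset First / one-past-last iteration of the active window
#'   (step, pulse, ramp).
#' @param duration Pulse duration in iterations (pulse only).
#' @param rise Ramp rise time in iterations (ramp only).
#' @param omega Harmonic frequency in Hz (harmonic only).
#' @param vartheta Harmonic phase in \[0, 2 pi) (harmonic only).
#'
#' @return Numeric vector of length `length` (class `stimulus_series`).
#' @examples
#' make_stimulus("constant", phi = 0.3, length = 10)
#' make_stimulus("harmonic", phi = 1/5, omega = 1, length = 4000)[1:5]
#' @export
make_stimulus <- function(kind, phi = 1, length,
                          onset = 0L, offset = length, duration = NULL,
                          rise = 1L, omega = NULL, vartheta = 0) {
  if (length <= 0) stop("make_stimulus: length must be positive", call. = FALSE)
  n <- seq_len(length) - 1L
  u <- switch(
    kind,
    constant = rep.int(phi, length),
    step = ifelse(n >= onset & n < offset, phi, 0),
    pulse = {
      if (is.null(duration)) stop("pulse stimulus needs 'duration'", call. = FALSE)
      ifelse(n >= onset & n < onset + duration, phi, 0)
    },
    ramp = {
      up <- pmin(pmax((n - onset + 1) / rise, 0), 1)
      ifelse(n < offset, phi * up, 0)
    },
    harmonic = {
      if (is.null(omega)) stop("harmonic stimulus needs 'omega'", call. = FALSE)
      if (omega < 0) stop("harmonic stimulus needs omega >= 0", call. = FALSE)
      phi * cos(omega * pi * n / 1000 + vartheta)
    },
    stop(sprintf("unknown stimulus kind '%s'", kind), call. = FALSE)
  )
  structure(u, class = c("stimulus_series", "numeric"))
}

#' Continuous-time stimulus function
#'
#' Returns the continuous-time counterpart `u(t)` of [make_stimulus()] for
#' driving the rate-reduced model, with `t` in iteration units so that the
#' harmonic case `phi * cos(omega * pi * t / 1000 + vartheta)` matches the
#' discrete series exactly at integer `t`.
#'
#' @inheritParams make_stimulus
#' @return A vectorized function of time `t`.
#' @export
stimulus_function <- function(kind, phi = 1, onset = 0, offset = Inf,
                              duration = NULL, rise = 1, omega = NULL,
                              vartheta = 0) {
  switch(
    kind,
    constant = function(t) rep.int(phi, length(t)),
    step = function(t) ifelse(t >= onset & t < offset, phi, 0),
    pulse = {
      if (is.null(duration)) stop("pulse stimulus needs 'duration'", call. = FALSE)
      function(t) ifelse(t >= onset & t < onset + duration, phi, 0)
    },
    ramp = function(t) {
      up <- pmin(pmax((t - onset + 1) / rise, 0), 1)
      ifelse(t < offset, phi * up, 0)
    },
    harmonic = {
      if (is.null(omega)) stop("harmonic stimulus needs 'omega'", call. = FALSE)
      function(t) phi * cos(omega * pi * t / 1000 + vartheta)
    },
    stop(sprintf("unknown stimulus kind '%s'", kind), call. = FALSE)
  )
}
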