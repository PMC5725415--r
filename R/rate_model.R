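#' Right-hand side of the rate-reduced adaptation equation
#'
#' The rate reduction replaces the binary spike variable of the map by the
#' instantaneous firing rate of the fast subsystem, giving the scalar ODE
#' `da/dt = epsilon * (-a - (1 - kappa) * u + gamma * S(kappa * u - a -
#' theta))`, with time measured in map-iteration units (one unit is about
#' 0.5 ms).
#'
#' @param a Adaptation value.
#' @param u Input value.
#' @param params A [neuron_params()] object.
#' @param S Firing-rate function mapping drive to \[0, 1/3\] (e.g.
#'   [staircase_fun()] or [table1_rate_function()]).
#'
#' @return `da/dt`.
#' @export
rate_rhs <- function(a, u, params, S) {
  params$epsilon * (-a - (1 - params$kappa) * u +
                      params$gamma * S(params$kappa * u - a - params$theta))
}

#' Integrate the rate-reduced neuron model
#'
#' Integrates the adaptation ODE with the classical fixed-step 4th-order
#' Runge-Kutta scheme (via [deSolve::rk4()]). A fixed step is used
#' deliberately: the staircase firing-rate function makes the right-hand side
#' discontinuous, and adaptive error control would chatter at the jumps; step
#' sensitivity should be assessed by halving `dt` instead.
#'
#' @param params A [neuron_params()] object.
#' @param input_fn Function of time returning the input `u(t)` (see
#'   [stimulus_function()]).
#' @param S Firing-rate function (drive to \[0, 1/3\]).
#' @param t_end End time in iteration units (> 0).
#' @param dt Time step (> 0), default 0.1.
#' @param a0 Initial adaptation value.
#'
#' @return A `rate_trace`: data frame with columns `t`, `u`, `a`, `r`
#'   (effective drive `kappa * u - a - theta`), and `rate` (`S(r)`).
#' @examples
#' sc <- rate_staircase(50)
#' p <- neuron_params(1/10, 1, 1/20, 1)
#' tr <- integrate_rate(p, function(t) rep(0.3, length(t)), staircase_fun(sc),
#'                      t_end = 200, dt = 0.1)
#' tail(tr$rate, 1)  # positive steady-state rate since 0.3 > theta
#' @export
integrate_rate <- function(params, input_fn, S, t_end, dt = 0.1, a0 = 0) {
  stopifnot(inherits(params, "neuron_params"), is.function(input_fn),
            is.function(S))
  if (dt <= 0) stop("integrate_rate: dt must be positive", call. = FALSE)
  if (t_end <= 0) stop("integrate_rate: t_end must be positive", call. = FALSE)

  times <- seq(0, t_end, by = dt)
  eps <- params$epsilon; kappa <- params$kappa
  gam <- params$gamma; theta <- params$theta
  rhs <- function(t, y, parms) {
    u <- input_fn(t)
    list(eps * (-y[1] - (1 - kappa) * u + gam * S(kappa * u - y[1] - theta)))
  }
  sol <- deSolve::rk4(y = c(a = a0), times = times, func = rhs, parms = NULL)
  a <- as.numeric(sol[, "a"])
  u <- input_fn(times)
  r <- kappa * u - a - theta
  structure(
    data.frame(t = times, u = u, a = a, r = r, rate = S(r)),
    class = c("rate_trace", "data.frame")
  )
}

#' Per-period integral of the firing rate
#'
#' Trapezoidal integral of the rate trace over exactly one forcing period
#' taken at the end of the trace (steady state), the discrete analogue of a
#' spikes-per-period count in the full map model.
#'
#' @param trace A `rate_trace` from [integrate_rate()].
#' @param period Forcing period in the trace's time units.
#'
#' @return The integral of `rate` over the final full period.
#' @export
periodic_rate_integral <- function(trace, period) {
  stopifnot(inherits(trace, "rate_trace"), period > 0)
  t <- trace$t
  t_end <- t[length(t)]
  if (t_end - t[1] < period) {
    stop("periodic_rate_integral: trace shorter than one period", call. = FALSE)
  }
  sel <- t >= t_end - period
  pracma::trapz(t[sel], trace$rate[sel])
}
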