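# Error function via the normal CDF (exact relation, no extra dependency).
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# Package a complex frequency-response value with modulus and phase
# (phase convention: principal argument in (-pi, pi]).
response_value <- function(z) {
  structure(
    list(value = z, modulus = Mod(z), phase = Arg(z)),
    class = "response_value"
  )
}

#' @export
print.response_value <- function(x, ...) {
  cat(sprintf("<response_value> %g%+gi  |.| = %g  arg = %g\n",
              Re(x$value), Im(x$value), x$modulus, x$phase))
  invisible(x)
}

#' Subthreshold frequency response of the map
#'
#' In the subthreshold (non-spiking) regime the map's adaptation equation is
#' linear, and under harmonic input `u_n = phi * cos(omega * pi * n / 1000 +
#' vartheta)` the steady-state effective drive is `kappa * u_n - a_n =
#' |F(omega)| * phi * cos(omega * pi * n / 1000 + vartheta + arg F(omega))`
#' with the complex frequency response
#' `F(omega) = kappa + epsilon * (1 - kappa) /
#'   (exp(i * omega * pi / 1000) + epsilon - 1)`.
#' `omega` is a continuous frequency parameter in Hz, valid on \[0, 1000\]
#' (the Nyquist frequency of the 0.5 ms iteration step). `F(0) = 1` and
#' `F(1000) = (2 * kappa - epsilon) / (2 - epsilon)`; the modulus is strictly
#' decreasing in `omega` exactly when `kappa` lies in `(-1 + epsilon, 1)`
#' (low-pass behavior) and increasing otherwise (high-pass).
#'
#' @param omega Frequency in Hz, in \[0, 1000\].
#' @param kappa Input partition parameter.
#' @param epsilon Adaptation time scale in (0, 1).
#'
#' @return A `response_value`: list with `value` (complex), `modulus`,
#'   `phase`.
#' @examples
#' map_response(0, kappa = 1/10, epsilon = 1/200)$value  # 1
#' @export
map_response <- function(omega, kappa, epsilon) {
  stopifnot(length(omega) == 1L, is.finite(omega))
  if (omega < 0 || omega > 1000) {
    stop("map_response: omega must lie in [0, 1000] Hz", call. = FALSE)
  }
  if (epsilon <= 0 || epsilon >= 1) {
    stop("map_response: epsilon must lie in (0, 1)", call. = FALSE)
  }
  z <- kappa + epsilon * (1 - kappa) /
    (exp(1i * omega * pi / 1000) + epsilon - 1)
  response_value(z)
}

#' Closed-form modulus of the map frequency response
#'
#' Direct evaluation of
#' `|F(omega)| = sqrt((epsilon^2 + 2 * kappa * (kappa - epsilon) * (1 - cos(omega * pi / 1000))) /
#'               (epsilon^2 + 2 * (1 - epsilon) * (1 - cos(omega * pi / 1000))))`,
#' an independent route to `Mod(map_response(...)$value)`.
#'
#' @inheritParams map_response
#' @return Modulus value(s); vectorized in `omega`.
#' @export
map_response_modulus <- function(omega, kappa, epsilon) {
  cc <- 1 - cos(omega * pi / 1000)
  sqrt((epsilon^2 + 2 * kappa * (kappa - epsilon) * cc) /
         (epsilon^2 + 2 * (1 - epsilon) * cc))
}

#' Frequency response of the rate-reduced model
#'
#' Continuous-time analogue of [map_response()]: under harmonic input the
#' subthreshold drive of the rate model is `|G(omega)| * phi * cos(...)` with
#' `G(omega) = kappa + epsilon * (1 - kappa) / (epsilon + i * omega * pi /
#' 1000)`. Valid for all `omega >= 0`; `G(0) = 1`, and the modulus is
#' strictly decreasing in `omega` exactly when `|kappa| < 1`.
#'
#' @param omega Frequency in Hz (`>= 0`).
#' @inheritParams map_response
#' @return A `response_value`.
#' @export
rate_response <- function(omega, kappa, epsilon) {
  stopifnot(length(omega) == 1L, is.finite(omega))
  if (omega < 0) stop("rate_response: omega must be >= 0", call. = FALSE)
  if (epsilon <= 0 || epsilon >= 1) {
    stop("rate_response: epsilon must lie in (0, 1)", call. = FALSE)
  }
  z <- kappa + epsilon * (1 - kappa) / (epsilon + 1i * omega * pi / 1000)
  response_value(z)
}

#' Closed-form modulus of the rate-model frequency response
#'
#' Direct evaluation of
#' `|G(omega)| = sqrt((epsilon^2 + kappa^2 * (pi * omega / 1000)^2) /
#'                    (epsilon^2 + (pi * omega / 1000)^2))`.
#'
#' @inheritParams rate_response
#' @return Modulus value(s); vectorized in `omega`.
#' @examples
#' # low-pass configuration: passes 1 Hz, blocks 2 Hz at threshold 1/7
#' rate_response_modulus(c(1, 2), kappa = 1/10, epsilon = 1/200) * (1/5)
#' @export
rate_response_modulus <- function(omega, kappa, epsilon) {
  x2 <- (pi * omega / 1000)^2
  sqrt((epsilon^2 + kappa^2 * x2) / (epsilon^2 + x2))
}

#' Sufficient quiescence condition for the map under harmonic input
#'
#' A map neuron receiving harmonic input of amplitude `phi` and frequency
#' `omega` never spikes if `|F(omega)| * phi <= theta`. The condition is
#' sufficient but not necessary: because the membrane potential needs a few
#' iterations to converge to its periodic orbit, the drive may exceed the
#' threshold briefly without eliciting a spike.
#'
#' @param omega Frequency in Hz, in \[0, 1000\].
#' @param phi Input amplitude.
#' @param params A [neuron_params()] object.
#'
#' @return `TRUE` if the no-spiking condition holds.
#' @export
quiescent_map <- function(omega, phi, params) {
  stopifnot(inherits(params, "neuron_params"))
  map_response_modulus(omega, params$kappa, params$epsilon) * phi <= params$theta
}

#' Exact quiescence condition for the rate model under harmonic input
#'
#' For the rate-reduced model the condition is an equivalence: the firing
#' rate is identically zero under harmonic input of amplitude `phi` and
#' frequency `omega` if and only if `|G(omega)| * phi <= theta`.
#'
#' @inheritParams quiescent_map
#' @return `TRUE` iff the steady-state firing rate is identically zero.
#' @export
quiescent_rate <- function(omega, phi, params) {
  stopifnot(inherits(params, "neuron_params"))
  rate_response_modulus(omega, params$kappa, params$epsilon) * phi <= params$theta
}

#' Closed-form subthreshold adaptation of the map
#'
#' In the subthreshold regime the adaptation recursion is linear with
#' explicit solution
#' `a_n = -epsilon * (1 - kappa) * sum_{m >= 1} (1 - epsilon)^{m-1} *
#' u_{n-m}`, the stimulus being extended by zeros before its first sample.
#' The sum is truncated once the geometric tail bound `(1 - epsilon)^M`
#' falls below `tol` (relative to the weight scale), which caps the absolute
#' truncation error at `tol * |1 - kappa| * max |u|`.
#'
#' This closed form is evaluated directly as a weighted sum (not by running
#' the recursion), so it serves as an independent oracle for the simulated
#' adaptation variable.
#'
#' @param stimulus Numeric vector `u_0, ..., u_{T-1}`.
#' @param params A [neuron_params()] object.
#' @param n Iteration index (0-based, may be a vector) at which to evaluate
#'   `a_n`.
#' @param tol Geometric tail tolerance (default `1e-12`).
#'
#' @return `a_n` value(s).
#' @export
adaptation_closed_form <- function(stimulus, params, n, tol = 1e-12) {
  stopifnot(inherits(params, "neuron_params"))
  u <- as.numeric(stimulus)
  eps <- params$epsilon; kappa <- params$kappa
  M_max <- ceiling(log(tol) / log(1 - eps))
  vapply(n, function(nn) {
    if (nn <= 0) return(0)
    M <- min(nn, M_max)
    m <- seq_len(M)
    # u_{n-m}: stimulus index nn - m (0-based) -> R index nn - m + 1
    -eps * (1 - kappa) * sum((1 - eps)^(m - 1) * u[nn - m + 1])
  }, numeric(1))
}
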