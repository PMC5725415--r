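#' Neuron parameter set
#'
#' Bundles the four intrinsic parameters of the modified Rulkov neuron (and of
#' its rate reduction): the spiking threshold `theta`, the fast/slow input
#' partition `kappa`, the adaptation time scale `epsilon`, and the adaptation
#' strength `gamma`.
#'
#' For constant external input `u = phi` the neuron spikes persistently if and
#' only if `phi > theta`. `kappa` sets the fraction of the input applied to the
#' fast (membrane potential) subsystem; values above 1 produce postinhibitory
#' rebound, `kappa = 0` produces long first-spike latencies, and negative
#' values reverse the transient response so that inhibition can induce
#' spiking. `epsilon` must lie strictly inside (0, 1); small values give a
#' large time-scale separation between membrane potential and adaptation.
#'
#' @param theta Spiking threshold (finite real).
#' @param kappa Input partition parameter (finite real, may be negative).
#' @param epsilon Adaptation time scale, strictly in (0, 1).
#' @param gamma Adaptation strength (finite real).
#'
#' @return An object of class `neuron_params` (a named list).
#' @examples
#' neuron_params(theta = 1/10, kappa = 1/2, epsilon = 1/2, gamma = 1/2)
#' @export
neuron_params <- function(theta, kappa, epsilon, gamma) {
  for (nm in c("theta", "kappa", "epsilon", "gamma")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    }
  }
  if (epsilon <= 0 || epsilon >= 1) {
    stop("'epsilon' must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(
    list(theta = theta, kappa = kappa, epsilon = epsilon, gamma = gamma),
    class = "neuron_params"
  )
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf(
    "<neuron_params> theta = %g, kappa = %g, epsilon = %g, gamma = %g\n",
    x$theta, x$kappa, x$epsilon, x$gamma
  ))
  invisible(x)
}

# Coerce a plain list (e.g. parsed from JSON/YAML) to neuron_params.
as_neuron_params <- function(x) {
  if (inherits(x, "neuron_params")) return(x)
  neuron_params(x$theta, x$kappa, x$epsilon, x$gamma)
}
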