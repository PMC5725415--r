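#' Spiking-network configuration
#'
#' Describes an all-to-all network of modified Rulkov neurons split into two
#' subpopulations placed equidistantly on \[-1, 1\] (both subpopulations
#' share the same position layout, endpoints included). Each subpopulation
#' has its own intrinsic parameters and synaptic decay rate `alpha`;
#' connection strengths follow the exponential distance rule
#' `c_ij = eta[p_i, p_j] * exp(-mu[p_i, p_j] * |x_i - x_j|)`. Gaussian
#' threshold noise of variance `sigma2` is redrawn independently per neuron
#' and per iteration. Self-connections are kept (the coupling is genuinely
#' all-to-all).
#'
#' With `n_per_pop` neurons on the length-2 domain, the implied density is
#' `n_per_pop / 2` per unit length; `rho_expected` (if given) is asserted
#' against it, which ties a network to the matching field configuration.
#'
#' @param pop1,pop2 Named lists with `alpha`, `theta`, `kappa`, `epsilon`,
#'   `gamma`.
#' @param n_per_pop Neurons per subpopulation (single count, used for both).
#' @param eta,mu 2x2 coupling matrices as in [field_config()].
#' @param sigma2 Threshold-noise variance (>= 0).
#' @param rho_expected Optional density to assert `n_per_pop / 2` against.
#'
#' @return An object of class `network_config`.
#' @export
network_config <- function(pop1, pop2, n_per_pop, eta, mu, sigma2 = 0,
                           rho_expected = NULL) {
  check_pop <- function(p, nm) {
    need <- c("alpha", "theta", "kappa", "epsilon", "gamma")
    miss <- setdiff(need, names(p))
    if (length(miss)) {
      stop(sprintf("network_config: %s is missing fields: %s", nm,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    if (p$alpha <= 0 || p$alpha > 1) {
      stop(sprintf("%s: alpha must lie in (0, 1]", nm), call. = FALSE)
    }
    if (p$epsilon <= 0 || p$epsilon >= 1) {
      stop(sprintf("%s: epsilon must lie in (0, 1)", nm), call. = FALSE)
    }
    p[need]
  }
  stopifnot(n_per_pop >= 1, sigma2 >= 0,
            is.matrix(eta), all(dim(eta) == c(2, 2)),
            is.matrix(mu), all(dim(mu) == c(2, 2)), all(mu >= 0))
  if (!is.null(rho_expected) &&
      abs(n_per_pop / 2 - rho_expected) > 1e-9) {
    stop(sprintf(
      "network_config: %d neurons per population on [-1, 1] give density %g, not the expected rho = %g",
      n_per_pop, n_per_pop / 2, rho_expected), call. = FALSE)
  }
  positions <- seq(-1, 1, length.out = n_per_pop)
  structure(
    list(pop = list(check_pop(pop1, "pop1"), check_pop(pop2, "pop2")),
         n_per_pop = as.integer(n_per_pop),
         positions = c(positions, positions),
         labels = rep(1:2, each = n_per_pop),
         eta = eta, mu = mu, sigma2 = sigma2),
    class = "network_config"
  )
}

#' Network matched to the packaged field configuration
#'
#' Builds the spiking network corresponding to [table1_field_config()]:
#' two subpopulations (excitatory and inhibitory) of `n_per_pop` neurons
#' each, all-to-all coupled with the same `eta` and `mu`, with threshold
#' noise `sigma2 = 1/4` by default. With the default 300 neurons per
#' subpopulation the density is 150 per unit length, matching the field's
#' `rho`.
#'
#' @param n_per_pop Neurons per subpopulation (default 300).
#' @param sigma2 Threshold-noise variance (default 1/4).
#' @param check_density If `TRUE` (default), assert that the implied density
#'   equals the field configuration's `rho = 150`.
#'
#' @return A [network_config()].
#' @export
table1_network_config <- function(n_per_pop = 300, sigma2 = 1/4,
                                  check_density = n_per_pop == 300) {
  fc <- table1_field_config()
  network_config(
    pop1 = c(list(alpha = fc$pop[[1]]$alpha), fc$pop[[1]][c("theta", "kappa", "epsilon", "gamma")]),
    pop2 = c(list(alpha = fc$pop[[2]]$alpha), fc$pop[[2]][c("theta", "kappa", "epsilon", "gamma")]),
    n_per_pop = n_per_pop,
    eta = fc$eta, mu = fc$mu, sigma2 = sigma2,
    rho_expected = if (check_density) fc$pop[[1]]$rho else NULL
  )
}

#' Distance-dependent connection matrix
#'
#' Assembles the N x N matrix `c_ij = eta[p_i, p_j] * exp(-mu[p_i, p_j] *
#' |x_i - x_j|)` (source neuron `j`, target neuron `i`). Within-subpopulation
#' blocks are symmetric; signs follow `eta`.
#'
#' @param config A [network_config()].
#' @return An N x N numeric matrix.
#' @export
build_connectivity <- function(config) {
  stopifnot(inherits(config, "network_config"))
  x <- config$positions; p <- config$labels
  dist <- abs(outer(x, x, "-"))
  eta_ij <- config$eta[cbind(rep(p, times = length(p)), rep(p, each = length(p)))]
  mu_ij <- config$mu[cbind(rep(p, times = length(p)), rep(p, each = length(p)))]
  matrix(eta_ij * exp(-mu_ij * dist), length(x), length(x))
}

# One synchronous network iteration. All spikes are evaluated from the
# pre-update state, then synapses, then the (v, a) maps.
# xi: per-neuron threshold-noise draws for this iteration.
network_step_core <- function(v, v_prev, a, u, xi, C, par) {
  drive <- par$kappa * u - a - (par$theta + xi)
  s <- as.numeric(spike_condition(v, v_prev, drive))
  u_next <- (1 - par$alpha) * u + par$alpha * as.numeric(C %*% s)
  v_next <- evaluate_f(v, v_prev, drive)
  a_next <- a - par$epsilon * (a + (1 - par$kappa) * u - par$gamma * s)
  list(v = v_next, v_prev = v, a = a_next, u = u_next, s = as.integer(s))
}

# Expand per-population parameters to per-neuron vectors.
network_par_vectors <- function(config) {
  p <- config$labels
  pick <- function(field) {
    vapply(config$pop, `[[`, numeric(1), field)[p]
  }
  list(theta = pick("theta"), kappa = pick("kappa"), epsilon = pick("epsilon"),
       gamma = pick("gamma"), alpha = pick("alpha"))
}

#' Advance the spiking network by one iteration
#'
#' Synchronous update: (i) spike flags are computed from the current
#' potentials and the per-neuron noisy threshold `theta + xi`,
#' `xi ~ N(0, sigma2)`; (ii) synaptic inputs follow the exponential-synapse
#' recursion `u_{n+1} = (1 - alpha) u_n + alpha * C s_n`; (iii) each
#' neuron's `(v, a)` advances by the single-neuron map using the same noisy
#' drive.
#'
#' @param state Named list with numeric vectors `v`, `v_prev`, `a`, `u` (one
#'   entry per neuron).
#' @param config A [network_config()].
#' @param C Connection matrix from [build_connectivity()] (computed if
#'   missing).
#'
#' @return Updated state list, with `s` holding the spike flags of the
#'   consumed iteration. Uses the current R random-number state for the
#'   threshold noise; seed externally for reproducibility.
#' @export
step_network <- function(state, config, C = build_connectivity(config)) {
  stopifnot(inherits(config, "network_config"))
  N <- length(state$v)
  par <- network_par_vectors(config)
  xi <- if (config$sigma2 > 0) stats::rnorm(N, 0, sqrt(config$sigma2)) else numeric(N)
  network_step_core(state$v, state$v_prev, state$a, state$u, xi, C, par)
}

#' Simulate the all-to-all spiking network
#'
#' Runs the coupled map network for `t_end` iterations from the default
#' initial state `v = v_prev = -50`, `a = 0`, `u = 0` (overridable), with
#' threshold noise redrawn every iteration. Deterministic given `seed`.
#'
#' @param config A [network_config()].
#' @param t_end Number of iterations.
#' @param seed Integer seed for the threshold noise (default 1).
#' @param init Optional named list of initial vectors `v`, `v_prev`, `a`,
#'   `u`.
#'
#' @return A list of class `network_result`: `raster` (data frame with
#'   columns `iteration` (0-based), `neuron` (1-based index)), `counts`
#'   (iterations x 2 matrix of per-population spike counts per iteration),
#'   `config`, `seed`, `t_end`, and the final `state`.
#' @export
simulate_network <- function(config, t_end, seed = 1, init = NULL) {
  stopifnot(inherits(config, "network_config"), t_end >= 1)
  N <- 2L * config$n_per_pop
  C <- build_connectivity(config)
  par <- network_par_vectors(config)
  sigma <- sqrt(config$sigma2)

  v <- rep.int(-50, N); v_prev <- rep.int(-50, N)
  a <- numeric(N); u <- numeric(N)
  if (!is.null(init)) {
    for (nm in intersect(names(init), c("v", "v_prev", "a", "u"))) {
      assign(nm, rep_len(init[[nm]], N))
    }
  }

  set.seed(seed)
  spike_it <- vector("list", t_end)
  counts <- matrix(0L, t_end, 2L)
  pop1 <- config$labels == 1L

  for (n in seq_len(t_end)) {
    xi <- if (sigma > 0) stats::rnorm(N, 0, sigma) else numeric(N)
    st <- network_step_core(v, v_prev, a, u, xi, C, par)
    fired <- which(st$s == 1L)
    if (length(fired)) {
      spike_it[[n]] <- cbind(n - 1L, fired)
      counts[n, 1L] <- sum(st$s[pop1])
      counts[n, 2L] <- sum(st$s) - counts[n, 1L]
    }
    v <- st$v; v_prev <- st$v_prev; a <- st$a; u <- st$u
  }

  ev <- do.call(rbind, spike_it)
  raster <- if (is.null(ev)) {
    data.frame(iteration = integer(0), neuron = integer(0))
  } else {
    data.frame(iteration = as.integer(ev[, 1]), neuron = as.integer(ev[, 2]))
  }
  structure(
    list(raster = raster, counts = counts, config = config, seed = seed,
         t_end = as.integer(t_end),
         state = list(v = v, v_prev = v_prev, a = a, u = u)),
    class = "network_result"
  )
}

#' Bin a spike raster into a space-time rate matrix
#'
#' Converts per-neuron spike events of one subpopulation into a matrix of
#' firing rates with rows = time bins and columns = spatial bins (same shape
#' convention as a `field_trace` rate matrix). Counts are normalized by
#' neurons-per-spatial-bin times bin duration, so a neuron spiking once per
#' iteration would register rate 1.
#'
#' @param result A `network_result` from [simulate_network()].
#' @param bin_width Temporal bin width in iterations (>= 1).
#' @param spatial_bins Number of equal-width spatial bins over \[-1, 1\].
#' @param population Which subpopulation to bin (1 or 2).
#'
#' @return Matrix of rates (time bins x spatial bins), with attributes
#'   `time_edges`, `space_edges`, `neurons_per_bin`.
#' @export
raster_to_rate <- function(result, bin_width, spatial_bins, population = 1L) {
  stopifnot(inherits(result, "network_result"), bin_width >= 1,
            spatial_bins >= 1, population %in% 1:2)
  config <- result$config
  keep <- config$labels[result$raster$neuron] == population
  ev <- result$raster[keep, , drop = FALSE]
  n_tbin <- ceiling(result$t_end / bin_width)
  t_edges <- seq(0, n_tbin * bin_width, by = bin_width)
  x_edges <- seq(-1, 1, length.out = spatial_bins + 1L)

  pos <- config$positions[ev$neuron]
  tb <- pmin(ev$iteration %/% bin_width + 1L, n_tbin)
  xb <- pmin(findInterval(pos, x_edges, rightmost.closed = TRUE), spatial_bins)

  counts <- matrix(0, n_tbin, spatial_bins)
  if (nrow(ev)) {
    tab <- table(factor(tb, levels = seq_len(n_tbin)),
                 factor(xb, levels = seq_len(spatial_bins)))
    counts <- matrix(as.numeric(tab), n_tbin, spatial_bins)
  }

  pop_pos <- config$positions[config$labels == population]
  npb <- as.numeric(table(factor(
    pmin(findInterval(pop_pos, x_edges, rightmost.closed = TRUE), spatial_bins),
    levels = seq_len(spatial_bins))))
  denom <- outer(rep(bin_width, n_tbin), npb)
  rate <- counts / ifelse(denom > 0, denom, NA_real_)
  attr(rate, "time_edges") <- t_edges
  attr(rate, "space_edges") <- x_edges
  attr(rate, "neurons_per_bin") <- npb
  rate
}
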