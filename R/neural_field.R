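#' Exponential connectivity kernel
#'
#' Isotropic connection strength from position `x_prime` (population `j`) to
#' position `x` (population `i`):
#' `J(x, x') = rho * eta * exp(-mu * |x - x'|)`, where `rho` is the density
#' of the source population, `eta` the maximal connection strength (sign
#' encodes excitation/inhibition), and `mu` the spatial decay rate.
#'
#' @param x,x_prime Positions in \[-1, 1\] (vectorized).
#' @param rho Source-population density per unit length (> 0).
#' @param eta Maximal connection strength.
#' @param mu Spatial decay rate (> 0).
#'
#' @return Kernel value(s).
#' @examples
#' connectivity_kernel(0, 0, rho = 150, eta = 2/3, mu = 4)  # 100
#' @export
connectivity_kernel <- function(x, x_prime, rho, eta, mu) {
  stopifnot(rho > 0, mu >= 0)
  rho * eta * exp(-mu * abs(x - x_prime))
}

#' Assemble quadrature-weighted coupling matrices
#'
#' Discretizes the four connectivity integrals of the two-population field on
#' a uniform grid over \[-1, 1\] by trapezoidal quadrature: entry `(p, q)` of
#' matrix `W[[i]][[j]]` is `J_ij(x_p, x_q) * w_q` with trapezoid weights
#' `w`, so that `W %*% S_j(r_j)` approximates
#' `integral J_ij(x, x') S_j(r_j(x')) dx'` to O(1/M^2). The kernel's kink on
#' the diagonal `x = x'` falls on grid nodes, which preserves the trapezoid
#' order.
#'
#' @param grid Uniform grid of `M >= 3` points spanning \[-1, 1\] (including
#'   endpoints).
#' @param eta 2x2 matrix of maximal connection strengths `eta_ij`.
#' @param mu 2x2 matrix of spatial decay rates `mu_ij` (> 0).
#' @param rho Length-2 vector of population densities.
#'
#' @return Nested list `W[[i]][[j]]` of four M x M matrices.
#' @export
assemble_weights <- function(grid, eta, mu, rho) {
  M <- length(grid)
  if (M < 3) stop("assemble_weights: need at least 3 grid points", call. = FALSE)
  stopifnot(is.matrix(eta), all(dim(eta) == c(2, 2)),
            is.matrix(mu), all(dim(mu) == c(2, 2)), all(mu > 0),
            length(rho) == 2, all(rho > 0))
  h <- diff(grid)
  if (max(abs(h - h[1])) > 1e-12 * abs(h[1])) {
    stop("assemble_weights: grid must be uniform", call. = FALSE)
  }
  w <- rep(h[1], M); w[c(1, M)] <- h[1] / 2
  dist <- abs(outer(grid, grid, "-"))
  lapply(1:2, function(i) lapply(1:2, function(j) {
    (rho[j] * eta[i, j] * exp(-mu[i, j] * dist)) * rep(w, each = M)
  }))
}

#' Two-population neural-field configuration
#'
#' Bundles the parameters of the augmented two-population neural field on the
#' domain (-1, 1): per population a synaptic decay rate `alpha`, the neuron
#' parameters `theta`, `kappa`, `epsilon`, `gamma`, a density `rho`, and a
#' firing-rate function `S`; plus the 2x2 coupling matrices `eta`
#' (strengths; negative entries are inhibitory) and `mu` (spatial decay
#' rates).
#'
#' @param pop1,pop2 Named lists with entries `alpha`, `theta`, `kappa`,
#'   `epsilon`, `gamma`, `rho`.
#' @param eta,mu 2x2 coupling matrices (`eta[i, j]`, `mu[i, j]` couple
#'   population `j` into population `i`).
#' @param S1,S2 Firing-rate functions for the two populations; default the
#'   packaged two-term erf approximation ([table1_rate_function()]).
#'
#' @return An object of class `field_config`.
#' @export
field_config <- function(pop1, pop2, eta, mu,
                         S1 = table1_rate_function(),
                         S2 = table1_rate_function()) {
  check_pop <- function(p, nm) {
    need <- c("alpha", "theta", "kappa", "epsilon", "gamma", "rho")
    miss <- setdiff(need, names(p))
    if (length(miss)) {
      stop(sprintf("field_config: %s is missing fields: %s", nm,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    if (p$alpha <= 0) stop(sprintf("%s: alpha must be > 0", nm), call. = FALSE)
    if (p$rho <= 0) stop(sprintf("%s: rho must be > 0", nm), call. = FALSE)
    if (p$epsilon <= 0 || p$epsilon >= 1) {
      stop(sprintf("%s: epsilon must lie in (0, 1)", nm), call. = FALSE)
    }
    p[need]
  }
  stopifnot(is.matrix(eta), all(dim(eta) == c(2, 2)),
            is.matrix(mu), all(dim(mu) == c(2, 2)), all(mu > 0))
  structure(
    list(pop = list(check_pop(pop1, "pop1"), check_pop(pop2, "pop2")),
         eta = eta, mu = mu, S = list(S1, S2)),
    class = "field_config"
  )
}

#' Packaged excitatory/inhibitory field configuration
#'
#' The showcase parameter set for the two-population field: an excitatory
#' population with rebound-type dynamics (`kappa = 2`, slow adaptation) and
#' an inhibitory population with low-pass dynamics, mutually coupled through
#' exponential kernels. Entries `eta[i, 2]` are negative (population 2
#' inhibits).
#'
#' Population 1: `alpha = 1/20`, `theta = 1/2`, `kappa = 2`,
#' `epsilon = 1/1000`, `gamma = 5`, `rho = 150`.
#' Population 2: `alpha = 1/10`, `theta = 4/5`, `kappa = 1/10`,
#' `epsilon = 1/100`, `gamma = 2`, `rho = 150`.
#' Coupling strengths `eta = rbind(c(2/3, -1/3), c(11/15, -11/30))`, decay
#' rates `mu = rbind(c(4, 1), c(17/4, 11/10))`.
#'
#' @return A [field_config()].
#' @export
table1_field_config <- function() {
  field_config(
    pop1 = list(alpha = 1/20, theta = 1/2, kappa = 2, epsilon = 1/1000,
                gamma = 5, rho = 150),
    pop2 = list(alpha = 1/10, theta = 4/5, kappa = 1/10, epsilon = 1/100,
                gamma = 2, rho = 150),
    eta = rbind(c(2/3, -1/3), c(11/15, -11/30)),
    mu = rbind(c(4, 1), c(17/4, 11/10))
  )
}

# Right-hand side of the discretized field. state: list(u1, a1, u2, a2);
# W: assembled weights. Returns the list of derivatives.
field_rhs_core <- function(state, config, W) {
  p1 <- config$pop[[1]]; p2 <- config$pop[[2]]
  S1 <- config$S[[1]]; S2 <- config$S[[2]]
  r1 <- p1$kappa * state$u1 - state$a1 - p1$theta
  r2 <- p2$kappa * state$u2 - state$a2 - p2$theta
  s1 <- S1(r1); s2 <- S2(r2)
  list(
    u1 = p1$alpha * (-state$u1 + W[[1]][[1]] %*% s1 + W[[1]][[2]] %*% s2),
    a1 = p1$epsilon * (-state$a1 - (1 - p1$kappa) * state$u1 + p1$gamma * s1),
    u2 = p2$alpha * (-state$u2 + W[[2]][[1]] %*% s1 + W[[2]][[2]] %*% s2),
    a2 = p2$epsilon * (-state$a2 - (1 - p2$kappa) * state$u2 + p2$gamma * s2)
  )
}

#' Field state derivative
#'
#' Evaluates the right-hand side of the discretized two-population field:
#' `du_i/dt = alpha_i * (-u_i + sum_j integral J_ij S_j dx')` and
#' `da_i/dt = epsilon_i * (-a_i - (1 - kappa_i) u_i + gamma_i S_i(r_i))`,
#' with `r_i = kappa_i u_i - a_i - theta_i`.
#'
#' @param state Named list with numeric vectors `u1`, `a1`, `u2`, `a2` on a
#'   common grid.
#' @param config A [field_config()].
#' @param grid The spatial grid the state lives on.
#'
#' @return Named list of derivatives (`u1`, `a1`, `u2`, `a2`).
#' @export
field_rhs <- function(state, config, grid) {
  stopifnot(inherits(config, "field_config"))
  W <- assemble_weights(grid, config$eta, config$mu,
                        c(config$pop[[1]]$rho, config$pop[[2]]$rho))
  lapply(field_rhs_core(state, config, W), as.numeric)
}

#' Simulate the two-population neural field
#'
#' Integrates the discretized field with the fixed-step classical
#' Runge-Kutta scheme on `M` uniform grid points over \[-1, 1\], recording
#' state and rate snapshots every `record_every` steps. The default initial
#' state is `u_i = a_i = 0` plus small seeded uniform noise (amplitude
#' `perturb`) to break spatial symmetry; pass `init_fn` for a deterministic,
#' grid-independent initial profile instead.
#'
#' @param config A [field_config()].
#' @param M Number of grid points including endpoints (default 201).
#' @param t_end End time in iteration units.
#' @param dt Time step (default 0.1).
#' @param record_every Record a snapshot every this many steps (default 10).
#' @param perturb Amplitude of the uniform random initial perturbation
#'   (default 0.01; ignored when `init_fn` is given).
#' @param seed Seed for the initial perturbation (default 1).
#' @param init_fn Optional function of position returning a named list
#'   (`u1`, `a1`, `u2`, `a2`) of initial profiles.
#'
#' @return A `field_trace`: list with `times`, `x` (grid), and time-by-space
#'   matrices `u1`, `a1`, `u2`, `a2`, `rate1`, `rate2`.
#' @export
simulate_field <- function(config, M = 201, t_end, dt = 0.1,
                           record_every = 10, perturb = 0.01, seed = 1,
                           init_fn = NULL) {
  stopifnot(inherits(config, "field_config"), M >= 3, t_end > 0, dt > 0)
  grid <- seq(-1, 1, length.out = M)
  W <- assemble_weights(grid, config$eta, config$mu,
                        c(config$pop[[1]]$rho, config$pop[[2]]$rho))
  p1 <- config$pop[[1]]; p2 <- config$pop[[2]]

  if (is.null(init_fn)) {
    set.seed(seed)
    y <- stats::runif(4 * M, -perturb, perturb)
  } else {
    init <- init_fn(grid)
    y <- c(init$u1, init$a1, init$u2, init$a2)
    if (length(y) != 4 * M) {
      stop("simulate_field: init_fn must return 4 profiles of grid length",
           call. = FALSE)
    }
  }

  i1 <- seq_len(M); i2 <- M + i1; i3 <- 2 * M + i1; i4 <- 3 * M + i1
  rhs <- function(t, y, parms) {
    d <- field_rhs_core(
      list(u1 = y[i1], a1 = y[i2], u2 = y[i3], a2 = y[i4]), config, W
    )
    list(c(d$u1, d$a1, d$u2, d$a2))
  }

  n_steps <- round(t_end / dt)
  rec <- unique(c(seq(0L, n_steps, by = record_every), n_steps))
  n_rec <- length(rec)
  times <- rec * dt
  u1 <- matrix(NA_real_, n_rec, M); a1 <- u1; u2 <- u1; a2 <- u1
  u1[1, ] <- y[i1]; a1[1, ] <- y[i2]; u2[1, ] <- y[i3]; a2[1, ] <- y[i4]

  for (r in seq_len(n_rec - 1L)) {
    chunk_times <- seq(rec[r], rec[r + 1L]) * dt
    sol <- deSolve::rk4(y = y, times = chunk_times, func = rhs, parms = NULL)
    y <- as.numeric(sol[nrow(sol), -1L])
    if (!all(is.finite(y))) {
      stop(sprintf("simulate_field: non-finite state at t = %g (instability)",
                   times[r + 1L]), call. = FALSE)
    }
    u1[r + 1L, ] <- y[i1]; a1[r + 1L, ] <- y[i2]
    u2[r + 1L, ] <- y[i3]; a2[r + 1L, ] <- y[i4]
  }

  rate1 <- config$S[[1]](p1$kappa * u1 - a1 - p1$theta)
  rate2 <- config$S[[2]](p2$kappa * u2 - a2 - p2$theta)
  dim(rate1) <- dim(u1); dim(rate2) <- dim(u2)
  structure(
    list(times = times, x = grid, u1 = u1, a1 = a1, u2 = u2, a2 = a2,
         rate1 = rate1, rate2 = rate2, dt = dt, M = M),
    class = "field_trace"
  )
}
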