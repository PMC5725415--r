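#' Expected firing rate under Gaussian threshold noise (quadrature)
#'
#' When the spiking threshold carries zero-mean Gaussian noise of variance
#' `sigma2`, the expected firing rate is the Gaussian-weighted average
#' `<S>(varsigma) = (2 pi sigma2)^{-1/2} * integral exp(-w^2 / (2 sigma2)) *
#' S(varsigma + w) dw`. The integral is computed by composite Gauss-Legendre
#' quadrature over `w` in `[-8 sigma, 8 sigma]`, with panels split at every
#' staircase discontinuity inside the window (the integrand is piecewise
#' smooth there) and further subdivided to at most `sigma / 2` width so the
#' Gaussian factor is resolved. Within `(0, varsigma_K)` the staircase is
#' evaluated exactly by period iteration.
#'
#' @param varsigma Drive value(s) at which to evaluate the expected rate.
#' @param sigma2 Noise variance (> 0).
#' @param staircase A [rate_staircase()]; defaults to a cached K = 200
#'   staircase.
#' @param n_nodes Gauss-Legendre nodes per panel (default 12).
#'
#' @return Expected rate value(s), smooth and sigmoidal in `varsigma`,
#'   increasing from 0 to 1/3.
#' @examples
#' sc <- rate_staircase(50)
#' expected_rate_quadrature(c(-3, 0.5, 4), sigma2 = 1/4, staircase = sc)
#' @export
expected_rate_quadrature <- function(varsigma, sigma2,
                                     staircase = default_staircase(),
                                     n_nodes = 12) {
  stopifnot(sigma2 > 0, inherits(staircase, "rate_staircase"))
  sigma <- sqrt(sigma2)
  gl <- pracma::gaussLegendre(n_nodes, -1, 1)
  knots <- staircase$knots

  vapply(varsigma, function(s) {
    lo <- -8 * sigma
    hi <- 8 * sigma
    # breakpoints where S(s + w) jumps: w = varsigma_k - s (and w = -s, the
    # edge of the spiking region)
    br <- c(knots - s, -s)
    br <- br[br > lo & br < hi]
    edges <- sort(unique(c(lo, hi, br)))
    # subdivide wide panels so the Gaussian factor is resolved
    max_w <- sigma / 2
    fine <- unlist(lapply(seq_len(length(edges) - 1L), function(i) {
      n_sub <- max(1L, ceiling((edges[i + 1L] - edges[i]) / max_w))
      seq(edges[i], edges[i + 1L], length.out = n_sub + 1L)[-1L]
    }))
    fine <- c(edges[1L], fine)
    a <- fine[-length(fine)]
    b <- fine[-1L]
    # all nodes and weights at once
    half <- (b - a) / 2
    mid <- (a + b) / 2
    w_nodes <- as.vector(outer(gl$x, half) + rep(mid, each = n_nodes))
    w_weights <- as.vector(outer(gl$w, half))
    Svals <- staircase_value(s + w_nodes, staircase, exact_tail = TRUE)
    g <- exp(-w_nodes^2 / (2 * sigma2)) / sqrt(2 * pi * sigma2)
    sum(w_weights * g * Svals)
  }, numeric(1))
}

#' Expected firing rate under Gaussian threshold noise (erf series)
#'
#' Series form of the expected rate: writing the staircase as a sum of
#' Heaviside jumps of size `1 / ((k + 2) (k + 3))` at `varsigma_k` and
#' averaging each against the Gaussian gives
#' `<S>(varsigma) = 1/6 + sum_k erf((varsigma - varsigma_k) /
#' sqrt(2 sigma2)) / (2 (k + 2) (k + 3))`.
#' The sum is truncated after `K` computed discontinuity points; the
#' remaining terms are collapsed at their limit `varsigma_k -> 0`, i.e. a
#' closing term `erf(varsigma / sqrt(2 sigma2)) / (2 (K + 3))` is added.
#' This keeps both limits (`0` at `-Inf`, `1/3` at `+Inf`) exact; the
#' residual error is bounded by `max_{k>K} varsigma_k *
#' sqrt(2 / (pi sigma2)) / (2 (K + 3))` and the crude bound `1 / (2 (K + 3))`
#' on the collapsed tail is attached as attribute `tail_bound`.
#'
#' @inheritParams expected_rate_quadrature
#' @param K Number of series terms; defaults to the staircase's `K`.
#'
#' @return Expected rate value(s) with attribute `tail_bound`.
#' @export
expected_rate_series <- function(varsigma, sigma2,
                                 staircase = default_staircase(),
                                 K = staircase$K) {
  stopifnot(sigma2 > 0, K >= 1, inherits(staircase, "rate_staircase"),
            K <= staircase$K)
  sd2 <- sqrt(2 * sigma2)
  pts <- rev(staircase$knots)[seq_len(K)]  # varsigma_1, ..., varsigma_K
  k <- seq_len(K)
  out <- vapply(varsigma, function(s) {
    1 / 6 + sum(erf((s - pts) / sd2) / (2 * (k + 2) * (k + 3))) +
      erf(s / sd2) / (2 * (K + 3))
  }, numeric(1))
  attr(out, "tail_bound") <- 1 / (2 * (K + 3))
  out
}

#' Error-function-sum approximation of the expected rate
#'
#' Constructs an `N`-term approximation
#' `1/6 + (1 / (6 N)) * sum_i erf((varsigma - nu_i) / chi_i)`
#' of the sigmoidal expected firing rate, with centers `nu_i` and widths
#' `chi_i > 0`. Evaluation is bounded in \[0, 1/3\].
#'
#' @param nu Numeric vector of centers.
#' @param chi Numeric vector of widths (positive, same length as `nu`).
#'
#' @return An object of class `erf_approximation`.
#' @examples
#' # two-term approximation used for the neural-field firing rates
#' table1_rate_function()
#' @export
erf_approximation <- function(nu, chi) {
  stopifnot(length(nu) == length(chi), length(nu) >= 1,
            all(is.finite(nu)), all(is.finite(chi)), all(chi > 0))
  structure(list(N = length(nu), nu = as.numeric(nu), chi = as.numeric(chi)),
            class = "erf_approximation")
}

#' @export
print.erf_approximation <- function(x, ...) {
  cat(sprintf("<erf_approximation> N = %d\n  nu:  %s\n  chi: %s\n", x$N,
              paste(signif(x$nu, 6), collapse = ", "),
              paste(signif(x$chi, 6), collapse = ", ")))
  invisible(x)
}

#' Evaluate an erf-sum approximation
#'
#' @param varsigma Drive value(s).
#' @param approx An [erf_approximation()].
#' @return Approximate expected rate value(s) in \[0, 1/3\].
#' @export
erf_approx_eval <- function(varsigma, approx) {
  stopifnot(inherits(approx, "erf_approximation"))
  out <- rep.int(1 / 6, length(varsigma))
  for (i in seq_len(approx$N)) {
    out <- out + erf((varsigma - approx$nu[i]) / approx$chi[i]) / (6 * approx$N)
  }
  out
}

#' Fit an erf-sum approximation to the expected rate
#'
#' Chooses the centers and widths of an `N`-term erf sum by least squares
#' against the quadrature expected rate on a drive grid (default
#' `[-3, 4]` in steps of 0.01, which covers the sigmoid's support for the
#' noise levels of interest). Uses Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]) from several deterministic seeded starts; widths
#' are optimized on a log scale to stay positive, and the returned terms are
#' sorted by center for reproducibility.
#'
#' @param sigma2 Noise variance (> 0).
#' @param N Number of erf terms (`>= 1`).
#' @param grid Drive grid for the least-squares norm.
#' @param staircase A [rate_staircase()] for the quadrature target.
#' @param n_starts Number of multi-starts (default 8).
#' @param seed Integer seed for the start jitter (default 1).
#'
#' @return An [erf_approximation()] with attributes `rss` (residual sum of
#'   squares), `max_abs_err`, and `target` (the quadrature curve on the
#'   grid).
#' @export
fit_erf_approximation <- function(sigma2, N, grid = seq(-3, 4, by = 0.01),
                                  staircase = default_staircase(),
                                  n_starts = 8, seed = 1) {
  stopifnot(sigma2 > 0, N >= 1)
  target <- expected_rate_quadrature(grid, sigma2, staircase = staircase)

  resid_fn <- function(par) {
    nu <- par[seq_len(N)]
    chi <- exp(par[N + seq_len(N)])
    approx <- erf_approximation(nu, chi)
    erf_approx_eval(grid, approx) - target
  }

  # deterministic multi-start around the sigmoid's midpoint and spread
  rng <- local({
    set.seed(seed)
    list(nu = matrix(stats::runif(n_starts * N, -0.5, 1.5), n_starts, N),
         chi = matrix(stats::runif(n_starts * N, 0.3, 1.5), n_starts, N))
  })
  best <- NULL
  for (i in seq_len(n_starts)) {
    par0 <- c(rng$nu[i, ], log(rng$chi[i, ]))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best)) {
    stop("fit_erf_approximation: optimizer failed from every start", call. = FALSE)
  }

  nu <- best$par[seq_len(N)]
  chi <- exp(best$par[N + seq_len(N)])
  ord <- order(nu)
  out <- erf_approximation(nu[ord], chi[ord])
  attr(out, "rss") <- best$rss
  attr(out, "max_abs_err") <- max(abs(erf_approx_eval(grid, out) - target))
  attr(out, "target") <- target
  out
}

#' Two-term firing-rate function for the field examples
#'
#' The fixed two-term erf approximation of the expected Rulkov firing rate at
#' noise level `sigma2 = 1/4` used by the two-population neural-field
#' example:
#' `S(varsigma) = 1/6 + erf((varsigma - 0.0335) / 0.6890) / 12 +
#'  erf((varsigma - 0.7099) / 0.8213) / 12`.
#'
#' @return A vectorized function mapping drive to rate in \[0, 1/3\].
#' @export
table1_rate_function <- function() {
  approx <- erf_approximation(nu = c(0.0335, 0.7099), chi = c(0.6890, 0.8213))
  function(varsigma) erf_approx_eval(varsigma, approx)
}

# Cached default staircase (K = 200), built on first use.
the <- new.env(parent = emptyenv())
default_staircase <- function() {
  if (is.null(the$staircase)) the$staircase <- rate_staircase(200)
  the$staircase
}
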