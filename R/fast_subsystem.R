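#' Fixed points of the fast subsystem
#'
#' At constant effective drive `varsigma = kappa * u - a - theta`, the fast
#' subsystem (the membrane-potential map with frozen adaptation) undergoes a
#' saddle-node bifurcation at `varsigma = 0`. For `varsigma < 0` a stable and
#' an unstable fixed point exist:
#' `v_s = 25 * (varsigma - 2 - sqrt(varsigma^2 - 8 * varsigma))`,
#' `v_u = 25 * (varsigma - 2 + sqrt(varsigma^2 - 8 * varsigma))`.
#' The unstable point always lies to the right of the reset potential -50, so
#' a stable fixed point and a limit cycle never coexist.
#'
#' @param varsigma Constant effective drive (finite real).
#'
#' @return A list with `v_stable` and `v_unstable` for `varsigma <= 0`
#'   (coincident at -50 when `varsigma = 0`), or `NULL` for `varsigma > 0`
#'   (no fixed points; the system settles into a stable periodic orbit).
#' @examples
#' fixed_points(-1/10)  # list(v_stable = -75, v_unstable = -30)
#' fixed_points(1/10)   # NULL
#' @export
fixed_points <- function(varsigma) {
  stopifnot(is.numeric(varsigma), length(varsigma) == 1L, is.finite(varsigma))
  if (varsigma > 0) return(NULL)
  disc <- sqrt(varsigma^2 - 8 * varsigma)
  list(
    v_stable = 25 * (varsigma - 2 - disc),
    v_unstable = 25 * (varsigma - 2 + disc)
  )
}

# One application of the fast subsystem at constant drive.
fss_step <- function(v, varsigma) {
  if (v < 0) {
    (2500 + 150 * v) / (50 - v) + 50 * varsigma
  } else if (v < 50 + 50 * varsigma) {
    50 + 50 * varsigma
  } else {
    -50
  }
}

#' Limit-cycle period of the fast subsystem
#'
#' For suprathreshold drive `varsigma > 0` the fast subsystem has a unique
#' stable limit cycle that visits the 'left' interval (-Inf, 0) some number
#' of times, then takes one iteration at the spike peak and one at the reset.
#' The period is found by iterating from the reset value `v = -50` and
#' counting iterations with `v < 0`, plus 2. The orbit through -50 is the
#' limit cycle itself, since -50 is on the cycle.
#'
#' @param varsigma Constant effective drive, strictly positive.
#' @param max_iter Safety cap on left-interval iterations (the period grows
#'   without bound as `varsigma` approaches 0 from above).
#'
#' @return Integer period `P(varsigma) >= 3`.
#' @examples
#' limit_cycle_period(1/10)  # 8
#' limit_cycle_period(3/2)   # 3 (maximal frequency: once per 3 iterations)
#' @export
limit_cycle_period <- function(varsigma, max_iter = 1e6) {
  stopifnot(is.numeric(varsigma), length(varsigma) == 1L, is.finite(varsigma))
  if (varsigma <= 0) {
    stop("limit_cycle_period: no limit cycle for varsigma <= 0", call. = FALSE)
  }
  v <- -50
  left <- 0L
  while (v < 0) {
    left <- left + 1L
    if (left > max_iter) {
      stop("limit_cycle_period: iteration cap exceeded (varsigma too close to 0)",
           call. = FALSE)
    }
    v <- (2500 + 150 * v) / (50 - v) + 50 * varsigma
  }
  left + 2L
}

#' Firing rate of the fast subsystem
#'
#' The firing-rate function `S` maps constant drive to the inverse
#' limit-cycle period: `S(varsigma) = 0` for `varsigma <= 0` and
#' `1 / P(varsigma)` for `varsigma > 0`. It is a nondecreasing staircase,
#' right-continuous at its discontinuity points, bounded above by the maximal
#' rate 1/3, and zero exactly on the non-positive half-line.
#'
#' @param varsigma Constant effective drive (vectorized).
#' @param max_period Iteration cap passed to [limit_cycle_period()]; drives
#'   so small that the period exceeds the cap are assigned rate 0 (the true
#'   rate there is below `1 / max_period`).
#'
#' @return Firing rate value(s) in \[0, 1/3\].
#' @examples
#' firing_rate(c(-1/2, 1/10, 2))  # 0, 1/8, 1/3
#' @export
firing_rate <- function(varsigma, max_period = 1e6) {
  vapply(varsigma, function(s) {
    if (!is.finite(s)) stop("firing_rate: varsigma must be finite", call. = FALSE)
    if (s <= 0) return(0)
    p <- tryCatch(limit_cycle_period(s, max_iter = max_period),
                  error = function(e) NA_integer_)
    if (is.na(p)) 0 else 1 / p
  }, numeric(1))
}

#' Discontinuity points of the firing-rate staircase
#'
#' Returns the decreasing sequence `varsigma_1 > varsigma_2 > ... > 0` at
#' which the limit-cycle period jumps from `k + 3` (just below) to `k + 2`
#' (at and above), so that `S(varsigma_k) = 1 / (k + 2)` with a jump of size
#' `1 / ((k + 2) * (k + 3))`. The first point is exactly `varsigma_1 = 1`
#' (the smallest drive at which the reset value maps directly to a
#' non-negative potential); the second has the closed form
#' `(5 - sqrt(17)) / 2`. All points are located by bisection on the
#' integer-valued period function.
#'
#' Each bisection is run to full floating-point resolution (the bracket is
#' narrowed until its midpoint degenerates), so the returned point is the
#' smallest representable double whose period is `k + 2`; in particular
#' `discontinuity_points(1)` returns exactly 1. `tol` only stops the
#' bisection earlier if a coarser answer suffices.
#'
#' @param K Number of discontinuity points to compute (`K >= 1`).
#' @param tol Absolute bisection tolerance; 0 (the default) bisects to full
#'   double resolution.
#'
#' @return Numeric vector `varsigma_1, ..., varsigma_K` (decreasing).
#' @examples
#' discontinuity_points(2)  # c(1, (5 - sqrt(17)) / 2)
#' @export
discontinuity_points <- function(K, tol = 0) {
  stopifnot(K >= 1)
  out <- numeric(K)
  hi_start <- 2
  for (k in seq_len(K)) {
    # varsigma_k = inf { s : P(s) <= k + 2 }.  Bracket: the period at the
    # previous discontinuity is k + 1 <= k + 2, so it serves as upper end.
    hi <- if (k == 1L) hi_start else out[k - 1L]
    lo <- hi / 2
    while (limit_cycle_period(lo) <= k + 2L) lo <- lo / 2
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (mid <= lo || mid >= hi) break  # bracket exhausted at double resolution
      if (limit_cycle_period(mid) <= k + 2L) hi <- mid else lo <- mid
    }
    out[k] <- hi
  }
  out
}

#' Staircase representation of the firing-rate function
#'
#' Precomputes the first `K` discontinuity points and packages them with the
#' plateau values `1 / (k + 2)` into a fast-to-evaluate representation of the
#' partial sum `S_K(varsigma) = sum_{k <= K} H(varsigma - varsigma_k) /
#' ((k + 2) (k + 3))` with the convention `H(0) = 1` (right-continuity from
#' above at each jump). Below `varsigma_K` the truncated staircase is 0 while
#' the exact rate is at most `1 / (K + 3)`; [staircase_value()] can fall back
#' to direct period iteration there.
#'
#' @param K Number of discontinuities retained (default 200).
#' @param tol Bisection tolerance for the discontinuity points (0 = full
#'   double resolution).
#'
#' @return An object of class `rate_staircase` with fields `knots`
#'   (increasing: `varsigma_K, ..., varsigma_1`), `values` (the plateau value
#'   on each `[varsigma_k, varsigma_{k-1})`), `K`, and `max_rate = 1/3`.
#' @export
rate_staircase <- function(K = 200, tol = 0) {
  pts <- discontinuity_points(K, tol = tol)
  structure(
    list(
      knots = rev(pts),                      # ascending
      values = rev(1 / (seq_len(K) + 2)),    # value on [knots[j], knots[j+1])
      K = K,
      max_rate = 1 / 3
    ),
    class = "rate_staircase"
  )
}

#' Evaluate a rate staircase
#'
#' @param varsigma Drive value(s).
#' @param staircase A [rate_staircase()] object.
#' @param exact_tail If `TRUE`, values in `(0, varsigma_K)` are computed by
#'   direct period iteration (exact, slower); if `FALSE` they are truncated
#'   to 0 (error at most `1 / (K + 3)`).
#'
#' @return Rate value(s) in \[0, 1/3\].
#' @export
staircase_value <- function(varsigma, staircase, exact_tail = FALSE) {
  stopifnot(inherits(staircase, "rate_staircase"))
  idx <- findInterval(varsigma, staircase$knots)
  out <- ifelse(idx > 0, staircase$values[pmax(idx, 1L)], 0)
  if (exact_tail) {
    tail_idx <- which(idx == 0 & varsigma > 0)
    if (length(tail_idx)) {
      out[tail_idx] <- firing_rate(varsigma[tail_idx], max_period = 1e5)
    }
  }
  as.numeric(out)
}

#' Turn a staircase into a plain rate function
#'
#' Convenience wrapper returning `function(varsigma)` suitable as the `S`
#' argument of [integrate_rate()] and friends.
#'
#' @inheritParams staircase_value
#' @return A vectorized function mapping drive to rate.
#' @export
staircase_fun <- function(staircase, exact_tail = FALSE) {
  force(staircase); force(exact_tail)
  function(varsigma) staircase_value(varsigma, staircase, exact_tail = exact_tail)
}
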