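test_that("connectivity kernel: peak value, symmetry, flat limit", {
  expect_equal(connectivity_kernel(0.3, 0.3, rho = 150, eta = 2/3, mu = 4), 100)
  x <- seq(-1, 1, by = 0.25)
  expect_equal(connectivity_kernel(x, 0.5, 150, 2/3, 4),
               connectivity_kernel(0.5, x, 150, 2/3, 4))
  expect_equal(connectivity_kernel(x, -0.7, 10, 0.5, 0), rep(5, length(x)))
})

test_that("assembled weights implement trapezoidal quadrature of the coupling integral", {
  grid <- seq(-1, 1, length.out = 41)
  eta <- rbind(c(2/3, -1/3), c(11/15, -11/30))
  mu <- rbind(c(4, 1), c(17/4, 11/10))
  W <- assemble_weights(grid, eta, mu, rho = c(150, 150))
  # eta = 0 gives zero matrices
  W0 <- assemble_weights(grid, matrix(0, 2, 2), mu, rho = c(150, 150))
  expect_true(all(W0[[1]][[2]] == 0))
  # flat kernel: field input is 2 * rho * eta * c for S == c
  Wf <- assemble_weights(grid, eta, matrix(1e-9, 2, 2), rho = c(150, 150))
  cst <- rep(0.2, 41)
  expect_equal(as.numeric(Wf[[1]][[1]] %*% cst), rep(2 * 150 * (2/3) * 0.2, 41),
               tolerance = 1e-6)
  # trapezoid order: halving h reduces the quadrature error by ~4
  g <- function(x) 0.1 + 0.05 * cos(pi * x)
  exact <- vapply(grid, function(x) {
    stats::integrate(function(xp) connectivity_kernel(x, xp, 150, 2/3, 4) * g(xp),
                     -1, 1, rel.tol = 1e-12)$value
  }, numeric(1))
  err_coarse <- max(abs(W[[1]][[1]] %*% g(grid) - exact))
  grid2 <- seq(-1, 1, length.out = 81)
  W2 <- assemble_weights(grid2, eta, mu, rho = c(150, 150))
  exact2 <- vapply(grid2, function(x) {
    stats::integrate(function(xp) connectivity_kernel(x, xp, 150, 2/3, 4) * g(xp),
                     -1, 1, rel.tol = 1e-12)$value
  }, numeric(1))
  err_fine <- max(abs(W2[[1]][[1]] %*% g(grid2) - exact2))
  expect_gt(err_coarse / err_fine, 3)
  expect_lt(err_coarse / err_fine, 5)
  expect_error(assemble_weights(grid[1:2], eta, mu, c(150, 150)), "3 grid")
})

test_that("field right-hand side decays linearly when uncoupled", {
  cfg <- field_config(
    pop1 = list(alpha = 0.1, theta = 0.5, kappa = 1, epsilon = 0.05,
                gamma = 0, rho = 150),
    pop2 = list(alpha = 0.2, theta = 0.5, kappa = 1, epsilon = 0.02,
                gamma = 0, rho = 150),
    eta = matrix(0, 2, 2), mu = matrix(1, 2, 2),
    S1 = function(r) rep(0, length(r)), S2 = function(r) rep(0, length(r))
  )
  grid <- seq(-1, 1, length.out = 11)
  st <- list(u1 = rep(0.3, 11), a1 = rep(0.2, 11),
             u2 = rep(-0.1, 11), a2 = rep(0.4, 11))
  d <- field_rhs(st, cfg, grid)
  expect_equal(d$u1, rep(-0.1 * 0.3, 11))
  expect_equal(d$a1, rep(-0.05 * 0.2, 11))
  expect_equal(d$u2, rep(-0.2 * -0.1, 11))
  expect_equal(d$a2, rep(-0.02 * 0.4, 11))
})

test_that("with zero coupling each grid point reproduces the rate model exactly", {
  fc <- table1_field_config()
  fc$eta <- matrix(0, 2, 2)
  init <- function(x) list(u1 = rep(0, length(x)), a1 = -0.5 * cos(pi * x),
                           u2 = rep(0, length(x)), a2 = 0.3 * sin(pi * x))
  ft <- simulate_field(fc, M = 21, t_end = 50, dt = 0.1, record_every = 50,
                       init_fn = init)
  for (j in c(3, 11, 17)) {
    p1 <- fc$pop[[1]]
    np <- neuron_params(p1$theta, p1$kappa, p1$epsilon, p1$gamma)
    rt <- integrate_rate(np, function(t) rep(0, length(t)),
                         table1_rate_function(), t_end = 50, dt = 0.1,
                         a0 = -0.5 * cos(pi * ft$x[j]))
    expect_identical(ft$a1[nrow(ft$a1), j], tail(rt$a, 1))
  }
})

test_that("a spatially uniform field with flat kernel reduces to a 4-dimensional system", {
  fc <- table1_field_config()
  fc$mu <- matrix(1e-9, 2, 2)
  init <- function(x) list(u1 = rep(0.05, length(x)), a1 = rep(0, length(x)),
                           u2 = rep(0.05, length(x)), a2 = rep(0, length(x)))
  ft <- simulate_field(fc, M = 21, t_end = 100, dt = 0.1, record_every = 100,
                       init_fn = init)
  # the uniform state stays uniform (up to the residual mu = 1e-9 tilt)
  expect_lt(diff(range(ft$u1[nrow(ft$u1), ])), 1e-6)
  # direct integration of the homogeneous system with coupling 2 * rho * eta
  p1 <- fc$pop[[1]]; p2 <- fc$pop[[2]]; S <- table1_rate_function()
  rhs4 <- function(t, y, parms) {
    s1 <- S(p1$kappa * y[1] - y[2] - p1$theta)
    s2 <- S(p2$kappa * y[3] - y[4] - p2$theta)
    list(c(
      p1$alpha * (-y[1] + 2 * 150 * (fc$eta[1, 1] * s1 + fc$eta[1, 2] * s2)),
      p1$epsilon * (-y[2] - (1 - p1$kappa) * y[1] + p1$gamma * s1),
      p2$alpha * (-y[3] + 2 * 150 * (fc$eta[2, 1] * s1 + fc$eta[2, 2] * s2)),
      p2$epsilon * (-y[4] - (1 - p2$kappa) * y[3] + p2$gamma * s2)
    ))
  }
  sol <- deSolve::rk4(c(0.05, 0, 0.05, 0), seq(0, 100, by = 0.1), rhs4, NULL)
  hom <- sol[nrow(sol), -1]
  expect_equal(ft$u1[nrow(ft$u1), 11], as.numeric(hom[1]), tolerance = 1e-6)
  expect_equal(ft$a1[nrow(ft$a1), 11], as.numeric(hom[2]), tolerance = 1e-6)
  expect_equal(ft$u2[nrow(ft$u2), 11], as.numeric(hom[3]), tolerance = 1e-6)
})

test_that("field rates stay in [0, 1/3] and symmetric data stay mirror-symmetric", {
  fc <- table1_field_config()
  init <- function(x) list(u1 = 0.05 * cos(pi * x), a1 = rep(0, length(x)),
                           u2 = 0.02 * cos(2 * pi * x), a2 = rep(0, length(x)))
  ft <- simulate_field(fc, M = 41, t_end = 100, dt = 0.1, record_every = 100,
                       init_fn = init)
  expect_true(all(ft$rate1 >= 0 & ft$rate1 <= 1/3))
  expect_true(all(ft$rate2 >= 0 & ft$rate2 <= 1/3))
  last <- ft$u1[nrow(ft$u1), ]
  expect_lt(max(abs(last - rev(last))), 1e-9)
})
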