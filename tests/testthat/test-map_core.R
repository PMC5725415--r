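test_that("evaluate_f selects exactly one branch and matches the piecewise formula", {
  expect_equal(evaluate_f(-50, 12, 0), -50)       # (2500 - 7500) / 100
  expect_equal(evaluate_f(0, -50, -1/10), 45)     # peak branch: 50 + 50 * (-0.1)
  expect_equal(evaluate_f(100, 0, 0), -50)        # reset branch

  set.seed(42)
  x1 <- runif(500, -80, 120); x2 <- runif(500, -80, 120)
  x3 <- runif(500, -2, 2)
  got <- evaluate_f(x1, x2, x3)
  manual <- numeric(500)
  for (i in 1:500) {
    manual[i] <- if (x1[i] < 0) {
      (2500 + 150 * x1[i]) / (50 - x1[i]) + 50 * x3[i]
    } else if (x1[i] < 50 + 50 * x3[i] && x2[i] < 0) {
      50 + 50 * x3[i]
    } else {
      -50
    }
  }
  expect_identical(got, manual)
  expect_error(evaluate_f(NA_real_, 0, 0), "finite")
})

test_that("spike condition: non-negative twice always spikes; sufficient-drive branch works", {
  expect_true(spike_condition(10, 5, -100))
  expect_false(spike_condition(-10, 100, 0))
  expect_true(spike_condition(100, -50, 1))   # 100 >= 50 + 50
  expect_false(spike_condition(10, -50, 0.5)) # 10 < 75, previous negative
})

test_that("step_neuron honors the saddle-node fixed point and the drive-to-peak map", {
  p <- neuron_params(0, 1, 1/2, 1)
  st <- step_neuron(map_state(), 0, p)
  expect_equal(st$v_curr, -50)
  expect_equal(st$a, 0)
  expect_equal(st$s, 0L)

  # unit drive maps the reset value to 0: f(-50, ., 1) = -50 + 50
  p2 <- neuron_params(0, 1, 1e-3, 0)
  st2 <- step_neuron(map_state(), 1, p2)
  expect_equal(st2$v_curr, 0)

  # gamma = 0, kappa = 1: adaptation relaxes geometrically with factor 1 - eps
  p3 <- neuron_params(10, 1, 0.25, 0)
  st3 <- map_state(a = 2)
  for (i in 1:5) st3 <- step_neuron(st3, 0.7, p3)
  expect_equal(st3$a, 2 * 0.75^5, tolerance = 1e-14)
})

test_that("reset contract: every spike is followed by v = -50 exactly", {
  p <- neuron_params(1/10, 1/2, 1/2, 1/2)
  tr <- simulate_neuron(p, make_stimulus("step", phi = 0.4, length = 800,
                                         onset = 100, offset = 700))
  expect_gt(sum(tr$s), 0)
  hit <- which(tr$s == 1L & tr$n < nrow(tr) - 1)
  expect_true(all(tr$v[hit + 1L] == -50))
  # s flags exactly the iterations where the spike condition holds
  drive <- p$kappa * tr$u - tr$a - p$theta
  v_prev <- c(-50, tr$v[-nrow(tr)])
  expect_identical(tr$s == 1L, as.vector(spike_condition(tr$v, v_prev, drive)))
})

test_that("persistent spiking occurs exactly for constant input above threshold", {
  p <- neuron_params(0.2, 1, 1/50, 1)
  above <- simulate_neuron(p, make_stimulus("constant", phi = 0.3, length = 6000))
  below <- simulate_neuron(p, make_stimulus("constant", phi = 0.1, length = 6000))
  expect_gt(sum(above$s[3001:6000]), 0)   # keeps spiking late
  expect_equal(sum(below$s[3001:6000]), 0) # at most finitely many spikes
  # zero input starting at the stable fixed point of drive -theta: v rests
  v_rest <- fixed_points(-p$theta)$v_stable
  rest <- simulate_neuron(p, make_stimulus("constant", phi = 0, length = 200),
                          init = map_state(v_curr = v_rest))
  expect_equal(sum(rest$s), 0)
  expect_lt(max(abs(rest$v - v_rest)), 1e-10)
})

test_that("subthreshold adaptation equals the closed-form geometric sum", {
  p <- neuron_params(10, 0.4, 0.05, 1)  # huge theta: never spikes
  set.seed(7)
  u <- runif(1500, -1, 1)
  tr <- simulate_neuron(p, u)
  expect_equal(sum(tr$s), 0)
  idx <- seq(0, 1499, by = 37)
  expect_lt(max(abs(tr$a[idx + 1] - adaptation_closed_form(u, p, idx))), 1e-9)
})

test_that("asymptotic spike rate under constant input does not depend on kappa", {
  counts <- vapply(c(0, 0.5, 1, 2), function(k) {
    p <- neuron_params(0.1, k, 0.02, 0.5)
    tr <- simulate_neuron(p, make_stimulus("constant", phi = 0.3, length = 5000))
    sum(tr$s[2001:5000])
  }, numeric(1))
  expect_lte(max(counts) - min(counts), 1)
})

test_that("stimulus generator produces the documented waveforms", {
  expect_equal(as.numeric(make_stimulus("constant", phi = 0.3, length = 10)),
               rep(0.3, 10))
  expect_equal(as.numeric(make_stimulus("harmonic", phi = 1, omega = 0, length = 5)),
               rep(1, 5))
  h <- make_stimulus("harmonic", phi = 1/5, omega = 1, length = 1001)
  expect_equal(h[1001], 1/5 * cos(pi), tolerance = 1e-15)  # n = 1000
  st <- make_stimulus("step", phi = 2, length = 10, onset = 3, offset = 7)
  expect_equal(as.numeric(st), c(0, 0, 0, 2, 2, 2, 2, 0, 0, 0))
  expect_error(make_stimulus("sawtooth", length = 5), "unknown")
  expect_error(simulate_neuron(neuron_params(0, 1, 0.5, 1), numeric(0)), "empty")
})

test_that("discrete and continuous stimulus forms agree at integer times", {
  for (kind_args in list(
    list(kind = "step", phi = 0.4, onset = 10, offset = 40),
    list(kind = "pulse", phi = -0.2, onset = 5, duration = 12),
    list(kind = "ramp", phi = 0.5, onset = 8, rise = 10, offset = 45),
    list(kind = "harmonic", phi = 0.3, omega = 7, vartheta = 1.1)
  )) {
    series <- do.call(make_stimulus, c(kind_args, list(length = 50)))
    fn <- do.call(stimulus_function, kind_args)
    expect_equal(as.numeric(series), fn(0:49), tolerance = 1e-14,
                 info = kind_args$kind)
  }
})
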