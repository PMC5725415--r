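# Shared fixtures: one staircase per test run (K = 200, matches the package
# default), plus the low-/high-pass filter parameter sets used throughout.
fixture_env <- new.env(parent = emptyenv())

test_staircase <- function() {
  if (is.null(fixture_env$sc)) fixture_env$sc <- rate_staircase(200)
  fixture_env$sc
}

lowpass_params <- function() neuron_params(1/7, 1/10, 1/200, 2)
highpass_params <- function() neuron_params(1/7, 2, 1/200, 2)

# Spikes counted over the final window of `period` iterations of a map trace.
spikes_last_period <- function(trace, period) {
  n <- nrow(trace)
  sum(trace$s[(n - period + 1):n])
}
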