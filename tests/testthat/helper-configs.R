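# Shared fixture configurations, built in code.

# Canonical 1D conflict: optima at -1/2 and +1/2, box [-10, 10].
default_1d <- function(p = 0.5, seed = 1L, ...) {
  conflict_config(n_dims = 1, d = 1, p = p, seed = seed, ...)
}

# A randomly placed 1D configuration for parameterized oracle checks.
random_1d_config <- function() {
  halfwidth <- runif(1, 2, 12)
  d <- runif(1, 0.2, halfwidth / 2)
  center <- runif(1, -halfwidth / 4, halfwidth / 4)
  sp <- space_spec(1, halfwidth = halfwidth)
  model_config(sp,
               agent_objective("A", center - d / 2),
               agent_objective("B", center + d / 2),
               p = runif(1, 0.05, 0.95))
}

expect_within_se <- function(estimate, truth, se, k = 3) {
  expect_lt(abs(estimate - truth), max(k * se, 1e-12))
}
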