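# Unit-scale runs of the experiment drivers; the published study designs run
# in test-acceptance.R.

test_that("1D conflict experiment reports hyper-maladaptation", {
  res <- exp_1d_conflict(seed = 41, n_events = 20000)
  expect_s3_class(res$trajectory, "gc_trajectory")
  expect_equal(sort(res$occupancy$weighting), c("event", "proposal"))
  # leap-frogging carries the phenotype far outside the battleground
  expect_true(any(abs(res$trajectory$records$x1) > 1))
  # the density of invasion events favours the outside (the hyper-
  # maladaptation claim); time-weighting reverses the ordering because the
  # phenotype lingers where beneficial sets are small, so the assertion is
  # event-weighted while both are reported
  ev <- res$occupancy[res$occupancy$weighting == "event", ]
  expect_gte(ev$outside, ev$inside - 3 * ev$se)
  for (s in res$maladaptation)
    expect_true(all(s$per_agent_overall > 0.5))
})

test_that("dimension scaling runs are reproducible and sized correctly", {
  res <- exp_dimension_scaling(seed = 42, n_grid = c(1, 2, 4),
                               n_events = 40, n_replicates = 30)
  expect_equal(res$table$n_dims, c(1, 2, 4))
  expect_true(all(res$table$se > 0))
  expect_gt(res$scaling_overall$exponent, 0.2)
  res2 <- exp_dimension_scaling(seed = 42, n_grid = c(1, 2, 4),
                                n_events = 40, n_replicates = 30)
  expect_identical(res$table, res2$table)
})

test_that("modularity experiment converges uncontested axes", {
  res <- exp_modularity(seed = 43, n_grid = c(1, 2, 4), n_events = 40,
                        n_replicates = 30, demo_n_events = 3000,
                        marginal_n_events = 8000, breaks = 40)
  expect_true(all(diff(res$demo$offaxis_deviation) <= 1e-12))
  expect_lt(res$demo$final_offaxis_deviation, 0.05)
  expect_lt(abs(res$scaling_overall$exponent), 0.25)
  expect_true(is.finite(res$marginal$sup_discrepancy_se_units))
})

test_that("power asymmetry peaks at even control", {
  res <- exp_p_sweep(seed = 44, p_grid = c(0.1, 0.5, 0.9), n_events = 5000)
  expect_equal(res$argmax_p, 0.5)
  tab <- res$table
  expect_gt(tab$maladaptation[tab$p == 0.5], tab$maladaptation[tab$p == 0.1])
  expect_gt(tab$maladaptation[tab$p == 0.5], tab$maladaptation[tab$p == 0.9])
})

test_that("pessima scenarios separate escape from persistence", {
  res <- exp_pessima(seed = 45, n_events = 5000)
  fin <- res$final
  expect_equal(fin$single_near_a, 0)
  expect_equal(fin$identical_near_a, 0)
  expect_gt(fin$disagreeing_near_a, 0.02)
  expect_gt(fin$disagreeing_near_b, 0.02)
  # windows table covers all three scenarios over all windows
  expect_equal(nrow(res$windows), 3 * 5)
})

test_that("compromise accounting reproduces the exact benchmarks", {
  res <- exp_compromise(seed = 46, dims = 1, n_events = 20000)
  expect_equal(res$longrun$midpoint_settlement, 0.5)
  expect_equal(res$longrun$adversary_optimum, 1)
  expect_gt(res$longrun$conflict_dist_a, 0.5)
  expect_gt(res$longrun$conflict_dist_b, 0.5)
  m <- res$myopic
  # participating is myopically no worse than relinquishing up to one
  # inter-optimum distance beyond the adversary's optimum ...
  keep <- m$z <= 1.5
  expect_true(all(m$participating[keep] <= m$relinquishing[keep] + 1e-12))
  # ... with exact equality at z = b + d
  eq <- m[m$z == 1.5, ]
  expect_equal(eq$participating, eq$relinquishing)
})

test_that("experiment outputs depend only on (config, seed)", {
  r1 <- exp_p_sweep(seed = 47, p_grid = c(0.3, 0.7), n_events = 1000)
  r2 <- exp_p_sweep(seed = 47, p_grid = c(0.3, 0.7), n_events = 1000)
  expect_identical(r1$table, r2$table)
  r3 <- exp_p_sweep(seed = 48, p_grid = c(0.3, 0.7), n_events = 1000)
  expect_false(identical(r1$table$maladaptation, r3$table$maladaptation))
})
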