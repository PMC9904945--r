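test_that("Fisher limit drives maladaptation to zero", {
  traj <- run_dynamics(conflict_config(p = 1, seed = 31), 2000,
                       on_absorbed = "truncate")
  expect_lt(traj$records$dist_a[nrow(traj$records)], 1e-10)
  s <- maladaptation_summary(traj)
  expect_lt(s$overall, 0.01)           # below 0.01 * d
  expect_equal(s$per_agent_overall[["b"]], s$overall + 1,
               tolerance = 0.02)       # b stays ~d away
})

test_that("overall maladaptation dominates every per-dimension deviation", {
  traj <- run_dynamics(conflict_config(n_dims = 3, seed = 32), 3000)
  for (wt in c("event", "proposal")) {
    s <- maladaptation_summary(traj, weighting = wt)
    expect_gte(s$overall, max(s$per_dimension) - 1e-12)
    expect_true(all(s$per_dimension >= 0))
    expect_equal(s$n_events_used,
                 if (wt == "proposal") 1499 else 1500)
  }
})

test_that("summaries rescale exactly with the space", {
  t1 <- run_dynamics(default_1d(seed = 33), 4000)
  t2 <- run_dynamics(conflict_config(d = 2, box_halfwidth = 20, seed = 33),
                     4000)
  set.seed(1); s1 <- maladaptation_summary(t1)
  set.seed(1); s2 <- maladaptation_summary(t2)
  expect_identical(s2$overall, 2 * s1$overall)
  expect_identical(s2$per_dimension, 2 * s1$per_dimension)
  expect_identical(s2$per_agent_overall, 2 * s1$per_agent_overall)
})

test_that("burn-in windows are validated", {
  traj <- run_dynamics(default_1d(seed = 34), 100)
  expect_error(maladaptation_summary(traj, burn_in = 100), "burn_in")
  expect_error(maladaptation_summary(traj, burn_in = -1), "burn_in")
})

test_that("occupancy of the whole space is exactly 1", {
  traj <- run_dynamics(default_1d(seed = 35), 500)
  o <- occupancy_probability(traj, region_whole_space())
  expect_equal(o$probability, 1)
  expect_equal(o$standard_error, 0)
})

test_that("region descriptors agree across equivalent geometries", {
  traj <- run_dynamics(conflict_config(n_dims = 2, seed = 36), 2000)
  set.seed(2)
  o_slab <- occupancy_probability(traj, region_slab(c(-0.5, 0), c(0.5, 0)))
  set.seed(2)
  o_int <- occupancy_probability(traj, region_interval(-0.5, 0.5, axis = 1))
  expect_equal(o_slab$probability, o_int$probability)
  expect_error(
    occupancy_probability(traj, region_ball(0, 1)),
    "dimension")
})

test_that("equilibrium histograms normalize and respect model symmetry", {
  traj <- run_dynamics(default_1d(seed = 37), 30000)
  for (wt in c("event", "proposal")) {
    h <- equilibrium_histogram(traj, breaks = 40, weighting = wt)
    expect_equal(sum(h$mass), 1, tolerance = 1e-12)
  }
  h <- equilibrium_histogram(traj, breaks = 40)
  # p = 1/2 model is symmetric about the midpoint: compare mirrored bins
  m1 <- h$mass
  m2 <- rev(h$mass)
  se <- sqrt(h$se^2 + rev(h$se)^2)
  ok <- abs(m1 - m2) <= 4 * pmax(se, 1e-12)
  expect_true(all(ok))
})

test_that("single-optimum mass concentrates at the optimum", {
  traj <- run_dynamics(conflict_config(p = 1, seed = 38), 3000,
                       on_absorbed = "truncate")
  h <- equilibrium_histogram(traj, breaks = seq(-10, 10, by = 0.5))
  # the optimum -0.5 sits on a bin edge; the two adjacent bins take all mass
  expect_gt(sum(h$mass[h$lo >= -1 & h$hi <= 0]), 0.99)
})

test_that("2D histograms return a normalized mass matrix", {
  traj <- run_dynamics(conflict_config(n_dims = 2, seed = 39), 2000)
  h <- equilibrium_histogram(traj, breaks = 20, axis = c(1, 2))
  expect_equal(sum(h$mass), 1, tolerance = 1e-12)
  traj3 <- run_dynamics(conflict_config(n_dims = 3, seed = 39), 100)
  expect_error(equilibrium_histogram(traj3, axis = c(1, 2, 3)),
               "one or two axes")
})

test_that("scaling fits recover known exponents", {
  n <- c(1, 2, 4, 8, 16)
  expect_equal(scaling_fit(data.frame(n_dims = n, mean = sqrt(n)))$exponent,
               0.5, tolerance = 1e-12)
  expect_equal(scaling_fit(data.frame(n_dims = n, mean = rep(3, 5)))$exponent,
               0, tolerance = 1e-12)
  expect_equal(scaling_fit(data.frame(n_dims = n, mean = 2 * n))$exponent,
               1, tolerance = 1e-12)
  expect_error(scaling_fit(data.frame(n_dims = c(1, 2), mean = c(1, 2))),
               "3 distinct")
  expect_error(scaling_fit(data.frame(n_dims = n, mean = c(-1, 1, 1, 1, 1))),
               "positive")
})

test_that("proposal weighting drops the right-censored final state", {
  traj <- run_dynamics(default_1d(seed = 40), 200)
  s_ev <- maladaptation_summary(traj, burn_in = 0, weighting = "event")
  s_pr <- maladaptation_summary(traj, burn_in = 0, weighting = "proposal")
  expect_equal(s_ev$n_events_used, 200)
  expect_equal(s_pr$n_events_used, 199)
  # manual weighted mean over the first 199 states with sojourn weights
  w <- traj$records$proposals[2:200]
  gov <- traj$records$governor[1:199]
  d_gov <- ifelse(gov == "A", traj$records$dist_a[1:199],
                  traj$records$dist_b[1:199])
  expect_equal(s_pr$overall, sum(d_gov * w) / sum(w))
})
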