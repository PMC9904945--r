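test_that("constructors validate geometry", {
  expect_error(space_spec(0), "positive integer")
  expect_error(space_spec(1, bounds = c(2, 1)), "lo < hi")
  expect_error(space_spec(1, bounds = c(-Inf, 1)), "finite")
  sp <- space_spec(2, halfwidth = 5)
  expect_error(model_config(sp, agent_objective("A", c(6, 0)),
                            agent_objective("B", c(1, 0))),
               "outside the space bounds")
  expect_error(model_config(sp, agent_objective("A", c(-1, 0)),
                            agent_objective("B", c(1, 0)), p = 1.5),
               "probability")
  expect_error(
    model_config(sp, agent_objective("A", c(-1, 0)),
                 agent_objective("B", c(1, 0), mode = "avoid_pessimum")),
    "same objective mode")
  cfg <- conflict_config(n_dims = 3, d = 2)
  expect_equal(cfg$d, 2)
  expect_equal(cfg$initial, c(0, 0, 0))
})

test_that("strict-improvement acceptance rule", {
  a <- agent_objective("A", -0.5)
  expect_true(is_beneficial(0.4, 0.1, a))          # 0.6 < 0.9
  expect_false(is_beneficial(0.0, 0.0, a))         # tie is not beneficial
  expect_false(is_beneficial(-0.5, 0.3, a))
  q <- agent_objective("A", c(0, 0), mode = "avoid_pessimum")
  expect_true(is_beneficial(c(0.2, 0), c(0.3, 0.4), q))   # 0.5 > 0.2
  expect_false(is_beneficial(c(0.2, 0), c(0, -0.2), q))   # tie
  expect_error(is_beneficial(c(0, 0), 1, a), "dimension mismatch")
})

test_that("pleiotropic proposals are uniform over the box", {
  sp <- space_spec(2, halfwidth = 10)
  set.seed(42)
  draws <- t(replicate(20000, propose_mutant(sp, c(1, 2), "pleiotropic")))
  expect_true(all(draws >= -10 & draws <= 10))
  se <- 20 / sqrt(12) / sqrt(nrow(draws))
  expect_lt(max(abs(colMeans(draws))), 3 * se)
})

test_that("modular proposals perturb exactly one axis", {
  sp <- space_spec(3, halfwidth = 10)
  cur <- c(1, 2, 3)
  set.seed(7)
  for (i in 1:200) {
    m <- propose_mutant(sp, cur, "modular")
    expect_equal(sum(m != cur), 1)
  }
})

test_that("proposals are exactly equivariant under space rescaling", {
  sp1 <- space_spec(2, halfwidth = 10)
  sp2 <- space_spec(2, halfwidth = 20)
  for (mode in c("pleiotropic", "modular")) {
    set.seed(11)
    m1 <- replicate(50, propose_mutant(sp1, c(1, -2), mode))
    set.seed(11)
    m2 <- replicate(50, propose_mutant(sp2, c(2, -4), mode))
    expect_identical(m2, 2 * m1)
  }
})

test_that("invasion_step accepts only governor-beneficial mutants", {
  cfg <- conflict_config(p = 1, initial = 3, seed = 1)
  set.seed(1)
  for (i in 1:50) {
    rec <- invasion_step(3, cfg)
    expect_identical(rec$governor, "A")
    expect_lt(rec$dist_a, 3.5)
  }
})

test_that("a phenotype at the sole governing optimum is absorbed", {
  cfg <- conflict_config(p = 1, initial = -0.5, max_proposals = 1e4,
                         seed = 2)
  set.seed(2)
  err <- tryCatch(invasion_step(-0.5, cfg),
                  geomconflict_absorbed = function(e) e)
  expect_s3_class(err, "geomconflict_absorbed")
  expect_equal(err$state, -0.5)
  # run_dynamics re-raises with the partial trajectory attached
  err2 <- tryCatch(run_dynamics(cfg, 5),
                   geomconflict_absorbed = function(e) e)
  expect_s3_class(err2$trajectory, "gc_trajectory")
  expect_equal(nrow(err2$trajectory$records), 0)
})

test_that("accepted-mutant law matches the exact interval oracle", {
  # fraction of accepted mutants landing outside the battleground, from the
  # midpoint, vs the closed-form inside/outside split
  cfg <- default_1d(seed = 3)
  truth <- next_mutation_inside_outside_1d(0, cfg)[["outside"]]
  set.seed(3)
  n <- 40000
  outside <- logical(n)
  for (i in seq_len(n)) {
    rec <- invasion_step(0, cfg)
    outside[i] <- abs(rec$phenotype) > 0.5
  }
  expect_within_se(mean(outside), truth, sqrt(truth * (1 - truth) / n))
})

test_that("single-optimum limit converges monotonically (Fisher limit)", {
  # pleiotropic p = 1 runs use the direct conditional sampler; the distance
  # halves per event until the phenotype reaches the optimum at double
  # precision, where the run is genuinely absorbed
  traj <- run_dynamics(conflict_config(p = 1, seed = 4), 200,
                       on_absorbed = "truncate")
  expect_gt(nrow(traj$records), 20)
  expect_true(all(diff(traj$records$dist_a) < 0))
  expect_lt(traj$records$dist_a[nrow(traj$records)], 1e-10)
  # the literal rejection loop under full modularity: the acceptance
  # probability halves with the remaining distance, so the proposal budget
  # truncates the run; convergence is monotone over the recorded prefix
  traj <- run_dynamics(conflict_config(p = 1, mutation_mode = "modular",
                                       seed = 4), 200,
                       on_absorbed = "truncate")
  expect_true(isTRUE(attr(traj, "absorbed")))
  expect_gte(nrow(traj$records), 5)
  expect_true(all(diff(traj$records$dist_a) < 0))
  # p = 0 mirrors to agent B; strict decrease is asserted above the
  # double-precision noise floor, where rounding can repeat a distance
  traj <- run_dynamics(conflict_config(p = 0, seed = 5), 200,
                       on_absorbed = "truncate")
  d <- traj$records$dist_b
  expect_true(all(diff(d) <= 0))
  expect_true(all(diff(d[d > 1e-12]) < 0))
  expect_lt(d[length(d)], 1e-10)
})

test_that("two-agent conflict sustains fluctuation", {
  traj <- run_dynamics(default_1d(seed = 6), 30)
  expect_false(all(diff(traj$records$dist_a) < 0))
  expect_true(all(traj$records$x1 >= -10 & traj$records$x1 <= 10))
})

test_that("trajectories are deterministic in the seed", {
  cfg <- conflict_config(n_dims = 2, mutation_mode = "modular", seed = 9)
  expect_identical(run_dynamics(cfg, 100), run_dynamics(cfg, 100))
  cfg16 <- conflict_config(n_dims = 16, seed = 9)  # direct engine
  expect_identical(run_dynamics(cfg16, 50), run_dynamics(cfg16, 50))
})

test_that("trajectories are exactly equivariant under rescaling", {
  for (n_dims in c(1, 4)) {
    t1 <- run_dynamics(conflict_config(n_dims = n_dims, seed = 10), 300)
    t2 <- run_dynamics(conflict_config(n_dims = n_dims, d = 2,
                                       box_halfwidth = 20, seed = 10), 300)
    x1 <- as.matrix(t1$records[paste0("x", seq_len(n_dims))])
    x2 <- as.matrix(t2$records[paste0("x", seq_len(n_dims))])
    expect_identical(x2, 2 * x1)
    expect_identical(t2$records$proposals, t1$records$proposals)
    expect_identical(t2$records$governor, t1$records$governor)
  }
})

test_that("direct and rejection engines agree in distribution", {
  # 2D pleiotropic model, one invasion from a fixed state: compare the
  # accepted-mutant mean and governor rate across engines
  run_once <- function(engine, seed) {
    cfg <- conflict_config(n_dims = 2, p = 0.5, seed = seed, engine = engine)
    set.seed(seed)
    rec <- invasion_step(c(0.3, 0.4), cfg)
    c(rec$phenotype, gov_a = rec$governor == "A")
  }
  n <- 3000
  rej <- vapply(seq_len(n), function(i) run_once("rejection", i), numeric(3))
  dir <- vapply(seq_len(n), function(i) run_once("direct", i + n), numeric(3))
  for (k in 1:3) {
    se <- sqrt(stats::var(rej[k, ]) / n + stats::var(dir[k, ]) / n)
    expect_within_se(mean(rej[k, ]), mean(dir[k, ]), se, k = 4)
  }
})

test_that("modular dynamics never worsen axes with a shared optimum", {
  cfg <- conflict_config(n_dims = 3, mutation_mode = "modular",
                         initial = c(0, 2, -3), seed = 12)
  traj <- run_dynamics(cfg, 2000)
  for (ax in c("x2", "x3")) {
    dev <- abs(traj$records[[ax]])
    expect_true(all(diff(dev) <= 1e-12))
  }
})
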