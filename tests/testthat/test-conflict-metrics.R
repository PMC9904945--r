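test_that("1D beneficial sets are the expected intervals", {
  sp <- space_spec(1, halfwidth = 10)
  s <- beneficial_set_1d(0, agent_objective("A", -0.5), sp)
  expect_equal(unname(s$intervals), rbind(c(-1, 0)))
  expect_equal(s$measure, 1)
  s <- beneficial_set_1d(-1, agent_objective("B", 0.5), sp)
  expect_equal(unname(s$intervals), rbind(c(-1, 2)))
  expect_equal(s$measure, 3)
  # pessimum-avoiding set is the complement of the radius-|z - q| interval
  s <- beneficial_set_1d(0.2, agent_objective("A", 0,
                                              mode = "avoid_pessimum"), sp)
  expect_equal(unname(s$intervals), rbind(c(-10, -0.2), c(0.2, 10)))
  expect_equal(s$measure, 19.6)
  # the far endpoint 2*o - z clips at the boundary
  s <- beneficial_set_1d(9.5, agent_objective("A", -0.5), sp)
  expect_equal(unname(s$intervals), rbind(c(-10, 9.5)))
  expect_equal(s$measure, 19.5)
  expect_error(beneficial_set_1d(0, agent_objective("A", c(0, 0)),
                                 space_spec(2)), "1D")
})

test_that("exact conflict intensity matches the interval oracle", {
  cfg <- default_1d()
  # maximal and equal to 1 anywhere strictly between the optima
  for (z in c(-0.49, -0.2, 0, 0.25, 0.49))
    expect_equal(conflict_intensity_1d(z, cfg)$intensity, 1)
  # frozen values computed from interval measures by hand:
  # z=-1: m_A=1, c_A=0; m_B=3, c_B=2; weights 1/4, 3/4 -> (3/4)(2/3)
  expect_equal(conflict_intensity_1d(-1, cfg)$intensity, 0.5)
  # z=-2: m_A=3, c_A=0; m_B=5, c_B=2; weights 3/8, 5/8 -> (5/8)(2/5)
  expect_equal(conflict_intensity_1d(-2, cfg)$intensity, 0.25)
  # declines monotonically beyond either optimum
  prof <- conflict_profile_1d(seq(0.5, 9.5, by = 0.1), cfg)
  expect_true(all(diff(prof$intensity) <= 1e-12))
  prof <- conflict_profile_1d(seq(-0.5, -9.5, by = -0.1), cfg)
  expect_true(all(diff(prof$intensity) <= 1e-12))
})

test_that("intensity is invariant under reflection with p swapped", {
  set.seed(100)
  for (i in 1:10) {
    hw <- runif(1, 2, 12)
    d <- runif(1, 0.2, hw / 2)
    p <- runif(1, 0.05, 0.95)
    z <- runif(1, -hw + 0.01, hw - 0.01)
    i1 <- conflict_intensity_1d(
      z, conflict_config(d = d, p = p, box_halfwidth = hw))$intensity
    i2 <- conflict_intensity_1d(
      -z, conflict_config(d = d, p = 1 - p, box_halfwidth = hw))$intensity
    expect_equal(i1, i2, tolerance = 1e-12)
  }
})

test_that("Monte Carlo intensity is consistent with the exact kernel", {
  cfg <- default_1d()
  set.seed(21)
  est <- conflict_intensity_mc(-1, cfg, 2e5)
  expect_within_se(est$intensity, 0.5, est$standard_error, k = 4)
  # modular proposal law shares the 1D kernel in one dimension
  cfg_mod <- conflict_config(mutation_mode = "modular")
  est <- conflict_intensity_mc(-1, cfg_mod, 1e5)
  expect_within_se(est$intensity, 0.5, est$standard_error, k = 4)
})

test_that("intensity on and off the inter-optimum segment in 2D", {
  cfg <- conflict_config(n_dims = 2)
  set.seed(22)
  # on the open segment every beneficial mutation is conflicted
  est <- conflict_intensity_mc(c(0.1, 0), cfg, 2e4)
  expect_equal(est$intensity, 1)
  # far off the segment the intensity is strictly below 1
  est <- conflict_intensity_mc(c(0, 5), cfg, 2e5)
  expect_gt((1 - est$intensity) / est$standard_error, 3)
})

test_that("next-mutation split matches frozen interval-oracle values", {
  cfg <- default_1d()
  expect_equal(next_mutation_inside_outside_1d(0, cfg),
               c(inside = 0.5, outside = 0.5))
  # z=-1: w_A=1/4 split (1/2,1/2); w_B=3/4 split (1/3,2/3)
  expect_equal(next_mutation_inside_outside_1d(-1, cfg),
               c(inside = 0.375, outside = 0.625))
  # z=-5: m_A=9 (1 inside), m_B=11 (1 inside)
  expect_equal(next_mutation_inside_outside_1d(-5, cfg),
               c(inside = 0.1, outside = 0.9))
  expect_equal(sum(next_mutation_inside_outside_1d(3.7, cfg)), 1)
})

test_that("the next beneficial mutation favours the outside everywhere", {
  # exact grid: hyper-maladaptation bound, all z and all p
  for (p in seq(0, 1, by = 0.25)) {
    cfg <- default_1d(p = p)
    for (z in seq(-9.9, 9.9, length.out = 67)) {
      io <- next_mutation_inside_outside_1d(z, cfg)
      expect_gte(io[["outside"]], io[["inside"]])
    }
  }
})

test_that("degenerate intensity queries fail loudly", {
  cfg <- default_1d(p = 1)
  # p=1 and phenotype at A's optimum: no beneficial mutation can invade
  expect_error(conflict_intensity_1d(-0.5, cfg), "no beneficial mutation")
  expect_error(conflict_intensity_mc(0, default_1d(), 0), "n_samples")
})
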