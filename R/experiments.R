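# Deterministic per-replicate seeds derived from one root seed, so every
# experiment is a pure function of (config, root seed).
.replicate_seeds <- function(root, k) {
  set.seed(as.integer(root))
  sample.int(.Machine$integer.max, k)
}

#' One-dimensional conflict dynamics and equilibrium
#'
#' Runs the canonical 1D two-optima model and summarizes it: the trajectory
#' itself (the never-ending phenotypic fluctuation), the equilibrium
#' histogram of invasion events, the occupancy of the battleground interval
#' between the two optima versus outside it (hyper-maladaptation), and the
#' per-agent maladaptation, under both event and proposal weighting.
#'
#' @param seed Root seed.
#' @param n_events Number of invasion events.
#' @param d Distance between the optima.
#' @param p Probability a mutation is governed by agent A.
#' @param box_halfwidth Half-width of the symmetric box.
#' @param burn_in Events discarded before the equilibrium summaries
#'   (default: first half).
#' @param breaks Histogram bins (count or break vector).
#' @return A list of class `"gc_experiment"` with elements `trajectory`,
#'   `histogram`, `occupancy` (data frame, one row per weighting), and
#'   `maladaptation` (list with `event` and `proposal` summaries).
#' @examples
#' \donttest{
#' res <- exp_1d_conflict(seed = 1, n_events = 5000)
#' res$occupancy
#' }
#' @export
exp_1d_conflict <- function(seed = 1L, n_events = 150000L, d = 1, p = 0.5,
                            box_halfwidth = 10 * d, burn_in = NULL,
                            breaks = 80L) {
  cfg <- conflict_config(n_dims = 1, d = d, p = p,
                         box_halfwidth = box_halfwidth, seed = seed)
  traj <- run_dynamics(cfg, n_events)
  battleground <- region_interval(cfg$agent_a$point, cfg$agent_b$point)
  occ <- do.call(rbind, lapply(c("event", "proposal"), function(wt) {
    o <- occupancy_probability(traj, battleground, burn_in = burn_in,
                               weighting = wt)
    data.frame(weighting = wt, inside = o$probability,
               outside = 1 - o$probability, se = o$standard_error)
  }))
  mal <- list(event = maladaptation_summary(traj, burn_in, "event"),
              proposal = maladaptation_summary(traj, burn_in, "proposal"))
  hist <- equilibrium_histogram(traj, breaks = breaks, burn_in = burn_in)
  structure(list(experiment = "conflict1d", config = cfg, trajectory = traj,
                 histogram = hist, occupancy = occ, maladaptation = mal),
            class = "gc_experiment")
}

# Endpoint statistics of one replicate. `overall` is the expected Euclidean
# distance from the optimum governing the next incoming mutation (A with
# probability p), i.e. p*dist_a + (1-p)*dist_b: the per-party distance that
# the midpoint (d/2) and capitulation (d) benchmarks refer to. Conditioning
# instead on the governor of the *recorded* invasion would bias the distance
# low (that invasion just moved the phenotype into its governor's beneficial
# ball). `per_dim` is the mean per-coordinate deviation from the recorded
# invasion's governing objective, the within-dimension maladaptation of the
# invasion snapshot.
.endpoint_stats <- function(traj) {
  rec <- traj$records[nrow(traj$records), ]
  n <- traj$config$space$n_dims
  p <- traj$config$p
  x <- as.numeric(rec[paste0("x", seq_len(n))])
  o <- if (rec$governor == "A") traj$config$agent_a$point
       else traj$config$agent_b$point
  c(overall = p * rec$dist_a + (1 - p) * rec$dist_b,
    per_dim = mean(abs(x - o)),
    to_a = rec$dist_a, to_b = rec$dist_b)
}

.endpoint_sweep <- function(n_grid, seeds, n_events, build_cfg) {
  rows <- lapply(seq_along(n_grid), function(i) {
    n <- n_grid[i]
    stats_mat <- vapply(seq_len(ncol(seeds)), function(r) {
      traj <- run_dynamics(build_cfg(n, seeds[i, r]), n_events)
      .endpoint_stats(traj)
    }, numeric(4))
    m <- rowMeans(stats_mat)
    se <- apply(stats_mat, 1L, stats::sd) / sqrt(ncol(seeds))
    data.frame(n_dims = n,
               mean = m["overall"], se = se["overall"],
               per_dim_mean = m["per_dim"], per_dim_se = se["per_dim"],
               dist_a_mean = m["to_a"], dist_a_se = se["to_a"],
               dist_b_mean = m["to_b"], dist_b_se = se["to_b"],
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Cost of complexity under full pleiotropy
#'
#' For each dimensionality in `n_grid`, runs `n_replicates` independent
#' trajectories of `n_events` invasion events and records the endpoint
#' distance to the governing optimum (and the mean per-dimension deviation),
#' then fits log-log scaling exponents. Under full pleiotropy the
#' per-dimension maladaptation is approximately constant in the
#' dimensionality while the overall maladaptation grows like its square root
#' — the conflict-driven cost of complexity.
#'
#' @param seed Root seed.
#' @param n_grid Dimensionalities to sweep.
#' @param n_events Invasion events per replicate (endpoint design).
#' @param n_replicates Replicates per dimensionality.
#' @param d,p,box_halfwidth,engine Model geometry (see [conflict_config()]).
#' @param mutation_mode `"pleiotropic"` (the default) or `"modular"`.
#' @return A list of class `"gc_experiment"` with `table` (one row per
#'   dimensionality), `scaling_overall` and `scaling_per_dimension`
#'   ([scaling_fit()]s).
#' @examples
#' \donttest{
#' res <- exp_dimension_scaling(seed = 1, n_grid = c(1, 2, 4),
#'                              n_replicates = 50)
#' res$scaling_overall$exponent
#' }
#' @export
exp_dimension_scaling <- function(seed = 1L, n_grid = c(1, 2, 4, 8, 16),
                                  n_events = 100L, n_replicates = 500L,
                                  d = 1, p = 0.5, box_halfwidth = 10 * d,
                                  mutation_mode = "pleiotropic",
                                  engine = "auto") {
  stopifnot(length(n_grid) >= 1L, n_replicates >= 1L)
  seeds <- matrix(.replicate_seeds(seed, length(n_grid) * n_replicates),
                  nrow = length(n_grid))
  tab <- .endpoint_sweep(n_grid, seeds, n_events, function(n, s) {
    conflict_config(n_dims = n, d = d, p = p, box_halfwidth = box_halfwidth,
                    mutation_mode = mutation_mode, seed = s, engine = engine)
  })
  fits <- if (length(unique(n_grid)) >= 3L) {
    list(overall = scaling_fit(tab),
         per_dim = scaling_fit(data.frame(n_dims = tab$n_dims,
                                          mean = tab$per_dim_mean,
                                          se = tab$per_dim_se)))
  } else list(overall = NULL, per_dim = NULL)
  structure(list(experiment = "scaling", mutation_mode = mutation_mode,
                 table = tab,
                 scaling_overall = fits$overall,
                 scaling_per_dimension = fits$per_dim),
            class = "gc_experiment")
}

#' Modularity abolishes the conflict-driven cost of complexity
#'
#' Three components: (i) the endpoint dimensionality sweep of
#' [exp_dimension_scaling()] under full modularity — the overall
#' maladaptation is approximately constant in the dimensionality; (ii) a
#' 2D convergence demonstration started with the uncontested axis displaced
#' by `demo_offset`, whose deviation shrinks monotonically toward zero
#' (mutational modularity lets uncontested traits reach their shared optimum
#' and stay there); (iii) a comparison of the conflict-axis marginal
#' histogram of a long 2D modular run against a matched 1D run — the
#' equilibrium recovers that of the lower-dimensional model.
#'
#' @param seed Root seed.
#' @param n_grid,n_events,n_replicates Endpoint sweep design.
#' @param d,p,box_halfwidth Model geometry.
#' @param demo_n_events Events in the 2D convergence demonstration.
#' @param demo_offset Initial displacement of the uncontested axis.
#' @param marginal_n_events Events in each of the marginal-comparison runs.
#' @param breaks Bins for the marginal comparison.
#' @return A list of class `"gc_experiment"` with `table`,
#'   `scaling_overall`, `scaling_per_dimension`, `demo` (trajectory +
#'   final uncontested-axis deviation), and `marginal` (common-break
#'   histograms of the 2D modular conflict axis and the 1D model, with the
#'   sup bin-mass discrepancy in combined-SE units).
#' @examples
#' \donttest{
#' res <- exp_modularity(seed = 1, n_grid = c(1, 2, 4), n_replicates = 50,
#'                       demo_n_events = 2000, marginal_n_events = 5000)
#' res$demo$final_offaxis_deviation
#' }
#' @export
exp_modularity <- function(seed = 1L, n_grid = c(1, 2, 4, 8, 16),
                           n_events = 100L, n_replicates = 500L,
                           d = 1, p = 0.5, box_halfwidth = 10 * d,
                           demo_n_events = 10000L, demo_offset = d,
                           marginal_n_events = 150000L, breaks = 80L) {
  sub <- .replicate_seeds(seed, 4L)
  scal <- exp_dimension_scaling(seed = sub[1L], n_grid = n_grid,
                                n_events = n_events,
                                n_replicates = n_replicates, d = d, p = p,
                                box_halfwidth = box_halfwidth,
                                mutation_mode = "modular")
  demo_cfg <- conflict_config(n_dims = 2, d = d, p = p,
                              box_halfwidth = box_halfwidth,
                              mutation_mode = "modular",
                              initial = c(0, demo_offset), seed = sub[2L])
  demo_traj <- run_dynamics(demo_cfg, demo_n_events)
  offaxis <- abs(demo_traj$records$x2)
  mod2 <- run_dynamics(conflict_config(n_dims = 2, d = d, p = p,
                                       box_halfwidth = box_halfwidth,
                                       mutation_mode = "modular",
                                       seed = sub[3L]), marginal_n_events)
  one <- run_dynamics(conflict_config(n_dims = 1, d = d, p = p,
                                      box_halfwidth = box_halfwidth,
                                      seed = sub[4L]), marginal_n_events)
  h2 <- equilibrium_histogram(mod2, breaks = breaks, axis = 1L)
  h1 <- equilibrium_histogram(one, breaks = breaks, axis = 1L)
  diff <- abs(h2$mass - h1$mass)
  se <- sqrt(h2$se^2 + h1$se^2)
  nz <- se > 0 | diff > 0
  sup_z <- if (any(nz)) max(diff[nz] / pmax(se[nz], .Machine$double.eps))
           else 0
  structure(list(experiment = "modularity",
                 table = scal$table,
                 scaling_overall = scal$scaling_overall,
                 scaling_per_dimension = scal$scaling_per_dimension,
                 demo = list(trajectory = demo_traj,
                             offaxis_deviation = offaxis,
                             final_offaxis_deviation = offaxis[length(offaxis)]),
                 marginal = list(modular_2d = h2, one_dimensional = h1,
                                 sup_discrepancy_se_units = sup_z)),
            class = "gc_experiment")
}

#' Maladaptation across the balance of power
#'
#' For each control probability `p` in the grid, runs a long trajectory and
#' reports the event-weighted mean distance of the phenotype from the
#' governing optimum — the optimum governing an incoming mutation, i.e.
#' `p * dist_a + (1 - p) * dist_b`, the same overall-maladaptation statistic
#' as the dimensionality experiments. It is maximal when the two agents
#' exert equal control (`p = 1/2`), declines monotonically as either agent's
#' control grows, and vanishes at `p` of 0 or 1 (Fisher's single-optimum
#' limit).
#'
#' @param seed Root seed.
#' @param p_grid Grid of control probabilities (symmetric about 0.5).
#' @param n_events Invasion events per grid point.
#' @param d,box_halfwidth Model geometry.
#' @param burn_in Events discarded (default: first half).
#' @return A list of class `"gc_experiment"` with `table` (columns `p`,
#'   `maladaptation`, `se`), `argmax_p`, and monotonicity flags on each side
#'   of the maximum.
#' @examples
#' \donttest{
#' res <- exp_p_sweep(seed = 1, p_grid = c(0.1, 0.5, 0.9), n_events = 4000)
#' res$argmax_p
#' }
#' @export
exp_p_sweep <- function(seed = 1L, p_grid = seq(0.1, 0.9, by = 0.1),
                        n_events = 20000L, d = 1, box_halfwidth = 10 * d,
                        burn_in = NULL) {
  stopifnot(length(p_grid) >= 1L, all(p_grid >= 0 & p_grid <= 1))
  seeds <- .replicate_seeds(seed, length(p_grid))
  rows <- lapply(seq_along(p_grid), function(i) {
    p <- p_grid[i]
    cfg <- conflict_config(n_dims = 1, d = d, p = p,
                           box_halfwidth = box_halfwidth, seed = seeds[i])
    traj <- run_dynamics(cfg, n_events)
    win <- .traj_window(traj, burn_in, "event")
    mix <- p * traj$records$dist_a[win$idx] +
      (1 - p) * traj$records$dist_b[win$idx]
    est <- mean(mix)
    se <- .block_boot_se(function(pos) mean(mix[pos]), length(mix))
    data.frame(p = p, maladaptation = est, se = se)
  })
  tab <- do.call(rbind, rows)
  i_max <- which.max(tab$maladaptation)
  left <- tab$maladaptation[seq_len(i_max)]
  right <- tab$maladaptation[seq.int(i_max, nrow(tab))]
  structure(list(experiment = "psweep", table = tab,
                 argmax_p = tab$p[i_max],
                 increasing_to_max = !is.unsorted(left),
                 decreasing_from_max = !is.unsorted(rev(right))),
            class = "gc_experiment")
}

# Windowed occupancy of the epsilon-balls around both pessima. Windows beyond
# the recorded trajectory (possible after absorption at the boundary) are
# filled with the frozen final state's membership.
.pessima_windows <- function(traj, q_a, q_b, epsilon, window, n_windows) {
  X <- traj_states(traj)
  n_rec <- nrow(X)
  in_a <- .region_contains(region_ball(q_a, epsilon), X)
  in_b <- .region_contains(region_ball(q_b, epsilon), X)
  out <- data.frame(window = seq_len(n_windows), occ_a = NA_real_,
                    occ_b = NA_real_, n_observed = 0L)
  for (wdx in seq_len(n_windows)) {
    i0 <- (wdx - 1L) * window + 1L
    i1 <- min(wdx * window, n_rec)
    if (i0 <= n_rec) {
      idx <- seq.int(i0, i1)
      pad <- window - length(idx)
      out$occ_a[wdx] <- (sum(in_a[idx]) + pad * in_a[n_rec]) / window
      out$occ_b[wdx] <- (sum(in_b[idx]) + pad * in_b[n_rec]) / window
      out$n_observed[wdx] <- length(idx)
    } else {
      out$occ_a[wdx] <- as.numeric(in_a[n_rec])
      out$occ_b[wdx] <- as.numeric(in_b[n_rec])
    }
  }
  out
}

#' Pessimum-avoidance dynamics: escape versus conflict-driven persistence
#'
#' Compares three pessimum-avoiding scenarios in 1D. With a single agent the
#' phenotype moves monotonically away from the pessimum, so the probability
#' of remaining close to it tends to zero. With two agents whose pessima are
#' placed so that they also disagree about the least-worst phenotype (each
#' agent's most-distant boundary point adjoins the rival's pessimum), the
#' tug-of-war keeps a substantial probability of the phenotype remaining
#' close to each pessimum in the long run. Two agents sharing one pessimum
#' behave like the single agent.
#'
#' The space here is a box of half-width `box_halfwidth` (default `1 * d`,
#' comparable to the pessima separation: in a space much larger than the
#' separation, both agents' least-worst corners lie far from both pessima
#' and near-pessimum occupancy vanishes for a different, trivial reason).
#'
#' @param seed Root seed.
#' @param d Distance between the two pessima (placed at `-d/2`, `+d/2`).
#' @param box_halfwidth Half-width of the box.
#' @param epsilon Radius of the "close to the pessimum" ball.
#' @param n_events Invasion events per scenario.
#' @param window Events per occupancy window.
#' @param p Balance of power in the two-agent scenarios.
#' @param start_offset Initial displacement from agent A's pessimum.
#' @return A list of class `"gc_experiment"` with `windows` (long-format
#'   windowed occupancy per scenario) and `final` (final-window occupancies
#'   and the two-agent / single-agent ratio).
#' @examples
#' \donttest{
#' res <- exp_pessima(seed = 1, n_events = 4000)
#' res$final
#' }
#' @export
exp_pessima <- function(seed = 1L, d = 1, box_halfwidth = 1 * d,
                        epsilon = 0.25 * d, n_events = 20000L,
                        window = 1000L, p = 0.5, start_offset = 0.05 * d) {
  q_a <- -d / 2
  q_b <- +d / 2
  sp <- space_spec(1, halfwidth = box_halfwidth)
  start <- q_a + start_offset
  seeds <- .replicate_seeds(seed, 3L)
  mk <- function(pt_a, pt_b, p_use, s) {
    model_config(sp,
                 agent_objective("A", pt_a, mode = "avoid_pessimum"),
                 agent_objective("B", pt_b, mode = "avoid_pessimum"),
                 p = p_use, initial = start, seed = s,
                 max_proposals = 1e5)
  }
  n_windows <- ceiling(n_events / window)
  scen <- list(
    single = mk(q_a, q_a, 1, seeds[1L]),
    disagreeing = mk(q_a, q_b, p, seeds[2L]),
    identical = mk(q_a, q_a, p, seeds[3L]))
  windows <- do.call(rbind, lapply(names(scen), function(nm) {
    traj <- run_dynamics(scen[[nm]], n_events, on_absorbed = "truncate")
    w <- .pessima_windows(traj, q_a, q_b, epsilon, window, n_windows)
    cbind(scenario = nm, w)
  }))
  fin <- windows[windows$window == n_windows, ]
  single_final <- fin$occ_a[fin$scenario == "single"]
  dis_a <- fin$occ_a[fin$scenario == "disagreeing"]
  dis_b <- fin$occ_b[fin$scenario == "disagreeing"]
  structure(list(experiment = "pessima", epsilon = epsilon,
                 windows = windows,
                 final = data.frame(
                   single_near_a = single_final,
                   disagreeing_near_a = dis_a,
                   disagreeing_near_b = dis_b,
                   identical_near_a = fin$occ_a[fin$scenario == "identical"],
                   ratio_vs_single = min(dis_a, dis_b) /
                     max(single_final, 1 / n_events))),
            class = "gc_experiment")
}

#' Is conflict worth it? Compromise and relinquishment accounting
#'
#' Quantifies, in units of the inter-optimum distance `d`, what each party
#' gets out of the conflict: (i) the long-run mean distance of the phenotype
#' from each optimum under conflict; (ii) the distance under a midpoint
#' settlement (`d/2` exactly); (iii) the distance under capitulation to the
#' adversary's optimum (`d` exactly). In 1D the conflict average exceeds
#' `d/2` (both parties would do better splitting the difference) and from two
#' dimensions up it exceeds `d` (each party would do better capitulating).
#' Yet the myopic comparison (iv) shows why neither party quits: at every
#' current phenotype, the exact expected distance to one's own optimum after
#' the next invasion is no worse when participating than when relinquishing
#' all control to the adversary.
#'
#' @param seed Root seed.
#' @param d Distance between the optima.
#' @param p Balance of power.
#' @param dims Dimensionalities for the long-run comparison.
#' @param n_events Events per long-run trajectory.
#' @param box_halfwidth Model geometry.
#' @param z_grid Grid of current phenotypes (conflict axis) for the myopic
#'   next-step comparison (1D, exact interval arithmetic).
#' @param burn_in Events discarded (default: first half).
#' @return A list of class `"gc_experiment"` with `longrun` (per
#'   dimensionality: mean distance to each optimum, with the `d/2` and `d`
#'   benchmarks) and `myopic` (per grid point: expected own-optimum distance
#'   after the next invasion, participating vs relinquishing).
#' @examples
#' \donttest{
#' res <- exp_compromise(seed = 1, dims = 1, n_events = 4000)
#' head(res$myopic)
#' }
#' @export
exp_compromise <- function(seed = 1L, d = 1, p = 0.5, dims = c(1, 2),
                           n_events = 100000L, box_halfwidth = 10 * d,
                           z_grid = seq(-2 * d, 2 * d, by = 0.25 * d),
                           burn_in = NULL) {
  seeds <- .replicate_seeds(seed, length(dims))
  longrun <- do.call(rbind, lapply(seq_along(dims), function(i) {
    cfg <- conflict_config(n_dims = dims[i], d = d, p = p,
                           box_halfwidth = box_halfwidth, seed = seeds[i])
    s <- maladaptation_summary(run_dynamics(cfg, n_events), burn_in, "event")
    data.frame(n_dims = dims[i],
               conflict_dist_a = s$per_agent_overall["a"],
               conflict_dist_a_se = s$per_agent_overall_se["a"],
               conflict_dist_b = s$per_agent_overall["b"],
               conflict_dist_b_se = s$per_agent_overall_se["b"],
               midpoint_settlement = d / 2,
               adversary_optimum = d,
               row.names = NULL)
  }))
  cfg1 <- conflict_config(n_dims = 1, d = d, p = p,
                          box_halfwidth = box_halfwidth, seed = seed)
  myopic <- do.call(rbind, lapply(z_grid, function(z) {
    sets <- .agent_sets_1d(z, cfg1)
    m_a <- sets$a$measure
    m_b <- sets$b$measure
    denom <- p * m_a + (1 - p) * m_b
    stay <- abs(z - cfg1$agent_a$point)
    e_a <- .iv_expected_absdist(sets$a$intervals, cfg1$agent_a$point)
    e_b <- .iv_expected_absdist(sets$b$intervals, cfg1$agent_a$point)
    participate <- if (denom <= 0) stay else {
      w_a <- p * m_a / denom
      (if (m_a > 0) w_a * e_a else 0) + (if (m_b > 0) (1 - w_a) * e_b else 0)
    }
    relinquish <- if (m_b > 0) e_b else stay
    data.frame(z = z, participating = participate, relinquishing = relinquish)
  }))
  structure(list(experiment = "compromise", longrun = longrun,
                 myopic = myopic),
            class = "gc_experiment")
}

#' @export
print.gc_experiment <- function(x, ...) {
  cat(sprintf("geomconflict experiment: %s\n", x$experiment))
  tab <- x$table %||% x$occupancy %||% x$longrun %||% x$final
  if (!is.null(tab)) print(tab)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
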