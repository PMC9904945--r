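#' Is a mutation beneficial for an agent?
#'
#' Under `seek_optimum` a mutant is beneficial iff it is strictly closer to
#' the agent's objective point than the current phenotype; under
#' `avoid_pessimum` iff strictly farther. Exact distance ties are not
#' beneficial (strict-improvement rule).
#'
#' @param current,mutant Numeric vectors of length `n_dims`.
#' @param objective An [agent_objective()].
#' @return Logical scalar.
#' @examples
#' a <- agent_objective("A", -0.5)
#' is_beneficial(0.4, 0.1, a)  # TRUE: 0.6 < 0.9
#' @export
is_beneficial <- function(current, mutant, objective) {
  stopifnot(inherits(objective, "agent_objective"))
  if (length(current) != length(mutant) ||
      length(current) != length(objective$point))
    stop("dimension mismatch between `current`, `mutant` and the objective")
  d2_cur <- sum((current - objective$point)^2)
  d2_mut <- sum((mutant - objective$point)^2)
  if (objective$mode == "seek_optimum") d2_mut < d2_cur else d2_mut > d2_cur
}

#' Draw one mutation proposal
#'
#' Proposals are uniform over the phenotype space. Pleiotropic mode redraws
#' every coordinate independently of the current phenotype; modular mode picks
#' one axis uniformly at random and redraws only that coordinate. Sampling is
#' performed in normalized unit coordinates and affinely mapped to the box, so
#' that runs with matched seeds on rescaled spaces produce exactly rescaled
#' proposals.
#'
#' Stream protocol (per proposal, consuming R's global RNG): pleiotropic draws
#' `n_dims` uniforms (one per coordinate, in axis order); modular draws one
#' uniform for the axis choice, then one for the new coordinate.
#'
#' @param space A [space_spec()].
#' @param current Numeric vector, the current phenotype (used by modular mode).
#' @param mode `"pleiotropic"` or `"modular"`.
#' @return Numeric vector, the proposed mutant phenotype.
#' @examples
#' set.seed(1)
#' propose_mutant(space_spec(2), c(0, 0), "pleiotropic")
#' @export
propose_mutant <- function(space, current,
                           mode = c("pleiotropic", "modular")) {
  mode <- match.arg(mode)
  stopifnot(inherits(space, "space_spec"))
  n <- space$n_dims
  if (length(current) != n) stop("`current` must have length n_dims")
  if (!.inside_space(space, current))
    stop("`current` lies outside the space bounds")
  w <- .space_widths(space)
  if (mode == "pleiotropic") {
    space$lower + stats::runif(n) * w
  } else {
    ax <- min(n, 1L + floor(stats::runif(1) * n))
    mutant <- current
    mutant[ax] <- space$lower[ax] + stats::runif(1) * w[ax]
    mutant
  }
}

.absorbed <- function(message, state, proposals_tried = NA_real_) {
  stop(structure(
    class = c("geomconflict_absorbed", "error", "condition"),
    list(message = message, call = sys.call(-1), state = state,
         proposals_tried = proposals_tried)))
}

# Literal propose/reject engine. Per proposal the stream consumes: one uniform
# for the governor, then the mutant draws of propose_mutant(). Proposals are
# generated in row-wise batches of runif(k * per_proposal), which consumes the
# stream in exactly the same order as drawing them one at a time.
.step_rejection <- function(current, cfg) {
  sp <- cfg$space
  n <- sp$n_dims
  w <- .space_widths(sp)
  seek <- cfg$objective_mode == "seek_optimum"
  pt_a <- cfg$agent_a$point
  pt_b <- cfg$agent_b$point
  cur_d2a <- sum((current - pt_a)^2)
  cur_d2b <- sum((current - pt_b)^2)
  modular <- cfg$mutation_mode == "modular"
  per <- if (modular) 3L else n + 1L
  tried <- 0
  k <- 32L
  repeat {
    k_use <- as.integer(min(k, max(1, cfg$max_proposals - tried)))
    # column j of U holds the uniforms of proposal j, in draw order, so the
    # stream is consumed exactly as by one-at-a-time proposals
    U <- matrix(stats::runif(k_use * per), nrow = per)
    gov_a <- U[1L, ] < cfg$p
    if (modular) {
      ax <- pmin(n, 1L + floor(U[2L, ] * n))
      newx <- sp$lower[ax] + U[3L, ] * w[ax]
      d2a <- cur_d2a - (current[ax] - pt_a[ax])^2 + (newx - pt_a[ax])^2
      d2b <- cur_d2b - (current[ax] - pt_b[ax])^2 + (newx - pt_b[ax])^2
    } else {
      X <- sp$lower + U[-1L, , drop = FALSE] * w
      Da <- X - pt_a
      Db <- X - pt_b
      d2a <- .colSums(Da * Da, n, k_use)
      d2b <- .colSums(Db * Db, n, k_use)
    }
    acc <- if (seek) {
      (gov_a & d2a < cur_d2a) | (!gov_a & d2b < cur_d2b)
    } else {
      (gov_a & d2a > cur_d2a) | (!gov_a & d2b > cur_d2b)
    }
    i <- which.max(acc)
    if (acc[i]) {
      if (modular) {
        x <- current
        x[ax[i]] <- newx[i]
        # recompute distances from coordinates to avoid drift in the
        # incremental update over long trajectories
        d2a_i <- sum((x - pt_a)^2)
        d2b_i <- sum((x - pt_b)^2)
      } else {
        x <- X[, i]
        d2a_i <- d2a[i]
        d2b_i <- d2b[i]
      }
      return(list(governor = if (gov_a[i]) "A" else "B",
                  proposals = tried + i,
                  phenotype = x,
                  dist_a = sqrt(d2a_i), dist_b = sqrt(d2b_i)))
    }
    tried <- tried + k_use
    if (tried >= cfg$max_proposals)
      .absorbed(sprintf(
        "no beneficial mutation accepted within %g proposals (stuck state)",
        cfg$max_proposals), current, tried)
    k <- min(k * 2L, 4096L)
  }
}

.unit_ball_volume <- function(n) pi^(n / 2) / gamma(n / 2 + 1)

# Beneficial measure of ball(center, radius) clipped to the box, relative to
# the box volume, computed in units of the first axis width so that the value
# is bit-identical under a global rescaling of the space. When the ball is not
# contained in the box the clipped fraction is estimated from 128 uniform ball
# draws (consumes the RNG; rare under the default geometry).
.ball_measure_rel <- function(center, radius, space) {
  n <- space$n_dims
  ref <- space$upper[1L] - space$lower[1L]
  w_rel <- (space$upper - space$lower) / ref
  vol_rel <- prod(w_rel)
  rho <- radius / ref
  m_rel <- .unit_ball_volume(n) * rho^n
  inside <- all(center - radius >= space$lower) &&
    all(center + radius <= space$upper)
  if (!inside) {
    k <- 128L
    G <- matrix(stats::rnorm(k * n), k, n)
    nr <- sqrt(rowSums(G * G))
    rad <- radius * stats::runif(k)^(1 / n)
    P <- matrix(center, k, n, byrow = TRUE) + (rad / nr) * G
    ok <- rowSums(
      P >= matrix(space$lower, k, n, byrow = TRUE) &
      P <= matrix(space$upper, k, n, byrow = TRUE)) == n
    m_rel <- m_rel * mean(ok)
  }
  min(m_rel, vol_rel) / vol_rel
}

.sample_ball_box <- function(center, radius, space) {
  n <- space$n_dims
  for (i in seq_len(1e5)) {
    g <- stats::rnorm(n)
    nr <- sqrt(sum(g * g))
    if (nr == 0) next
    x <- center + (radius * stats::runif(1)^(1 / n)) * (g / nr)
    if (.inside_space(space, x)) return(x)
  }
  stop("failed to sample a point in ball intersect box (degenerate geometry)")
}

# Equivalent-in-law engine for pleiotropic optimum-seeking models: the mutant
# accepted by the literal propose/reject loop is uniform on the governor's
# beneficial ball intersected with the box; the governor of the accepted
# mutation is A with probability p*m_A / (p*m_A + (1-p)*m_B); and the number
# of proposals consumed is geometric with success probability
# (p*m_A + (1-p)*m_B) / vol(box), drawn here by inverse CDF (double-valued,
# so astronomically long waits in high dimension do not overflow).
# Stream protocol: one uniform for the governor, one for the geometric
# proposal count, then the ball draws (plus clip-fraction draws when a
# beneficial ball overhangs the box boundary).
.step_direct <- function(current, cfg) {
  sp <- cfg$space
  pt_a <- cfg$agent_a$point
  pt_b <- cfg$agent_b$point
  r_a <- sqrt(sum((current - pt_a)^2))
  r_b <- sqrt(sum((current - pt_b)^2))
  m_a <- if (r_a > 0) .ball_measure_rel(pt_a, r_a, sp) else 0
  m_b <- if (r_b > 0) .ball_measure_rel(pt_b, r_b, sp) else 0
  w_a <- cfg$p * m_a
  w_b <- (1 - cfg$p) * m_b
  tot <- w_a + w_b
  if (tot <= 0)
    .absorbed("no strictly beneficial mutation exists from this state",
              current)
  gov_a <- stats::runif(1) < w_a / tot
  p_acc <- min(tot, 1)
  u <- stats::runif(1)
  proposals <- if (p_acc >= 1) 1 else 1 + floor(log(u) / log1p(-p_acc))
  x <- if (gov_a) .sample_ball_box(pt_a, r_a, sp)
       else .sample_ball_box(pt_b, r_b, sp)
  list(governor = if (gov_a) "A" else "B",
       proposals = proposals,
       phenotype = x,
       dist_a = sqrt(sum((x - pt_a)^2)),
       dist_b = sqrt(sum((x - pt_b)^2)))
}

.resolve_engine <- function(cfg) {
  if (cfg$engine != "auto") return(cfg$engine)
  if (cfg$mutation_mode != "pleiotropic" ||
      cfg$objective_mode != "seek_optimum") return("rejection")
  # direct sampling where the literal loop is infeasible: the per-proposal
  # acceptance probability is a ball-to-box volume ratio, astronomically
  # small in higher dimension and geometrically shrinking in the
  # single-party limit
  if (cfg$space$n_dims >= 2L || cfg$p == 0 || cfg$p == 1) "direct"
  else "rejection"
}

#' Run one invasion event
#'
#' Repeatedly draws a governor (agent A with probability `p`, else B) and a
#' mutation proposal until one is beneficial for its governor; the accepted
#' mutant fixes immediately (Fisher's certain-fixation convention: every
#' beneficial mutation proceeds to fixation, so the invasion event is the unit
#' of simulated time). Uses R's global RNG stream; seed it (or call via
#' [run_dynamics()]) for reproducibility.
#'
#' Two engines are available. `"rejection"` is the literal bounded
#' propose/reject loop. `"direct"` draws the accepted mutant from its exact
#' conditional law (uniform on the governor's beneficial region), the governor
#' from its exact conditional weights, and the proposal count from its exact
#' geometric law; it is equivalent in distribution and is the only feasible
#' route for pleiotropic models in higher dimensions, where the acceptance
#' probability per proposal (the ball-to-box volume ratio) is astronomically
#' small.
#'
#' @param current Numeric vector, current phenotype (inside the space).
#' @param config A [model_config()].
#' @return A one-event record: list with `governor` (`"A"`/`"B"`),
#'   `proposals` (number of proposals drawn until acceptance, inclusive),
#'   `phenotype`, `dist_a`, `dist_b`.
#' @section Absorbed states: when no strictly beneficial mutant exists (e.g.
#'   `p = 1` with the phenotype exactly at agent A's optimum), or the
#'   rejection loop exceeds `max_proposals`, an error of class
#'   `"geomconflict_absorbed"` is raised carrying the stuck state.
#' @examples
#' cfg <- conflict_config(seed = 1)
#' set.seed(1)
#' invasion_step(0, cfg)
#' @export
invasion_step <- function(current, config) {
  stopifnot(inherits(config, "model_config"))
  current <- as.numeric(current)
  if (length(current) != config$space$n_dims)
    stop("`current` must have length n_dims")
  if (!.inside_space(config$space, current))
    stop("`current` lies outside the space bounds")
  if (.resolve_engine(config) == "direct") .step_direct(current, config)
  else .step_rejection(current, config)
}

#' Simulate a trajectory of invasion events
#'
#' Applies [invasion_step()] `n_events` times from the configured initial
#' phenotype, seeding the RNG from `config$seed` first, so the trajectory is a
#' deterministic function of the configuration.
#'
#' @param config A [model_config()].
#' @param n_events Positive integer, number of invasion events to simulate.
#' @param init_rng Seed the RNG from `config$seed` first (default `TRUE`; set
#'   `FALSE` to continue an existing stream, e.g. inside replicate drivers).
#' @param on_absorbed `"error"` (default) or `"truncate"`: what to do when a
#'   step finds no beneficial mutant within the proposal budget — a genuinely
#'   stuck state, e.g. the single-party limit closing in on its optimum.
#'   `"truncate"` returns the recorded prefix (with attribute
#'   `absorbed = TRUE`): the phenotype is frozen from there on.
#' @return An object of class `"gc_trajectory"`: list with `config`,
#'   `initial`, and `records`, a data frame with columns `event`, `governor`,
#'   `proposals`, `x1...xn`, `dist_a`, `dist_b`.
#' @section Absorbed states: if a step raises an absorbed error, the error is
#'   re-raised with the partial trajectory attached as the condition field
#'   `$trajectory` (or the prefix is returned, under
#'   `on_absorbed = "truncate"`).
#' @examples
#' traj <- run_dynamics(conflict_config(seed = 7), 30)
#' head(traj$records)
#' @export
run_dynamics <- function(config, n_events, init_rng = TRUE,
                         on_absorbed = c("error", "truncate")) {
  on_absorbed <- match.arg(on_absorbed)
  stopifnot(inherits(config, "model_config"))
  n_events <- as.integer(n_events)
  if (is.na(n_events) || n_events < 1L) stop("`n_events` must be >= 1")
  if (init_rng) set.seed(config$seed)
  n <- config$space$n_dims
  X <- matrix(NA_real_, n_events, n)
  governor <- character(n_events)
  proposals <- numeric(n_events)
  dist_a <- numeric(n_events)
  dist_b <- numeric(n_events)
  cur <- config$initial
  step_fn <- if (.resolve_engine(config) == "direct") .step_direct
             else .step_rejection
  i <- 0L
  absorbed <- tryCatch({
    while (i < n_events) {
      rec <- step_fn(cur, config)
      i <- i + 1L
      X[i, ] <- rec$phenotype
      governor[i] <- rec$governor
      proposals[i] <- rec$proposals
      dist_a[i] <- rec$dist_a
      dist_b[i] <- rec$dist_b
      cur <- rec$phenotype
    }
    NULL
  }, geomconflict_absorbed = function(e) e)
  if (!is.null(absorbed)) {
    partial <- .make_trajectory(config, X, governor, proposals,
                                dist_a, dist_b, i)
    if (on_absorbed == "truncate") {
      attr(partial, "absorbed") <- TRUE
      return(partial)
    }
    absorbed$trajectory <- partial
    stop(absorbed)
  }
  .make_trajectory(config, X, governor, proposals, dist_a, dist_b, n_events)
}

.make_trajectory <- function(config, X, governor, proposals,
                             dist_a, dist_b, n_used) {
  keep <- seq_len(n_used)
  n <- config$space$n_dims
  Xk <- X[keep, , drop = FALSE]
  colnames(Xk) <- paste0("x", seq_len(n))
  records <- data.frame(event = keep,
                        governor = governor[keep],
                        proposals = proposals[keep])
  records <- cbind(records, as.data.frame(Xk))
  records$dist_a <- dist_a[keep]
  records$dist_b <- dist_b[keep]
  structure(list(config = config, initial = config$initial,
                 records = records),
            class = "gc_trajectory")
}

#' @export
print.gc_trajectory <- function(x, ...) {
  n <- nrow(x$records)
  cat(sprintf("trajectory: %d invasion events, %d-D %s model (p = %g)\n",
              n, x$config$space$n_dims, x$config$mutation_mode, x$config$p))
  if (n) {
    last <- x$records[n, ]
    cat(sprintf("  final distances: to a = %.4g, to b = %.4g\n",
                last$dist_a, last$dist_b))
  }
  invisible(x)
}

# Phenotype matrix (events x n_dims) of a trajectory.
traj_states <- function(traj) {
  n <- traj$config$space$n_dims
  as.matrix(traj$records[paste0("x", seq_len(n))])
}
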