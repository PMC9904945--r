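#' Define a finite phenotype space
#'
#' The phenotype space is a finite axis-aligned box in `n_dims` dimensions.
#' Mutation proposals are drawn uniformly over this box (fully pleiotropic
#' mode) or uniformly along a single axis of it (fully modular mode), so all
#' occupancy statistics depend on its extent; the box is therefore an explicit,
#' reported part of every model configuration.
#'
#' @param n_dims Positive integer, number of trait dimensions.
#' @param bounds Either `NULL` (symmetric box `[-halfwidth, halfwidth]` on
#'   every axis), a numeric vector `c(lo, hi)` recycled to all axes, or a
#'   2-row matrix with one column per axis (row 1 = lower, row 2 = upper).
#' @param halfwidth Half-width of the default symmetric box (used only when
#'   `bounds` is `NULL`).
#'
#' @return An object of class `"space_spec"` with elements `n_dims`, `lower`,
#'   `upper`.
#' @examples
#' space_spec(2, halfwidth = 10)
#' space_spec(1, bounds = c(-1, 1))
#' @export
space_spec <- function(n_dims, bounds = NULL, halfwidth = 10) {
  n_dims <- as.integer(n_dims)
  if (length(n_dims) != 1L || is.na(n_dims) || n_dims < 1L)
    stop("`n_dims` must be a single positive integer")
  if (is.null(bounds)) {
    if (!is.finite(halfwidth) || halfwidth <= 0)
      stop("`halfwidth` must be a positive finite number")
    lower <- rep(-halfwidth, n_dims)
    upper <- rep(halfwidth, n_dims)
  } else if (is.matrix(bounds)) {
    if (nrow(bounds) != 2L || ncol(bounds) != n_dims)
      stop("`bounds` matrix must be 2 x n_dims")
    lower <- bounds[1L, ]
    upper <- bounds[2L, ]
  } else {
    if (length(bounds) != 2L)
      stop("`bounds` vector must be c(lo, hi)")
    lower <- rep(bounds[1L], n_dims)
    upper <- rep(bounds[2L], n_dims)
  }
  if (!all(is.finite(lower)) || !all(is.finite(upper)))
    stop("all bounds must be finite")
  if (!all(lower < upper))
    stop("each axis must satisfy lo < hi")
  structure(list(n_dims = n_dims, lower = lower, upper = upper),
            class = "space_spec")
}

#' @export
print.space_spec <- function(x, ...) {
  cat(sprintf("phenotype space: %d-dimensional box\n", x$n_dims))
  cat(sprintf("  axis %d: [%g, %g]\n", seq_len(x$n_dims), x$lower, x$upper),
      sep = "")
  invisible(x)
}

.space_widths <- function(space) space$upper - space$lower

.space_volume <- function(space) prod(.space_widths(space))

.inside_space <- function(space, x) {
  all(x >= space$lower) && all(x <= space$upper)
}

#' Define an agent's objective
#'
#' Each agent either seeks an optimum (a mutation is beneficial iff it takes
#' the phenotype strictly closer to `point`) or avoids a pessimum (beneficial
#' iff strictly farther from `point`). Exact ties are never beneficial.
#'
#' @param label Agent identifier, `"A"` or `"B"`.
#' @param point Numeric vector, the optimum (or pessimum), inside the space.
#' @param mode `"seek_optimum"` or `"avoid_pessimum"`.
#'
#' @return An object of class `"agent_objective"`.
#' @examples
#' agent_objective("A", c(-0.5, 0))
#' agent_objective("B", 0.5, mode = "avoid_pessimum")
#' @export
agent_objective <- function(label = c("A", "B"), point,
                            mode = c("seek_optimum", "avoid_pessimum")) {
  label <- match.arg(label)
  mode <- match.arg(mode)
  point <- as.numeric(point)
  if (!all(is.finite(point))) stop("`point` must be finite")
  structure(list(label = label, point = point, mode = mode),
            class = "agent_objective")
}

#' @export
print.agent_objective <- function(x, ...) {
  cat(sprintf("agent %s: %s at (%s)\n", x$label,
              if (x$mode == "seek_optimum") "optimum" else "pessimum",
              paste(signif(x$point, 6), collapse = ", ")))
  invisible(x)
}

#' Assemble a two-agent model configuration
#'
#' Binds the phenotype space, both agents' objectives, the balance of power
#' `p` (probability that any given mutation is governed by agent A), the
#' mutation mode and the initial phenotype into a validated configuration.
#' The derived quantity `d`, the Euclidean distance between the two objective
#' points, is the natural unit for all maladaptation statistics.
#'
#' @param space A [space_spec()].
#' @param agent_a,agent_b [agent_objective()]s; both must share the same mode.
#' @param p Probability in `[0, 1]` that a mutation is governed by agent A.
#' @param mutation_mode `"pleiotropic"` (each mutation redraws every
#'   coordinate) or `"modular"` (each mutation redraws exactly one coordinate).
#' @param initial Numeric vector, starting phenotype (default: midpoint of the
#'   two objective points).
#' @param seed Integer seed; `run_dynamics()` seeds the RNG with it.
#' @param max_proposals Guard on the number of proposals per invasion event in
#'   the rejection engine; exceeding it raises an "absorbed" error.
#' @param engine `"auto"`, `"rejection"` (literal propose/reject loop) or
#'   `"direct"` (equivalent-in-law conditional sampler; see
#'   [invasion_step()]). `"auto"` picks `"direct"` for pleiotropic
#'   optimum-seeking models in 2+ dimensions and `"rejection"` otherwise.
#'
#' @return An object of class `"model_config"`.
#' @examples
#' sp <- space_spec(1, halfwidth = 10)
#' model_config(sp, agent_objective("A", -0.5), agent_objective("B", 0.5),
#'              p = 0.5, seed = 1)
#' @seealso [conflict_config()] for the default conflict geometry.
#' @export
model_config <- function(space, agent_a, agent_b, p = 0.5,
                         mutation_mode = c("pleiotropic", "modular"),
                         initial = NULL, seed = 1L, max_proposals = 1e6,
                         engine = c("auto", "rejection", "direct")) {
  mutation_mode <- match.arg(mutation_mode)
  engine <- match.arg(engine)
  stopifnot(inherits(space, "space_spec"),
            inherits(agent_a, "agent_objective"),
            inherits(agent_b, "agent_objective"))
  n <- space$n_dims
  if (length(agent_a$point) != n || length(agent_b$point) != n)
    stop("agent objective points must have length n_dims")
  if (!.inside_space(space, agent_a$point))
    stop("agent A objective point lies outside the space bounds")
  if (!.inside_space(space, agent_b$point))
    stop("agent B objective point lies outside the space bounds")
  if (agent_a$mode != agent_b$mode)
    stop("both agents must share the same objective mode")
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("`p` must be a single probability in [0, 1]")
  if (is.null(initial)) initial <- (agent_a$point + agent_b$point) / 2
  initial <- as.numeric(initial)
  if (length(initial) != n) stop("`initial` must have length n_dims")
  if (!.inside_space(space, initial))
    stop("`initial` phenotype lies outside the space bounds")
  if (!is.finite(max_proposals) || max_proposals < 1)
    stop("`max_proposals` must be a positive number")
  structure(list(
    space = space,
    agent_a = agent_a,
    agent_b = agent_b,
    p = as.numeric(p),
    mutation_mode = mutation_mode,
    objective_mode = agent_a$mode,
    initial = initial,
    seed = as.integer(seed),
    max_proposals = as.numeric(max_proposals),
    engine = engine,
    d = sqrt(sum((agent_a$point - agent_b$point)^2))
  ), class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(
    "two-agent geometric model: %d-D %s, %s, p = %g, d = %g, seed = %d\n",
    x$space$n_dims, x$mutation_mode, x$objective_mode, x$p, x$d, x$seed))
  invisible(x)
}

#' Default conflict geometry
#'
#' Convenience constructor for the canonical layout used throughout: objective
#' points at `(-d/2, 0, ..., 0)` and `(+d/2, 0, ..., 0)` so that the conflict
#' is confined to axis 1 and all other axes are uncontested; symmetric box of
#' half-width `box_halfwidth` (default `10 * d`) on every axis; initial
#' phenotype at the midpoint (the origin).
#'
#' @param n_dims Number of trait dimensions.
#' @param d Distance between the two objective points (the unit of all
#'   reported maladaptation statistics).
#' @param p Probability a mutation is governed by agent A.
#' @param mutation_mode,objective_mode,seed,max_proposals,engine See
#'   [model_config()] and [agent_objective()].
#' @param box_halfwidth Half-width of the symmetric box.
#' @param initial Starting phenotype (default: the origin/midpoint).
#'
#' @return A `"model_config"`.
#' @examples
#' conflict_config(n_dims = 2, d = 1, p = 0.5, seed = 42)
#' @export
conflict_config <- function(n_dims = 1, d = 1, p = 0.5,
                            mutation_mode = c("pleiotropic", "modular"),
                            objective_mode = c("seek_optimum",
                                               "avoid_pessimum"),
                            box_halfwidth = 10 * d, initial = NULL,
                            seed = 1L, max_proposals = 1e6,
                            engine = c("auto", "rejection", "direct")) {
  mutation_mode <- match.arg(mutation_mode)
  objective_mode <- match.arg(objective_mode)
  engine <- match.arg(engine)
  if (!is.finite(d) || d <= 0) stop("`d` must be a positive distance")
  sp <- space_spec(n_dims, halfwidth = box_halfwidth)
  pt_a <- c(-d / 2, rep(0, n_dims - 1))
  pt_b <- c(+d / 2, rep(0, n_dims - 1))
  model_config(sp,
               agent_objective("A", pt_a, mode = objective_mode),
               agent_objective("B", pt_b, mode = objective_mode),
               p = p, mutation_mode = mutation_mode, initial = initial,
               seed = seed, max_proposals = max_proposals, engine = engine)
}
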