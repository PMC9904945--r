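# --- interval-union algebra (1D beneficial sets) -------------------------
# Intervals are open; endpoints have measure zero, so open/closed distinctions
# only matter for the strict-improvement convention, never for measures.

.iv_make <- function(lo, hi) {
  keep <- which(hi > lo)
  m <- cbind(lo = lo[keep], hi = hi[keep])
  if (nrow(m) > 1L) {
    m <- m[order(m[, 1L]), , drop = FALSE]
    out <- m[1L, , drop = FALSE]
    for (i in seq_len(nrow(m) - 1L) + 1L) {
      j <- nrow(out)
      if (m[i, 1L] <= out[j, 2L]) {
        out[j, 2L] <- max(out[j, 2L], m[i, 2L])
      } else {
        out <- rbind(out, m[i, ])
      }
    }
    m <- out
  }
  m
}

.iv_measure <- function(iv) if (nrow(iv)) sum(iv[, 2L] - iv[, 1L]) else 0

.iv_intersect <- function(x, y) {
  if (!nrow(x) || !nrow(y)) return(.iv_make(numeric(0), numeric(0)))
  lo <- outer(x[, 1L], y[, 1L], pmax)
  hi <- outer(x[, 2L], y[, 2L], pmin)
  .iv_make(as.numeric(lo), as.numeric(hi))
}

.iv_complement <- function(x, lo, hi) {
  if (!nrow(x)) return(.iv_make(lo, hi))
  gaps_lo <- c(lo, x[, 2L])
  gaps_hi <- c(x[, 1L], hi)
  .iv_make(gaps_lo, gaps_hi)
}

# \int_S |x - p| dx over an interval union, via F(x) = (x-p)|x-p|/2.
.iv_expected_absdist <- function(iv, point) {
  if (!nrow(iv)) return(NA_real_)
  f <- function(x) (x - point) * abs(x - point) / 2
  sum(f(iv[, 2L]) - f(iv[, 1L])) / .iv_measure(iv)
}

.interval_union <- function(iv) {
  structure(list(intervals = iv, measure = .iv_measure(iv)),
            class = "interval_union")
}

#' @export
print.interval_union <- function(x, ...) {
  if (!nrow(x$intervals)) {
    cat("interval union: empty\n")
  } else {
    cat("interval union:",
        paste(sprintf("(%g, %g)", x$intervals[, 1L], x$intervals[, 2L]),
              collapse = " U "),
        sprintf("  [measure %g]\n", x$measure))
  }
  invisible(x)
}

#' Beneficial set of a 1D phenotype for one agent
#'
#' For an optimum-seeking agent at `o` with the phenotype at `z`, the set of
#' mutants beneficial for that agent is the open interval `(o - r, o + r)`
#' with `r = |z - o|`, clipped to the space bounds; for a pessimum-avoiding
#' agent it is the complement (within the bounds) of the closed interval of
#' radius `r` around the pessimum.
#'
#' @param z Numeric scalar, current phenotype (inside the bounds).
#' @param objective An [agent_objective()] with a 1D point.
#' @param space A 1D [space_spec()].
#' @return An object of class `"interval_union"` with fields `intervals`
#'   (matrix of disjoint open intervals) and `measure`.
#' @examples
#' sp <- space_spec(1, halfwidth = 10)
#' beneficial_set_1d(0, agent_objective("A", -0.5), sp)  # (-1, 0), measure 1
#' @export
beneficial_set_1d <- function(z, objective, space) {
  stopifnot(inherits(objective, "agent_objective"),
            inherits(space, "space_spec"))
  if (space$n_dims != 1L) stop("beneficial_set_1d requires a 1D space")
  if (length(objective$point) != 1L) stop("objective point must be 1D")
  z <- as.numeric(z)
  if (length(z) != 1L || !.inside_space(space, z))
    stop("`z` must be a scalar inside the space bounds")
  o <- objective$point
  r <- abs(z - o)
  lo <- space$lower
  hi <- space$upper
  iv_ball <- .iv_make(max(o - r, lo), min(o + r, hi))
  if (objective$mode == "seek_optimum") {
    .interval_union(iv_ball)
  } else {
    .interval_union(.iv_complement(iv_ball, lo, hi))
  }
}

.agent_sets_1d <- function(z, config) {
  list(a = beneficial_set_1d(z, config$agent_a, config$space),
       b = beneficial_set_1d(z, config$agent_b, config$space))
}

.conflict_estimate <- function(point, intensity, method,
                               n_samples = NULL, standard_error = NULL) {
  structure(list(point = point, intensity = intensity, method = method,
                 n_samples = n_samples, standard_error = standard_error),
            class = "conflict_estimate")
}

#' @export
print.conflict_estimate <- function(x, ...) {
  cat(sprintf("conflict intensity at (%s): %.6g [%s%s]\n",
              paste(signif(x$point, 6), collapse = ", "), x$intensity,
              x$method,
              if (!is.null(x$standard_error))
                sprintf(", SE %.3g, n = %g", x$standard_error, x$n_samples)
              else ""))
  invisible(x)
}

#' Exact 1D conflict intensity
#'
#' The intensity of conflict at a phenotype `z` is the probability that the
#' next beneficial mutation — whichever agent governs it — is beneficial only
#' for its governing agent and deleterious for the other. With uniform
#' proposals this is exact interval arithmetic: writing `m_g` for the measure
#' of agent `g`'s beneficial set and `c_g` for the measure of its part that is
#' strictly deleterious for the other agent, the governor of the next
#' beneficial mutation is A with probability `w_A = p m_A / (p m_A + (1-p)
#' m_B)`, and the intensity is `w_A c_A / m_A + w_B c_B / m_B`. It equals 1
#' exactly when `z` lies strictly between the two optima and declines
#' monotonically beyond either optimum.
#'
#' @param z Numeric scalar phenotype.
#' @param config A 1D [model_config()].
#' @return A `"conflict_estimate"` with `method = "exact_1d"`.
#' @examples
#' cfg <- conflict_config()
#' conflict_intensity_1d(0, cfg)$intensity    # 1
#' conflict_intensity_1d(-1, cfg)$intensity   # 0.5
#' @export
conflict_intensity_1d <- function(z, config) {
  stopifnot(inherits(config, "model_config"))
  if (config$space$n_dims != 1L)
    stop("conflict_intensity_1d requires a 1D model")
  sets <- .agent_sets_1d(z, config)
  m_a <- sets$a$measure
  m_b <- sets$b$measure
  denom <- config$p * m_a + (1 - config$p) * m_b
  if (denom <= 0)
    stop("no beneficial mutation exists at this phenotype")
  shared <- .iv_measure(.iv_intersect(sets$a$intervals, sets$b$intervals))
  c_a <- m_a - shared
  c_b <- m_b - shared
  w_a <- config$p * m_a / denom
  w_b <- 1 - w_a
  term_a <- if (m_a > 0) w_a * c_a / m_a else 0
  term_b <- if (m_b > 0) w_b * c_b / m_b else 0
  .conflict_estimate(z, term_a + term_b, "exact_1d")
}

#' Monte Carlo conflict intensity (any dimension)
#'
#' Draws (governor, mutant) pairs from the model's proposal law and, among
#' proposals beneficial for their governor, estimates the probability that the
#' mutant is strictly deleterious for the other agent. Consistent for the
#' exact intensity as `n_samples` grows; in 1D it can be checked against
#' [conflict_intensity_1d()].
#'
#' @param z Numeric phenotype vector (inside the bounds).
#' @param config A [model_config()].
#' @param n_samples Number of proposal draws.
#' @return A `"conflict_estimate"` with `method = "monte_carlo"`, Bernoulli
#'   standard error `sqrt(phat (1 - phat) / k)` over the `k` beneficial draws.
#' @examples
#' cfg <- conflict_config(n_dims = 2)
#' set.seed(1)
#' conflict_intensity_mc(c(0, 0), cfg, 1e4)
#' @export
conflict_intensity_mc <- function(z, config, n_samples) {
  stopifnot(inherits(config, "model_config"))
  n <- config$space$n_dims
  z <- as.numeric(z)
  if (length(z) != n) stop("`z` must have length n_dims")
  if (!.inside_space(config$space, z))
    stop("`z` lies outside the space bounds")
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L) stop("`n_samples` must be >= 1")
  sp <- config$space
  w <- .space_widths(sp)
  gov_a <- stats::runif(n_samples) < config$p
  if (config$mutation_mode == "pleiotropic") {
    X <- matrix(sp$lower, n_samples, n, byrow = TRUE) +
      matrix(stats::runif(n_samples * n), n_samples, n) *
      matrix(w, n_samples, n, byrow = TRUE)
  } else {
    ax <- pmin(n, 1L + floor(stats::runif(n_samples) * n))
    X <- matrix(z, n_samples, n, byrow = TRUE)
    X[cbind(seq_len(n_samples), ax)] <-
      sp$lower[ax] + stats::runif(n_samples) * w[ax]
  }
  Da <- X - matrix(config$agent_a$point, n_samples, n, byrow = TRUE)
  Db <- X - matrix(config$agent_b$point, n_samples, n, byrow = TRUE)
  d2a <- rowSums(Da * Da)
  d2b <- rowSums(Db * Db)
  cur_d2a <- sum((z - config$agent_a$point)^2)
  cur_d2b <- sum((z - config$agent_b$point)^2)
  seek <- config$objective_mode == "seek_optimum"
  better_a <- if (seek) d2a < cur_d2a else d2a > cur_d2a
  better_b <- if (seek) d2b < cur_d2b else d2b > cur_d2b
  worse_a <- if (seek) d2a > cur_d2a else d2a < cur_d2a
  worse_b <- if (seek) d2b > cur_d2b else d2b < cur_d2b
  beneficial <- ifelse(gov_a, better_a, better_b)
  k <- sum(beneficial)
  if (k == 0L)
    stop("no beneficial draws among n_samples; increase n_samples")
  conflicted <- ifelse(gov_a, worse_b, worse_a)[beneficial]
  phat <- mean(conflicted)
  .conflict_estimate(z, phat, "monte_carlo", n_samples = k,
                     standard_error = sqrt(phat * (1 - phat) / k))
}

#' Where does the next beneficial mutation land? (exact, 1D)
#'
#' Conditional on the next beneficial mutation, the exact probabilities that
#' the accepted mutant lies strictly inside the open interval between the two
#' optima (the battleground) versus outside it, computed from the agents'
#' beneficial-set interval measures with the same governor weighting as
#' [conflict_intensity_1d()]. Under uniform proposals the outside probability
#' is at least as large as the inside probability for every phenotype and
#' every balance of power — the exact form of the hyper-maladaptation result.
#'
#' @param z Numeric scalar phenotype.
#' @param config A 1D optimum-seeking [model_config()].
#' @return Named numeric vector `c(inside =, outside =)` summing to 1.
#' @examples
#' cfg <- conflict_config()
#' next_mutation_inside_outside_1d(0, cfg)   # c(0.5, 0.5)
#' next_mutation_inside_outside_1d(-1, cfg)  # c(0.375, 0.625)
#' @export
next_mutation_inside_outside_1d <- function(z, config) {
  stopifnot(inherits(config, "model_config"))
  if (config$space$n_dims != 1L)
    stop("next_mutation_inside_outside_1d requires a 1D model")
  if (config$objective_mode != "seek_optimum")
    stop("defined for optimum-seeking models only")
  sets <- .agent_sets_1d(z, config)
  m_a <- sets$a$measure
  m_b <- sets$b$measure
  denom <- config$p * m_a + (1 - config$p) * m_b
  if (denom <= 0)
    stop("no beneficial mutation exists at this phenotype")
  battleground <- .iv_make(min(config$agent_a$point, config$agent_b$point),
                           max(config$agent_a$point, config$agent_b$point))
  in_a <- .iv_measure(.iv_intersect(sets$a$intervals, battleground))
  in_b <- .iv_measure(.iv_intersect(sets$b$intervals, battleground))
  w_a <- config$p * m_a / denom
  w_b <- 1 - w_a
  inside <- (if (m_a > 0) w_a * in_a / m_a else 0) +
    (if (m_b > 0) w_b * in_b / m_b else 0)
  c(inside = inside, outside = 1 - inside)
}

#' Conflict-intensity profile along the 1D axis
#'
#' Evaluates the conflict intensity on a grid of phenotypes, exactly or by
#' Monte Carlo, in the tabular layout used for profile exports.
#'
#' @param z_values Numeric vector of phenotypes.
#' @param config A 1D [model_config()].
#' @param method `"exact_1d"` or `"monte_carlo"`.
#' @param n_samples Monte Carlo sample size per point (ignored for exact).
#' @return Data frame with columns `z`, `intensity`, `method`, `se`.
#' @examples
#' conflict_profile_1d(seq(-2, 2, 0.5), conflict_config())
#' @export
conflict_profile_1d <- function(z_values, config,
                                method = c("exact_1d", "monte_carlo"),
                                n_samples = 1e5) {
  method <- match.arg(method)
  rows <- lapply(z_values, function(z) {
    est <- if (method == "exact_1d") conflict_intensity_1d(z, config)
           else conflict_intensity_mc(z, config, n_samples)
    data.frame(z = z, intensity = est$intensity, method = est$method,
               se = if (is.null(est$standard_error)) NA_real_
                    else est$standard_error)
  })
  do.call(rbind, rows)
}
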