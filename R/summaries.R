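# --- trajectory weighting -------------------------------------------------
# Event weighting averages over invasion snapshots with equal weight
# (archaeological-record view). Proposal weighting weights each post-invasion
# state by its sojourn in proposals, i.e. the proposals_used of the NEXT
# event; the final state's sojourn is right-censored and is dropped
# (unbiased for the stationary law). The distinction never changes the
# qualitative results; both are reported.
.traj_window <- function(traj, burn_in, weighting) {
  n <- nrow(traj$records)
  if (is.null(burn_in)) burn_in <- floor(n / 2)
  burn_in <- as.integer(burn_in)
  if (burn_in < 0 || burn_in >= n)
    stop("`burn_in` must be in [0, n_events)")
  idx <- seq.int(burn_in + 1L, n)
  if (weighting == "proposal") {
    idx <- idx[idx < n]
    if (!length(idx))
      stop("empty post-burn-in window under proposal weighting")
    w <- traj$records$proposals[idx + 1L]
  } else {
    w <- rep(1, length(idx))
  }
  list(idx = idx, w = w, burn_in = burn_in)
}

# Circular moving-block bootstrap over a window of length n_win. `stat_fn`
# maps a vector of positions (1..n_win) to a numeric stat vector; returns the
# resampling SD of each component. Invasion snapshots are autocorrelated, so
# iid bootstrap errors would be overconfident.
.block_boot_se <- function(stat_fn, n_win, block = 100L, n_boot = 200L) {
  block <- max(1L, min(as.integer(block), n_win))
  nb <- ceiling(n_win / block)
  reps <- NULL
  for (r in seq_len(n_boot)) {
    starts <- sample.int(n_win, nb, replace = TRUE)
    pos <- (rep(starts, each = block) +
              rep(seq_len(block) - 1L, times = nb) - 1L) %% n_win + 1L
    pos <- pos[seq_len(n_win)]
    v <- stat_fn(pos)
    if (is.null(reps)) reps <- matrix(NA_real_, n_boot, length(v))
    reps[r, ] <- v
  }
  apply(reps, 2L, stats::sd)
}

.weighted_mean <- function(x, w) sum(x * w) / sum(w)

#' Long-run maladaptation summary of a trajectory
#'
#' The degree of maladaptation is the average Euclidean distance of the
#' phenotype from the governing optimum — the optimum (or pessimum) of the
#' agent that governed each recorded invasion. Reported per dimension (mean
#' absolute coordinate deviation from the governing objective), overall
#' (mean Euclidean distance), and per agent (mean distance to each objective
#' point regardless of governor), with moving-block-bootstrap standard errors.
#'
#' @param traj A `"gc_trajectory"`.
#' @param burn_in Events discarded before averaging (default: first half).
#' @param weighting `"event"` (equal weight per invasion snapshot) or
#'   `"proposal"` (each state weighted by its sojourn in proposals; the final,
#'   right-censored state is dropped).
#' @param block,n_boot Block length and resample count for the bootstrap SEs.
#' @return An object of class `"maladaptation_summary"`.
#' @examples
#' traj <- run_dynamics(conflict_config(seed = 1), 2000)
#' maladaptation_summary(traj)
#' @export
maladaptation_summary <- function(traj, burn_in = NULL,
                                  weighting = c("event", "proposal"),
                                  block = 100L, n_boot = 200L) {
  stopifnot(inherits(traj, "gc_trajectory"))
  weighting <- match.arg(weighting)
  win <- .traj_window(traj, burn_in, weighting)
  n <- traj$config$space$n_dims
  X <- traj_states(traj)[win$idx, , drop = FALSE]
  rec <- traj$records[win$idx, ]
  is_a <- rec$governor == "A"
  O <- matrix(traj$config$agent_b$point, nrow(X), n, byrow = TRUE)
  if (any(is_a))
    O[is_a, ] <- matrix(traj$config$agent_a$point, sum(is_a), n, byrow = TRUE)
  dev <- abs(X - O)
  overall <- ifelse(is_a, rec$dist_a, rec$dist_b)
  vals <- cbind(dev, overall = overall, to_a = rec$dist_a, to_b = rec$dist_b)
  w <- win$w
  stat_fn <- function(pos) {
    colSums(vals[pos, , drop = FALSE] * w[pos]) / sum(w[pos])
  }
  est <- stat_fn(seq_along(win$idx))
  se <- .block_boot_se(stat_fn, length(win$idx), block, n_boot)
  structure(list(
    weighting = weighting,
    burn_in_events = win$burn_in,
    n_events_used = length(win$idx),
    per_dimension = unname(est[seq_len(n)]),
    per_dimension_se = unname(se[seq_len(n)]),
    overall = unname(est[n + 1L]),
    overall_se = unname(se[n + 1L]),
    per_agent_overall = c(a = unname(est[n + 2L]), b = unname(est[n + 3L])),
    per_agent_overall_se = c(a = unname(se[n + 2L]), b = unname(se[n + 3L]))
  ), class = "maladaptation_summary")
}

#' @export
print.maladaptation_summary <- function(x, ...) {
  cat(sprintf(
    "maladaptation (%s-weighted, burn-in %d, %d events used)\n",
    x$weighting, x$burn_in_events, x$n_events_used))
  cat(sprintf("  overall distance from governing objective: %.4g (SE %.2g)\n",
              x$overall, x$overall_se))
  cat(sprintf("  per-dimension deviation: %s\n",
              paste(sprintf("%.4g", x$per_dimension), collapse = ", ")))
  cat(sprintf("  mean distance to a: %.4g (SE %.2g); to b: %.4g (SE %.2g)\n",
              x$per_agent_overall["a"], x$per_agent_overall_se["a"],
              x$per_agent_overall["b"], x$per_agent_overall_se["b"]))
  invisible(x)
}

# --- regions --------------------------------------------------------------

#' Region descriptors for occupancy statistics
#'
#' `region_interval(lo, hi)` is the open 1D interval `(lo, hi)` on a chosen
#' axis; `region_slab(a, b)` is the open slab between the two hyperplanes
#' through `a` and `b` orthogonal to the segment joining them (the natural
#' multi-dimensional cylinder extension of the 1D battleground); and
#' `region_ball(center, radius)` is the closed Euclidean ball, used for
#' "close to a point" occupancy.
#'
#' @param lo,hi Interval endpoints.
#' @param axis Axis index the interval applies to (default 1, the
#'   conventional conflict axis).
#' @param a,b Points defining the slab faces.
#' @param center,radius Ball centre and radius.
#' @return An object of class `"gc_region"`.
#' @examples
#' region_interval(-0.5, 0.5)
#' region_ball(c(-0.5, 0), 0.25)
#' @name regions
NULL

#' @rdname regions
#' @export
region_interval <- function(lo, hi, axis = 1L) {
  stopifnot(is.finite(lo), is.finite(hi), lo < hi)
  structure(list(type = "interval", lo = lo, hi = hi, axis = as.integer(axis)),
            class = "gc_region")
}

#' @rdname regions
#' @export
region_slab <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == length(b), sum((a - b)^2) > 0)
  structure(list(type = "slab", a = a, b = b), class = "gc_region")
}

#' @rdname regions
#' @export
region_ball <- function(center, radius) {
  stopifnot(is.finite(radius), radius > 0)
  structure(list(type = "ball", center = as.numeric(center), radius = radius),
            class = "gc_region")
}

#' @rdname regions
#' @export
region_whole_space <- function() {
  structure(list(type = "all"), class = "gc_region")
}

.region_dim <- function(region) {
  switch(region$type,
         interval = region$axis,
         slab = length(region$a),
         ball = length(region$center),
         all = NA_integer_)
}

# Logical membership of each row of X (events x n_dims).
.region_contains <- function(region, X) {
  switch(region$type,
    interval = {
      x <- X[, region$axis]
      x > region$lo & x < region$hi
    },
    slab = {
      u <- region$b - region$a
      len2 <- sum(u * u)
      t <- (X - matrix(region$a, nrow(X), ncol(X), byrow = TRUE)) %*% u / len2
      as.vector(t > 0 & t < 1)
    },
    ball = {
      D <- X - matrix(region$center, nrow(X), ncol(X), byrow = TRUE)
      rowSums(D * D) <= region$radius^2
    },
    all = rep(TRUE, nrow(X)))
}

#' Occupancy probability of a region
#'
#' Weighted fraction of post-burn-in recorded states lying in a region, with
#' a moving-block-bootstrap standard error.
#'
#' @param traj A `"gc_trajectory"`.
#' @param region A region descriptor (see [region_interval()]).
#' @param burn_in,weighting,block,n_boot As in [maladaptation_summary()].
#' @return An object of class `"occupancy_result"` with fields `region`,
#'   `probability`, `standard_error`, `weighting`, `n_events_used`.
#' @examples
#' traj <- run_dynamics(conflict_config(seed = 1), 2000)
#' occupancy_probability(traj, region_interval(-0.5, 0.5))
#' @export
occupancy_probability <- function(traj, region, burn_in = NULL,
                                  weighting = c("event", "proposal"),
                                  block = 100L, n_boot = 200L) {
  stopifnot(inherits(traj, "gc_trajectory"), inherits(region, "gc_region"))
  weighting <- match.arg(weighting)
  n <- traj$config$space$n_dims
  rd <- .region_dim(region)
  if (!is.na(rd) && region$type != "interval" && rd != n)
    stop("region dimension does not match the space")
  if (region$type == "interval" && (region$axis < 1L || region$axis > n))
    stop("interval region axis outside the space dimensions")
  win <- .traj_window(traj, burn_in, weighting)
  X <- traj_states(traj)[win$idx, , drop = FALSE]
  inside <- as.numeric(.region_contains(region, X))
  w <- win$w
  stat_fn <- function(pos) .weighted_mean(inside[pos], w[pos])
  prob <- stat_fn(seq_along(win$idx))
  se <- if (all(inside == inside[1L])) 0
        else .block_boot_se(stat_fn, length(win$idx), block, n_boot)
  structure(list(region = region, probability = prob, standard_error = se,
                 weighting = weighting, n_events_used = length(win$idx)),
            class = "occupancy_result")
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf("occupancy of %s region: %.4g (SE %.2g, %s-weighted, n = %d)\n",
              x$region$type, x$probability, x$standard_error, x$weighting,
              x$n_events_used))
  invisible(x)
}

#' Equilibrium histogram of recorded states
#'
#' Normalized histogram (bin masses summing to 1) of the post-burn-in states
#' projected onto one axis, with block-bootstrap bin standard errors; with
#' two axes, a normalized 2D mass matrix (no SEs).
#'
#' @param traj A `"gc_trajectory"`.
#' @param breaks Either a number of equal-width bins spanning the axis bounds
#'   or an explicit break vector.
#' @param axis Axis index (length 1) or pair of axis indices (length 2).
#' @param burn_in,weighting,block,n_boot As in [maladaptation_summary()].
#' @return For one axis, a data frame `lo`, `hi`, `mass`, `se`; for two axes,
#'   a list with `breaks_x`, `breaks_y`, `mass`.
#' @examples
#' traj <- run_dynamics(conflict_config(seed = 1), 2000)
#' h <- equilibrium_histogram(traj, breaks = 20)
#' sum(h$mass)  # 1
#' @export
equilibrium_histogram <- function(traj, breaks = 50L, axis = 1L,
                                  burn_in = NULL,
                                  weighting = c("event", "proposal"),
                                  block = 100L, n_boot = 200L) {
  stopifnot(inherits(traj, "gc_trajectory"))
  weighting <- match.arg(weighting)
  n <- traj$config$space$n_dims
  if (!all(axis >= 1L & axis <= n))
    stop("`axis` outside the space dimensions")
  if (!length(axis) %in% 1:2)
    stop("histograms are supported on one or two axes; project via `axis`")
  win <- .traj_window(traj, burn_in, weighting)
  X <- traj_states(traj)[win$idx, , drop = FALSE]
  w <- win$w
  mk_breaks <- function(ax, br) {
    if (length(br) == 1L)
      seq(traj$config$space$lower[ax], traj$config$space$upper[ax],
          length.out = br + 1L)
    else as.numeric(br)
  }
  if (length(axis) == 2L) {
    bx <- mk_breaks(axis[1L], breaks)
    by <- mk_breaks(axis[2L], breaks)
    ix <- findInterval(X[, axis[1L]], bx, rightmost.closed = TRUE,
                       all.inside = TRUE)
    iy <- findInterval(X[, axis[2L]], by, rightmost.closed = TRUE,
                       all.inside = TRUE)
    mass <- matrix(0, length(bx) - 1L, length(by) - 1L)
    for (k in seq_along(ix)) mass[ix[k], iy[k]] <- mass[ix[k], iy[k]] + w[k]
    return(list(breaks_x = bx, breaks_y = by, mass = mass / sum(w)))
  }
  br <- mk_breaks(axis, breaks)
  nb <- length(br) - 1L
  bin <- findInterval(X[, axis], br, rightmost.closed = TRUE,
                      all.inside = TRUE)
  stat_fn <- function(pos) {
    m <- numeric(nb)
    agg <- rowsum(w[pos], bin[pos])
    m[as.integer(rownames(agg))] <- agg[, 1L]
    m / sum(w[pos])
  }
  # event weighting: tabulate is much faster than aggregate
  if (weighting == "event")
    stat_fn <- function(pos) tabulate(bin[pos], nbins = nb) / length(pos)
  mass <- stat_fn(seq_along(win$idx))
  se <- .block_boot_se(stat_fn, length(win$idx), block, n_boot)
  data.frame(lo = br[-length(br)], hi = br[-1L], mass = mass, se = se)
}

#' Log-log power-law fit of maladaptation against dimensionality
#'
#' Ordinary least squares of `log(mean)` on `log(n_dims)`; the slope is the
#' scaling exponent of maladaptation with the dimensionality of the phenotype
#' space (0.5 = square-root cost of complexity; 0 = no cost).
#'
#' @param points Data frame with columns `n_dims`, `mean` and optionally `se`.
#' @return An object of class `"scaling_fit"` with `points`, `exponent`,
#'   `intercept`, `r_squared`, `residuals`.
#' @examples
#' scaling_fit(data.frame(n_dims = c(1, 2, 4, 8, 16),
#'                        mean = sqrt(c(1, 2, 4, 8, 16))))$exponent  # 0.5
#' @export
scaling_fit <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("n_dims", "mean") %in% names(points)))
  if (length(unique(points$n_dims)) < 3L)
    stop("scaling_fit needs at least 3 distinct n_dims values")
  if (any(points$mean <= 0))
    stop("all means must be positive for a log-log fit")
  fit <- stats::lm(log(mean) ~ log(n_dims), data = points)
  res <- unname(stats::residuals(fit))
  ss_tot <- sum((log(points$mean) - mean(log(points$mean)))^2)
  structure(list(points = points,
                 exponent = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1,
                 residuals = res),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf(
    "log-log scaling fit over n = {%s}: exponent %.4g (R^2 %.3f)\n",
    paste(x$points$n_dims, collapse = ", "), x$exponent, x$r_squared))
  invisible(x)
}
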