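# Deterministic polynomial hash of the canonical (key-sorted) JSON of an
# object; used to stamp outputs so a manifest identifies its configuration
# irrespective of key order.
.canonical_json <- function(x) {
  sort_keys <- function(o) {
    if (is.list(o) && !is.null(names(o)))
      o <- lapply(o[order(names(o))], sort_keys)
    else if (is.list(o))
      o <- lapply(o, sort_keys)
    o
  }
  as.character(jsonlite::toJSON(sort_keys(x), auto_unbox = TRUE, digits = NA,
                                null = "null", force = TRUE))
}

.hash_string <- function(s) {
  b <- utf8ToInt(s)
  mod <- 2147483647
  h1 <- 17; h2 <- 31
  for (x in b) {
    h1 <- (h1 * 31 + x) %% mod
    h2 <- (h2 * 131 + x) %% mod
  }
  sprintf("%08x%08x", h1, h2)
}

#' Hash of a configuration
#'
#' Stable 16-hex-digit identifier of a configuration (or any list), invariant
#' under key reordering. Stamped into run manifests and output sidecars.
#'
#' @param config A list-like configuration object.
#' @return A character scalar.
#' @examples
#' config_hash(list(a = 1, b = 2)) == config_hash(list(b = 2, a = 1))
#' @export
config_hash <- function(config) {
  .hash_string(.canonical_json(unclass(config)))
}

.experiment_names <- c("conflict1d", "scaling", "modularity", "psweep",
                       "pessima", "compromise")

# Allowed keys and defaults per experiment; defaults that depend on d are
# expressed as functions of the filled config.
.config_schema <- function() {
  common <- list(seed = 1L, d = 1, p = 0.5,
                 box_halfwidth = function(cfg) 10 * cfg$d)
  list(
    conflict1d = c(common, list(n_events = 150000L, burn_in = NULL,
                                breaks = 80L)),
    scaling = c(common, list(n_grid = c(1, 2, 4, 8, 16), n_events = 100L,
                             n_replicates = 500L,
                             mutation_mode = "pleiotropic")),
    modularity = c(common, list(n_grid = c(1, 2, 4, 8, 16), n_events = 100L,
                                n_replicates = 500L, demo_n_events = 10000L,
                                demo_offset = function(cfg) cfg$d,
                                marginal_n_events = 150000L, breaks = 80L)),
    psweep = c(common[c("seed", "d", "box_halfwidth")],
               list(p_grid = seq(0.1, 0.9, by = 0.1), n_events = 20000L,
                    burn_in = NULL)),
    pessima = c(common[c("seed", "d", "p")],
                list(box_halfwidth = function(cfg) cfg$d,
                     epsilon = function(cfg) 0.25 * cfg$d,
                     n_events = 20000L, window = 1000L,
                     start_offset = function(cfg) 0.05 * cfg$d)),
    compromise = c(common, list(dims = c(1, 2), n_events = 100000L,
                                z_grid = function(cfg)
                                  seq(-2 * cfg$d, 2 * cfg$d,
                                      by = 0.25 * cfg$d),
                                burn_in = NULL)))
}

#' Load and validate an experiment configuration
#'
#' Reads a flat JSON experiment configuration, rejects unknown keys, checks
#' value ranges, and fills documented defaults (`d = 1`, `p = 0.5`, box
#' half-width `10 d` — `1 d` for the pessima experiment — and each
#' experiment's published design sizes).
#'
#' @param path Path to a JSON file with at least an `experiment` key (one of
#'   `conflict1d`, `scaling`, `modularity`, `psweep`, `pessima`,
#'   `compromise`).
#' @return A validated list of class `"experiment_config"`.
#' @examples
#' f <- tempfile(fileext = ".json")
#' writeLines('{"experiment": "conflict1d", "seed": 1}', f)
#' cfg <- load_config(f)
#' cfg$p  # 0.5
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(obj$experiment))
    stop("config key `experiment` is required")
  if (!obj$experiment %in% .experiment_names)
    stop("config key `experiment` must be one of: ",
         paste(.experiment_names, collapse = ", "))
  schema <- .config_schema()[[obj$experiment]]
  unknown <- setdiff(names(obj), c("experiment", names(schema)))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- obj
  for (key in names(schema)) {
    if (is.null(cfg[[key]]) && !is.function(schema[[key]]))
      cfg[[key]] <- schema[[key]]
  }
  for (key in names(schema)) {
    if (is.null(cfg[[key]]) && is.function(schema[[key]]))
      cfg[[key]] <- schema[[key]](cfg)
  }
  .validate_experiment_config(cfg)
  structure(cfg, class = "experiment_config")
}

.validate_experiment_config <- function(cfg) {
  chk_prob <- function(key) {
    v <- cfg[[key]]
    if (!is.null(v) && (!is.numeric(v) || any(v < 0 | v > 1)))
      stop(sprintf("config key `%s` must lie in [0, 1]", key))
  }
  chk_pos <- function(key) {
    v <- cfg[[key]]
    if (!is.null(v) && (!is.numeric(v) || any(!is.finite(v) | v <= 0)))
      stop(sprintf("config key `%s` must be positive", key))
  }
  chk_prob("p"); chk_prob("p_grid")
  chk_pos("d"); chk_pos("box_halfwidth"); chk_pos("n_events")
  chk_pos("n_replicates"); chk_pos("epsilon"); chk_pos("window")
  chk_pos("n_grid"); chk_pos("dims")
  if (!is.null(cfg$d) && !is.null(cfg$box_halfwidth) &&
      cfg$d / 2 > cfg$box_halfwidth)
    stop("config key `box_halfwidth`: objective points at +/- d/2 ",
         "would lie outside the space bounds")
  invisible(cfg)
}

#' Run the experiment named by a configuration
#'
#' Dispatches a validated [load_config()] object (or an equivalent list) to
#' the matching `exp_*()` driver.
#'
#' @param cfg An `"experiment_config"` (or list with the same keys).
#' @return The driver's `"gc_experiment"` result.
#' @examples
#' \donttest{
#' run_experiment(list(experiment = "psweep", seed = 1,
#'                     p_grid = c(0.2, 0.5, 0.8), n_events = 3000))
#' }
#' @export
run_experiment <- function(cfg) {
  args <- unclass(cfg)
  experiment <- args$experiment
  args$experiment <- NULL
  fn <- switch(experiment,
               conflict1d = exp_1d_conflict,
               scaling = exp_dimension_scaling,
               modularity = exp_modularity,
               psweep = exp_p_sweep,
               pessima = exp_pessima,
               compromise = exp_compromise,
               stop("unknown experiment: ", experiment))
  do.call(fn, args[intersect(names(args), names(formals(fn)))])
}

#' Serialize a model configuration
#'
#' Writes/reads a [model_config()] as a flat key-value JSON file (keys:
#' `n_dims`, `bounds`, `optimum_a`, `optimum_b`, `objective_mode`, `p`,
#' `mutation_mode`, `initial`, `seed`, `max_proposals`, `engine`), such that
#' `read_model_config(write_model_config(cfg, path))` reproduces `cfg`.
#'
#' @param config A `"model_config"`.
#' @param path File path.
#' @return `write_model_config` returns `path` invisibly;
#'   `read_model_config` returns a `"model_config"`.
#' @examples
#' f <- tempfile(fileext = ".json")
#' cfg <- conflict_config(seed = 3)
#' write_model_config(cfg, f)
#' identical(read_model_config(f), cfg)
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  flat <- list(n_dims = config$space$n_dims,
               bounds = rbind(config$space$lower, config$space$upper),
               optimum_a = config$agent_a$point,
               optimum_b = config$agent_b$point,
               objective_mode = config$objective_mode,
               p = config$p,
               mutation_mode = config$mutation_mode,
               initial = config$initial,
               seed = config$seed,
               max_proposals = config$max_proposals,
               engine = config$engine)
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  flat <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (flat$p < 0 || flat$p > 1) stop("config key `p` must lie in [0, 1]")
  sp <- space_spec(flat$n_dims, bounds = matrix(as.numeric(flat$bounds),
                                                nrow = 2))
  model_config(sp,
               agent_objective("A", flat$optimum_a,
                               mode = flat$objective_mode),
               agent_objective("B", flat$optimum_b,
                               mode = flat$objective_mode),
               p = flat$p, mutation_mode = flat$mutation_mode,
               initial = flat$initial, seed = flat$seed,
               max_proposals = as.numeric(flat$max_proposals),
               engine = flat$engine)
}

#' Write a trajectory as CSV with a JSON config sidecar
#'
#' @param traj A `"gc_trajectory"`.
#' @param path CSV path; the configuration is echoed next to it as
#'   `<path-sans-.csv>_config.json`.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_trajectory(run_dynamics(conflict_config(seed = 1), 50), f)
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "gc_trajectory"))
  utils::write.csv(traj$records, path, row.names = FALSE)
  write_model_config(traj$config, paste0(sub("\\.csv$", "", path),
                                         "_config.json"))
  invisible(path)
}

# Flatten an experiment result into a named list of data frames; scalar-ish
# leaves go to the summary list.
.collect_tables <- function(x, prefix = NULL) {
  tables <- list()
  summary <- list()
  for (nm in names(x)) {
    v <- x[[nm]]
    key <- paste(c(prefix, nm), collapse = "_")
    if (is.data.frame(v)) {
      tables[[key]] <- v
    } else if (inherits(v, "gc_trajectory")) {
      tables[[key]] <- v$records
    } else if (inherits(v, "scaling_fit")) {
      summary[[key]] <- list(exponent = v$exponent,
                             intercept = v$intercept,
                             r_squared = v$r_squared)
    } else if (inherits(v, "maladaptation_summary")) {
      summary[[key]] <- unclass(v)
    } else if (is.list(v) && !is.null(names(v)) &&
               !inherits(v, "model_config")) {
      sub <- .collect_tables(v, key)
      tables <- c(tables, sub$tables)
      summary <- c(summary, sub$summary)
    } else if (is.atomic(v) && length(v) <= 32L) {
      summary[[key]] <- v
    }
  }
  list(tables = tables, summary = summary)
}

#' Write experiment results with a run manifest
#'
#' Writes every table of an experiment result (or any named list of data
#' frames) as a CSV under `outdir`, collects scalar summaries into
#' `summary.json`, and writes `manifest.json` recording the configuration
#' hash, seed, package version, and per-file row counts. Re-running with the
#' same configuration and seed overwrites the same files with identical
#' content.
#'
#' @param results A `"gc_experiment"` or named list of data frames.
#' @param outdir Output directory (created if missing).
#' @param config Optional configuration to hash into the manifest.
#' @param seed Optional root seed to record.
#' @return The manifest, invisibly.
#' @examples
#' \donttest{
#' res <- exp_p_sweep(seed = 1, p_grid = c(0.3, 0.5, 0.7), n_events = 2000)
#' write_results(res, tempfile("out"))
#' }
#' @export
write_results <- function(results, outdir, config = NULL, seed = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.data.frame(results)) results <- list(result = results)
  col <- .collect_tables(results)
  files <- data.frame(file = character(0), rows = integer(0))
  for (nm in names(col$tables)) {
    f <- file.path(outdir, paste0(nm, ".csv"))
    utils::write.csv(col$tables[[nm]], f, row.names = FALSE)
    files <- rbind(files, data.frame(file = basename(f),
                                     rows = nrow(col$tables[[nm]])))
  }
  if (length(col$summary)) {
    f <- file.path(outdir, "summary.json")
    jsonlite::write_json(col$summary, f, auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE)
    files <- rbind(files, data.frame(file = "summary.json", rows = NA))
  }
  manifest <- list(
    package = "geomconflict",
    version = as.character(utils::packageVersion("geomconflict")),
    config_hash = if (is.null(config)) NA else config_hash(config),
    seed = if (is.null(seed)) NA else seed,
    files = files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE, dataframe = "rows")
  invisible(manifest)
}
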