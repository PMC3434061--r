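#' Load a run configuration
#'
#' Reads a declarative YAML configuration describing one experiment and
#' validates it against the schema below; unset fields take documented
#' defaults (nominal rate constants, variant `wild_type`). Unknown keys,
#' unknown experiment or variant names, and non-positive rate overrides are
#' rejected with named errors.
#'
#' Schema (all keys optional except `experiment`):
#' \preformatted{
#' experiment: nullclines | scan | ssa | compare
#' variant:    wild_type | uncoupled | no_feedback
#' parameters: {alpha: 60, delta_A: 1.2, ...}   # overrides of nominal values
#' seed:       1            # master seed (scan, ssa)
#' seeds:      [1, 2, ...]  # replicate seeds (compare)
#' t_end:      600          # hours
#' burn_in:    100          # hours
#' n_draws:    50           # scan parameter draws
#' n_ic:       50           # scan initial conditions per draw
#' mode:       all_parameters | single_parameter
#' antitoxin:  with_dimer | monomer
#' }
#'
#' @param path YAML file path.
#' @return Object of class `run_config`: the validated settings with a
#'   fully resolved `params` element.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("malformed config file: ", conditionMessage(e), call. = FALSE))
  if (is.null(raw)) raw <- list()
  as_run_config(raw)
}

# internal: validate a config list (also the programmatic entry point)
as_run_config <- function(raw) {
  known <- c("experiment", "variant", "parameters", "seed", "seeds",
             "t_end", "burn_in", "n_draws", "n_ic", "mode", "antitoxin")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  experiment <- raw$experiment %||% "nullclines"
  if (!experiment %in% c("nullclines", "scan", "ssa", "compare"))
    stop("unknown experiment: ", experiment, call. = FALSE)
  variant <- raw$variant %||% "wild_type"
  if (!variant %in% c("wild_type", "uncoupled", "no_feedback"))
    stop("unknown variant: ", variant, call. = FALSE)
  params <- do.call(hipba_params, as.list(raw$parameters %||% list()))
  cfg <- list(
    experiment = experiment, variant = variant, params = params,
    parameter_overrides = raw$parameters %||% list(),
    seed = raw$seed %||% 1L,
    seeds = raw$seeds %||% seq_len(10L),
    t_end = raw$t_end %||% if (experiment == "compare") 600 else 1000,
    burn_in = raw$burn_in %||% 100,
    n_draws = raw$n_draws %||% 50L, n_ic = raw$n_ic %||% 50L,
    mode = raw$mode %||% "all_parameters",
    antitoxin = raw$antitoxin %||% "with_dimer")
  if (!cfg$mode %in% c("all_parameters", "single_parameter"))
    stop("unknown scan mode: ", cfg$mode, call. = FALSE)
  if (!cfg$antitoxin %in% c("with_dimer", "monomer"))
    stop("unknown antitoxin accounting: ", cfg$antitoxin, call. = FALSE)
  if (cfg$t_end <= cfg$burn_in)
    stop("t_end must exceed burn_in", call. = FALSE)
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configured experiment and write its outputs
#'
#' Executes one of the four analysis stages — `nullclines` (phase-plane
#' equilibrium count of the reduced model), `scan` (Monte-Carlo
#' multistability scan), `ssa` (one stochastic trajectory with its ratio
#' series and histogram) or `compare` (three-architecture persistence
#' comparison) — and writes CSV/JSON results plus a JSON manifest recording
#' the configuration, seeds, package version, runtime and headline numbers,
#' sufficient to regenerate the outputs exactly.
#'
#' @param config a `run_config` (from \code{\link{load_config}}).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the manifest as a list; files are written to
#'   `out_dir`.
#' @export
run_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  results <- switch(config$experiment,
    nullclines = {
      ncs <- count_equilibria(config$params)
      nullclines_to_csv(ncs, file.path(out_dir, "nullclines.csv"))
      utils::write.csv(ncs$points, file.path(out_dir, "equilibria.csv"),
                       row.names = FALSE)
      list(n_equilibria = ncs$n_equilibria,
           stable = sum(ncs$points$stable))
    },
    scan = {
      net <- build_network(config$variant)
      scan <- run_scan(net, config$params, mode = config$mode,
                       n_draws = config$n_draws, n_ic = config$n_ic,
                       t_end = config$t_end, seed = config$seed)
      scan_to_files(scan, file.path(out_dir, "scan.json"),
                    file.path(out_dir, "scan.csv"))
      list(verdict = scan$verdict,
           max_clusters = max(scan$draws$clusters, na.rm = TRUE))
    },
    ssa = {
      net <- build_network(config$variant)
      run <- gillespie_run(net, config$params, t_end = config$t_end,
                           seed = config$seed, burn_in = config$burn_in,
                           antitoxin = config$antitoxin, record = "grid")
      traj <- data.frame(time = run$times, run$states, check.names = FALSE)
      utils::write.csv(traj, file.path(out_dir, "trajectory.csv"),
                       row.names = FALSE)
      series <- compute_R(run, antitoxin = config$antitoxin)
      utils::write.csv(r_histogram(series),
                       file.path(out_dir, "r_histogram.csv"),
                       row.names = FALSE)
      st <- time_weighted_stats(run, "R")
      pers <- detect_persistence(series)
      list(n_events = run$n_events, mean_R = st$mean, fano_R = st$fano,
           fraction_persistent = pers$fraction_exact %||% pers$fraction)
    },
    compare = {
      cmp <- compare_architectures(config$params, config$seeds,
                                   t_end = config$t_end,
                                   burn_in = config$burn_in,
                                   antitoxin = config$antitoxin)
      utils::write.csv(cmp$summary, file.path(out_dir, "comparison.csv"),
                       row.names = FALSE)
      utils::write.csv(cmp$replicates,
                       file.path(out_dir, "replicates.csv"),
                       row.names = FALSE)
      as.list(stats::setNames(cmp$summary$mean_R,
                              paste0("mean_R_", cmp$summary$variant)))
    })

  manifest <- list(
    experiment = config$experiment, variant = config$variant,
    parameter_overrides = config$parameter_overrides,
    seed = config$seed, seeds = config$seeds,
    t_end = config$t_end, burn_in = config$burn_in,
    package_version = as.character(utils::packageVersion("hipbasim")),
    runtime_seconds = round(proc.time()[["elapsed"]] - t0, 2),
    results = results)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
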