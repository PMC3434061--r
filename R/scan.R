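#' Sample rate constants from log-normal distributions
#'
#' Draws a parameter set with each varied constant taken from a log-normal
#' distribution whose median is the nominal value and whose central 95\%
#' interval equals the tested range (for the default decade-wide ranges,
#' `sdlog = log(10)/1.96`). Samples are not truncated to the range. In
#' `single_parameter` mode only `which_parameter` is drawn and all other
#' constants stay nominal; in `all_parameters` mode every constant is drawn
#' independently.
#'
#' @param params nominal `hipba_params` (also supplies the ranges).
#' @param mode `"single_parameter"` or `"all_parameters"`.
#' @param which_parameter name of the varied constant (single mode only).
#' @return A new `hipba_params` with the sampled values.
#' @export
sample_parameters <- function(params,
                              mode = c("single_parameter", "all_parameters"),
                              which_parameter = NULL) {
  assert_params(params)
  mode <- match.arg(mode)
  value <- params$value
  sdlog <- (log(params$range[, "high"]) - log(params$range[, "low"])) /
    (2 * stats::qnorm(0.975))
  if (mode == "single_parameter") {
    if (is.null(which_parameter) || !which_parameter %in% names(value))
      stop("which_parameter must name one rate constant; got: ",
           if (is.null(which_parameter)) "NULL" else which_parameter,
           call. = FALSE)
    value[which_parameter] <- stats::rlnorm(
      1, meanlog = log(value[which_parameter]),
      sdlog = sdlog[which_parameter])
  } else {
    value[] <- stats::rlnorm(length(value), meanlog = log(value),
                             sdlog = sdlog)
  }
  out <- params
  out$value <- value
  out$range[, "low"] <- pmin(out$range[, "low"], value)
  out$range[, "high"] <- pmax(out$range[, "high"], value)
  out
}

#' Draw a random initial condition
#'
#' Initial mRNA amounts uniform on `mrna_range` (default 0 to 100) and all
#' non-promoter protein species (including the dimer and the complex)
#' uniform on `protein_range` (default 0 to 1000), independently. Promoter
#' states are held fixed at the network default (all copies free).
#'
#' @param network a `hipba_network`.
#' @param mrna_range,protein_range length-2 nonnegative bounds.
#' @return Named numeric state vector.
#' @export
sample_initial_conditions <- function(network, mrna_range = c(0, 100),
                                      protein_range = c(0, 1000)) {
  stopifnot(length(mrna_range) == 2, length(protein_range) == 2,
            all(mrna_range >= 0), all(protein_range >= 0))
  init <- network$init_default
  is_m <- network$roles == "mrna"
  is_p <- network$roles == "protein"
  init[is_m] <- stats::runif(sum(is_m), mrna_range[1], mrna_range[2])
  init[is_p] <- stats::runif(sum(is_p), protein_range[1], protein_range[2])
  init
}

#' Cluster converged final states with a relative-difference metric
#'
#' Single-linkage clustering of steady states under the distance
#' `max_i |x_i - y_i| / max(x_i, y_i, eps)` (the largest per-species
#' relative difference, with a small floor guarding zero amounts). Two
#' states belong to the same equilibrium when linked below `rel_tol`; the
#' cluster count is the number of distinct equilibria, so a count of 1 from
#' widely scattered initial conditions is evidence of monostability.
#'
#' @param states matrix of final states, one row per run.
#' @param rel_tol relative tolerance (default 0.01, the 1\% criterion).
#' @param eps amount floor (molecules) for the relative difference.
#' @return Integer cluster count.
#' @export
cluster_final_states <- function(states, rel_tol = 0.01, eps = 1e-6) {
  states <- as.matrix(states)
  if (nrow(states) == 0) stop("no states to cluster", call. = FALSE)
  stopifnot(rel_tol > 0, rel_tol < 1)
  m <- nrow(states)
  if (m == 1) return(1L)
  D <- matrix(0, m, m)
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    d <- max(abs(states[i, ] - states[j, ]) /
               pmax(states[i, ], states[j, ], eps))
    D[i, j] <- D[j, i] <- d
  }
  hc <- stats::hclust(stats::as.dist(D), method = "single")
  max(stats::cutree(hc, h = rel_tol))
}

#' Monte-Carlo multistability scan
#'
#' For each parameter draw, integrates the deterministic model from many
#' random initial conditions to steady state and clusters the final states
#' with the 1\% relative metric. A cluster count of 1 for every draw is the
#' monostability verdict; any count above 1 flags multistability (as the
#' planted bistable control does). Two study designs are supported:
#' `single_parameter` (each rate constant varied alone, `n_draws` times
#' each) and `all_parameters` (all constants drawn jointly).
#'
#' @param network a `hipba_network` (or a synthetic fixture network carrying
#'   its own rates, in which case set `sample = FALSE`).
#' @param params nominal `hipba_params`.
#' @param mode scan design; see \code{\link{sample_parameters}}.
#' @param n_draws parameter draws (per parameter in single mode).
#' @param n_ic random initial conditions per draw.
#' @param parameters which constants to vary in single mode (default all
#'   17, in canonical order).
#' @param t_end integration horizon per initial condition (hours).
#' @param rel_tol clustering tolerance (1\% criterion).
#' @param steady_tol residual infinity-norm above which a run is counted as
#'   non-converged and excluded from clustering.
#' @param mrna_range,protein_range initial-condition bounds.
#' @param sample if `FALSE`, parameters stay fixed and only initial
#'   conditions vary (used for fixture networks).
#' @param seed master seed; each draw uses the deterministically derived
#'   sub-seed `seed + draw index`, so results are reproducible and
#'   individual draws can be rerun in isolation.
#' @return Object of class `scan_result`: per-draw parameter values,
#'   cluster counts, non-convergence counts, and the overall verdict
#'   (`"monostable"` or `"multistable"`).
#' @export
run_scan <- function(network, params, mode = c("all_parameters",
                                               "single_parameter"),
                     n_draws = 50, n_ic = 50, parameters = NULL,
                     t_end = 1000, rel_tol = 0.01, steady_tol = 1e-4,
                     mrna_range = c(0, 100), protein_range = c(0, 1000),
                     sample = TRUE, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_draws >= 1, n_ic >= 1)
  if (mode == "single_parameter") {
    if (is.null(parameters)) parameters <- names(params$value)
    draws <- data.frame(parameter = rep(parameters, each = n_draws),
                        rep = rep(seq_len(n_draws), length(parameters)))
  } else {
    draws <- data.frame(parameter = NA_character_, rep = seq_len(n_draws))
  }

  counts <- integer(nrow(draws))
  n_fail <- integer(nrow(draws))
  par_values <- matrix(NA_real_, nrow(draws), length(params$value),
                       dimnames = list(NULL, names(params$value)))
  for (d in seq_len(nrow(draws))) {
    set.seed((seed + d) %% .Machine$integer.max)
    p_d <- if (sample && is.null(network$rate_values)) {
      if (mode == "single_parameter")
        sample_parameters(params, "single_parameter", draws$parameter[d])
      else sample_parameters(params, "all_parameters")
    } else params
    par_values[d, ] <- p_d$value
    finals <- matrix(NA_real_, n_ic, length(network$species))
    ok <- logical(n_ic)
    for (i in seq_len(n_ic)) {
      ic <- sample_initial_conditions(network, mrna_range, protein_range)
      traj <- tryCatch(
        simulate_deterministic(network, p_d, ic, t_end = t_end, n_out = 5),
        error = function(e) NULL)
      if (is.null(traj)) next
      xf <- pmax(traj$states[nrow(traj$states), ], 0)
      if (max(abs(ode_rhs(xf, p_d, network))) < steady_tol) {
        finals[i, ] <- xf
        ok[i] <- TRUE
      }
    }
    n_fail[d] <- sum(!ok)
    counts[d] <- if (any(ok))
      cluster_final_states(finals[ok, , drop = FALSE], rel_tol) else NA_integer_
  }

  structure(list(
    variant = network$variant, mode = mode,
    draws = cbind(draws, clusters = counts, n_nonconverged = n_fail),
    parameter_values = par_values,
    config = list(n_draws = n_draws, n_ic = n_ic, t_end = t_end,
                  rel_tol = rel_tol, steady_tol = steady_tol,
                  mrna_range = mrna_range, protein_range = protein_range,
                  seed = seed),
    verdict = if (any(counts > 1, na.rm = TRUE)) "multistable"
              else "monostable"),
    class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("Multistability scan (", x$mode, ", variant '", x$variant, "'): ",
      nrow(x$draws), " draws x ", x$config$n_ic, " initial conditions\n",
      "verdict: ", x$verdict,
      " (max cluster count ", max(x$draws$clusters, na.rm = TRUE),
      "; non-converged runs ", sum(x$draws$n_nonconverged), ")\n", sep = "")
  invisible(x)
}

#' Persist a scan result
#'
#' Writes a JSON document (config, verdict, per-draw cluster counts) and,
#' optionally, a CSV summary with one row per draw (sampled parameter
#' values, cluster count, non-converged count).
#'
#' @param scan a `scan_result`.
#' @param json_path,csv_path output paths (`NULL` to skip either).
#' @return `invisible(scan)`.
#' @export
scan_to_files <- function(scan, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(scan, "scan_result"))
  if (!is.null(json_path)) {
    doc <- list(variant = scan$variant, mode = scan$mode,
                config = scan$config, verdict = scan$verdict,
                clusters = scan$draws$clusters,
                n_nonconverged = scan$draws$n_nonconverged)
    jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(csv_path)) {
    df <- cbind(scan$draws, as.data.frame(scan$parameter_values))
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(scan)
}
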