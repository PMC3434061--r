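#' Persistence ratio series from a stochastic run
#'
#' Computes `R(t) = free HipA / (free HipA + free HipB)` along the stored
#' trajectory. Free HipA is monomeric A; free HipB is monomeric B plus, by
#' default, two per unbound dimer (`antitoxin = "with_dimer"`), since
#' dimerized HipB is neither neutralizing HipA in the AB2A complex nor bound
#' to the promoter. Intervals with no free molecules of either kind are
#' marked `NA` (undefined) and excluded from statistics: they are data, not
#' errors. A cell is a persister while `R` exceeds the threshold (strictly;
#' `R = 0.5` is not persistence).
#'
#' @param run an `ssa_run` whose network contains species `A` and `B`.
#' @param antitoxin `"with_dimer"` (default) or `"monomer"`; see
#'   \code{\link{gillespie_run}}.
#' @param threshold persistence threshold (default 0.5).
#' @return Object of class `r_series`: `times`, `R` (with `NA` for
#'   undefined intervals), `threshold`, `t_end`, `burn_in`, and source-run
#'   metadata. When the requested accounting matches the run's, the exact
#'   dwell-time accumulators are attached as `exact`.
#' @export
compute_R <- function(run, antitoxin = c("with_dimer", "monomer"),
                      threshold = 0.5) {
  stopifnot(inherits(run, "ssa_run"))
  antitoxin <- match.arg(antitoxin)
  stopifnot(threshold > 0, threshold < 1)
  if (!all(c("A", "B") %in% run$species))
    stop("run does not contain species A and B", call. = FALSE)
  w <- r_weights(list(species = run$species), antitoxin)
  num <- drop(run$states %*% w$num)
  den <- drop(run$states %*% w$den)
  R <- ifelse(num + den > 0, num / (num + den), NA_real_)
  exact <- if (identical(antitoxin, run$antitoxin) &&
                 threshold == run$threshold) run$acc else NULL
  structure(list(times = run$times, R = R, threshold = threshold,
                 antitoxin = antitoxin, t_end = run$t_end,
                 burn_in = run$burn_in, variant = run$variant,
                 seed = run$seed, exact = exact),
            class = "r_series")
}

#' @export
print.r_series <- function(x, ...) {
  cat("Persistence-ratio series (variant '", x$variant, "'): ",
      length(x$times), " stored points, threshold ", x$threshold, "\n",
      sep = "")
  invisible(x)
}

#' Detect persistence episodes
#'
#' Finds the maximal intervals with `R` strictly above the threshold —
#' the episodes during which free toxin outnumbers free antitoxin and the
#' cell is in the persister state — and the dwell-time fraction spent there.
#' Undefined (`NA`) intervals separate episodes only if the ratio is on
#' opposite sides across them; the side is carried across undefined gaps,
#' matching the crossing accounting of the exact accumulators.
#'
#' @param series an `r_series`.
#' @param after_burn_in restrict to the post-burn-in window (default TRUE).
#' @return List: `events` (data frame `start`, `end`, `duration` in hours),
#'   `n_events`, `fraction` (time above threshold / defined time), and
#'   `time_defined`. When exact accumulators are available the fraction
#'   reported in `fraction_exact` comes from them.
#' @export
detect_persistence <- function(series, after_burn_in = TRUE) {
  stopifnot(inherits(series, "r_series"))
  t0 <- if (after_burn_in) series$burn_in else series$times[1]
  win <- window_series(series$times, series$R, t0)
  tt <- win$times
  R <- win$values
  if (!length(tt) || all(is.na(R)))
    stop("series has no defined ratio values in the requested window",
         call. = FALSE)
  w <- diff(c(tt, series$t_end))
  above <- R > series$threshold          # NA where undefined
  # carry the last defined side across undefined gaps
  side <- above
  for (i in seq_along(side)) if (is.na(side[i]) && i > 1) side[i] <- side[i - 1]
  side[is.na(side)] <- FALSE
  r <- rle(side)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  ev <- which(r$values)
  events <- data.frame(
    start = tt[starts[ev]],
    end = c(tt, series$t_end)[ends[ev] + 1],
    row.names = NULL)
  events$duration <- events$end - events$start
  list(events = events, n_events = nrow(events),
       fraction = sum(w[which(above)]) / sum(w[!is.na(R)]),
       fraction_exact = if (!is.null(series$exact))
         series$exact$r_time_above / series$exact$r_time_defined else NULL,
       time_defined = sum(w[!is.na(R)]))
}

# internal: restrict a piecewise-constant series to [t0, end]; the value
# holding at t0 was set by the last point at or before it
window_series <- function(times, values, t0) {
  later <- times > t0
  i0 <- which(times <= t0)
  if (length(i0)) {
    list(times = c(t0, times[later]),
         values = c(values[max(i0)], values[later]))
  } else {
    list(times = times[later], values = values[later])
  }
}

#' Dwell-time-weighted histogram of the persistence ratio
#'
#' Pools one or more ratio series into a histogram over [0, 1], each value
#' weighted by the time the trajectory dwells at it, normalized to total
#' mass 1. Undefined intervals are excluded.
#'
#' @param series an `r_series` or a list of them (an ensemble of simulated
#'   cells).
#' @param bins number of equal-width bins on [0, 1].
#' @param after_burn_in restrict to post-burn-in data (default TRUE).
#' @return Data frame with `mid`, `lower`, `upper`, `mass`.
#' @export
r_histogram <- function(series, bins = 50, after_burn_in = TRUE) {
  if (inherits(series, "r_series")) series <- list(series)
  stopifnot(length(series) >= 1, bins >= 1)
  breaks <- seq(0, 1, length.out = bins + 1)
  mass <- numeric(bins)
  for (s in series) {
    stopifnot(inherits(s, "r_series"))
    t0 <- if (after_burn_in) s$burn_in else s$times[1]
    win <- window_series(s$times, s$R, t0)
    tt <- win$times; R <- win$values
    w <- diff(c(tt, s$t_end))
    ok <- !is.na(R) & w > 0
    if (!any(ok)) next
    idx <- pmin(pmax(findInterval(R[ok], breaks, rightmost.closed = TRUE),
                     1L), bins)
    mass <- mass + vapply(seq_len(bins), function(b) sum(w[ok][idx == b]),
                          numeric(1))
  }
  if (sum(mass) <= 0)
    stop("no defined ratio values across the supplied series", call. = FALSE)
  mass <- mass / sum(mass)
  data.frame(mid = (breaks[-1] + breaks[-(bins + 1)]) / 2,
             lower = breaks[-(bins + 1)], upper = breaks[-1], mass = mass)
}

#' Compare regulatory architectures by persistence statistics
#'
#' Runs replicate stochastic simulations ("simulated cells", one independent
#' seed each) of the wild-type, transcriptionally uncoupled and feedback-free
#' networks at shared rate constants, and summarizes each architecture by
#' the across-replicate mean and standard error of: dwell-weighted mean R,
#' Fano factor (variance/mean) of R, and the persistence-time fraction.
#' The replicate-level values come from the exact dwell-time accumulators.
#'
#' @param params shared `hipba_params`.
#' @param seeds integer vector of replicate seeds (>= 3; >= 10 for the
#'   ordering tests).
#' @param t_end,burn_in per-replicate horizon and discarded transient
#'   (hours).
#' @param variants architectures to include.
#' @param antitoxin,threshold see \code{\link{compute_R}}.
#' @return Object of class `architecture_comparison`: `replicates` (one row
#'   per architecture x seed) and `summary` (one row per architecture).
#' @export
compare_architectures <- function(params, seeds, t_end = 600, burn_in = 100,
                                  variants = c("wild_type", "uncoupled",
                                               "no_feedback"),
                                  antitoxin = "with_dimer",
                                  threshold = 0.5) {
  if (length(seeds) < 3)
    stop("at least 3 replicate seeds are required", call. = FALSE)
  rows <- list()
  for (v in variants) {
    net <- build_network(v)
    eq <- round(find_equilibrium(net, params))
    for (s in seeds) {
      run <- gillespie_run(net, params, init = eq, t_end = t_end, seed = s,
                           burn_in = burn_in, antitoxin = antitoxin,
                           record = "grid", n_grid = 200,
                           threshold = threshold)
      st <- time_weighted_stats(run, "R")
      rows[[length(rows) + 1]] <- data.frame(
        variant = v, seed = s, mean_R = st$mean, var_R = st$var,
        fano_R = st$fano,
        fraction_persistent = run$acc$r_time_above / run$acc$r_time_defined,
        upcrossings = run$acc$r_upcrossings)
    }
  }
  reps <- do.call(rbind, rows)
  se <- function(x) stats::sd(x) / sqrt(length(x))
  summ <- do.call(rbind, lapply(split(reps, reps$variant), function(d)
    data.frame(variant = d$variant[1], n = nrow(d),
               mean_R = mean(d$mean_R), se_mean_R = se(d$mean_R),
               fano_R = mean(d$fano_R), se_fano_R = se(d$fano_R),
               fraction_persistent = mean(d$fraction_persistent))))
  summ <- summ[order(match(summ$variant, variants)), ]
  rownames(summ) <- NULL
  structure(list(replicates = reps, summary = summ,
                 seeds = seeds, t_end = t_end, burn_in = burn_in,
                 antitoxin = antitoxin, threshold = threshold),
            class = "architecture_comparison")
}

#' @export
print.architecture_comparison <- function(x, ...) {
  cat("Architecture comparison (", length(x$seeds), " replicates x ",
      x$t_end, " h, burn-in ", x$burn_in, " h)\n", sep = "")
  print(x$summary, digits = 4, ...)
  invisible(x)
}

#' One-sided rank tests of the architecture orderings
#'
#' Tests, across replicate seeds, whether the mean persistence ratio and its
#' Fano factor are ordered uncoupled > wild type > no feedback — the
#' expectation that uncoupling transcription raises both the mean and the
#' noise of R while removing autorepression lowers both. Uses one-sided
#' Wilcoxon rank-sum tests on the replicate-level statistics.
#'
#' @param cmp an `architecture_comparison` containing all three variants
#'   with >= 10 replicates each.
#' @param alpha significance level (default 0.05).
#' @return Data frame with one row per (statistic, comparison): the
#'   hypothesized direction, p-value, and whether it is significant at
#'   `alpha`.
#' @export
test_orderings <- function(cmp, alpha = 0.05) {
  stopifnot(inherits(cmp, "architecture_comparison"))
  reps <- cmp$replicates
  need <- c("wild_type", "uncoupled", "no_feedback")
  n_by <- table(reps$variant)
  if (!all(need %in% names(n_by)) || any(n_by[need] < 10))
    stop("ordering tests need >= 10 replicates of each architecture",
         call. = FALSE)
  pairs <- list(c("uncoupled", "wild_type"), c("wild_type", "no_feedback"))
  out <- list()
  for (stat in c("mean_R", "fano_R")) {
    for (pr in pairs) {
      hi <- reps[reps$variant == pr[1], stat]
      lo <- reps[reps$variant == pr[2], stat]
      p <- stats::wilcox.test(hi, lo, alternative = "greater",
                              exact = FALSE)$p.value
      out[[length(out) + 1]] <- data.frame(
        statistic = stat, greater = pr[1], lesser = pr[2],
        p_value = p, significant = p < alpha)
    }
  }
  do.call(rbind, out)
}
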