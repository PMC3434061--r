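#' Propensity of one reaction at an integer state
#'
#' Mass-action propensity with combinatorial counting for multi-copy
#' reactants: a reactant entering with stoichiometry `r` contributes the
#' falling factorial `x(x-1)...(x-r+1)`, and the reaction's multiplier
#' supplies the half factors, so HipB dimerization at `B` copies has
#' propensity `beta_B2 * B(B-1)/2` and complex association
#' `mu * A(A-1)/2 * B2`. The propensity is zero whenever any reactant is
#' absent.
#'
#' @param reaction reaction index (1-based, in network reaction order).
#' @param state integer state vector in species order.
#' @param params,network as elsewhere.
#' @return Propensity in events/hour.
#' @export
propensity <- function(reaction, state, params, network) {
  assert_state(state, network, integer = TRUE)
  j <- as.integer(reaction)
  if (is.na(j) || j < 1L || j > length(network$rate_names))
    stop("reaction index out of range", call. = FALSE)
  k <- reaction_rates(network, params)[j]
  r <- network$reactant[, j]
  ff <- mapply(function(x, o) if (o == 0) 1 else prod(pmax(x - 0:(o - 1), 0)),
               state, r)
  unname(network$mult[j] * k * prod(ff))
}

#' Run an exact stochastic simulation
#'
#' Gillespie direct-method simulation of a reaction network. The run is the
#' study's data generator: molecule-count trajectories whose fluctuations
#' (bursty transcription and translation, binding noise, rare excursions of
#' the toxin/antitoxin ratio) are the object of analysis. Dwell-time-weighted
#' moments of every species — and of the persistence ratio
#' `R = A/(A + B)` when the network contains free `A` and `B` — are
#' accumulated exactly over `[burn_in, t_end]` during the run.
#'
#' @param network a `hipba_network` (any variant, or a custom mass-action
#'   network of the same structure).
#' @param params a `hipba_params`.
#' @param init integer initial state. Default: the deterministic equilibrium
#'   rounded to integer counts (minimizes the initial transient); pass
#'   `network$init_default` for an empty cell.
#' @param t_end simulated horizon, hours.
#' @param seed integer seed; the run is a deterministic function of
#'   (network, params, init, seed).
#' @param burn_in initial span excluded from all accumulated statistics
#'   (hours); the default discards the first 100 h so statistics reflect the
#'   stationary regime.
#' @param antitoxin accounting of free HipB in the persistence ratio:
#'   `"with_dimer"` (default) counts each unbound HipB dimer as two free
#'   antitoxin molecules, so `R = A / (A + B + 2 B2)`; `"monomer"` counts
#'   monomeric HipB only, `R = A / (A + B)`, as a sensitivity check.
#'   Promoter-bound repressors and the AB2A complex are never counted.
#' @param record `"events"` stores the state after every event (up to
#'   `max_store`); `"grid"` stores the piecewise-constant state sampled on a
#'   uniform grid of `n_grid + 1` times. Statistics are exact either way.
#' @param max_store,n_grid storage limits for the two recording modes.
#' @param threshold persistence threshold on R (default 0.5).
#' @return An object of class `ssa_run`: `times`, `states` (stored
#'   trajectory), `species`, `n_events`, `final_state`, `absorbed` flag,
#'   run metadata, and `acc`, the exact dwell-time accumulators.
#' @examples
#' net <- build_network("wild_type")
#' run <- gillespie_run(net, hipba_params(), t_end = 20, seed = 1,
#'                      burn_in = 5)
#' time_weighted_stats(run, "M")
#' @export
gillespie_run <- function(network, params, init = NULL, t_end = 1000,
                          seed = NULL, burn_in = 100,
                          antitoxin = c("with_dimer", "monomer"),
                          record = c("events", "grid"),
                          max_store = 1e6, n_grid = 2000, threshold = 0.5) {
  record <- match.arg(record)
  antitoxin <- match.arg(antitoxin)
  stopifnot(t_end > burn_in, burn_in >= 0)
  if (is.null(init)) {
    init <- round(find_equilibrium(network, params))
  }
  init <- round(as.numeric(init))
  assert_state(init, network, integer = TRUE)
  if (!is.null(seed)) set.seed(as.integer(seed))

  w <- r_weights(network, antitoxin)

  out <- ssa_run_cpp(network$reactant, network$net,
                     reaction_rates(network, params), network$mult,
                     init, t_end, burn_in,
                     record == "events", as.integer(max_store),
                     as.integer(n_grid), w$num, w$den, threshold)
  colnames(out$states) <- network$species
  names(out$final_state) <- network$species
  names(out$acc$sum_x) <- names(out$acc$sum_x2) <- network$species
  structure(list(times = out$times, states = out$states,
                 species = network$species, variant = network$variant,
                 backend = "ssa", record = record,
                 n_events = out$n_events, absorbed = out$absorbed,
                 truncated_store = out$truncated_store,
                 final_state = out$final_state,
                 t_end = t_end, burn_in = burn_in, seed = seed,
                 antitoxin = antitoxin,
                 threshold = threshold, acc = out$acc),
            class = "ssa_run")
}

# internal: per-species weights defining the persistence ratio
# R = num / (num + den). Free toxin: monomeric A. Free antitoxin: monomeric
# B, plus 2 per unbound dimer under the default accounting. Complexed (AB2A)
# and promoter-bound molecules never count.
r_weights <- function(network, antitoxin = "with_dimer") {
  nS <- length(network$species)
  num <- den <- numeric(nS)
  iA <- match("A", network$species)
  iB <- match("B", network$species)
  if (is.na(iA) || is.na(iB)) return(list(num = num, den = den))
  num[iA] <- 1
  den[iB] <- 1
  iB2 <- match("B2", network$species)
  if (antitoxin == "with_dimer" && !is.na(iB2)) den[iB2] <- 2
  list(num = num, den = den)
}

#' @export
print.ssa_run <- function(x, ...) {
  cat("SSA run (variant '", x$variant, "'): ", format(x$n_events, big.mark = ","),
      " events over ", x$t_end, " h (burn-in ", x$burn_in, " h), seed ",
      if (is.null(x$seed)) "NULL" else x$seed, "\n", sep = "")
  if (x$absorbed) cat("  note: all propensities reached zero (absorbed)\n")
  invisible(x)
}

#' Dwell-time-weighted moments of an observable
#'
#' Mean, variance and Fano factor (variance/mean) of a species or of the
#' persistence ratio R, weighted by the time the trajectory dwells in each
#' state over `[burn_in, t_end]` — not by event counts. For an `ssa_run`
#' these come from exact accumulators integrated during simulation.
#'
#' @param run an `ssa_run`.
#' @param observable a species name, or `"R"` for the persistence ratio
#'   (intervals with `A + B = 0` are excluded as undefined).
#' @return List with `mean`, `var`, `fano`, and `time` (the observation
#'   time; for `"R"` the defined dwell time).
#' @export
time_weighted_stats <- function(run, observable) {
  stopifnot(inherits(run, "ssa_run"))
  acc <- run$acc
  if (identical(observable, "R")) {
    Td <- acc$r_time_defined
    if (Td <= 0) stop("R is undefined (A + B = 0) for the whole run",
                      call. = FALSE)
    m <- acc$r_sum / Td
    v <- max(acc$r_sum2 / Td - m^2, 0)
  } else {
    i <- match(observable, run$species)
    if (is.na(i)) stop("unknown observable: ", observable, call. = FALSE)
    Td <- acc$T
    m <- acc$sum_x[[i]] / Td
    v <- max(acc$sum_x2[[i]] / Td - m^2, 0)
  }
  fano <- if (m > 0) v / m else if (v == 0) NA_real_ else
    stop("Fano factor undefined: zero mean with nonzero variance",
         call. = FALSE)
  list(mean = m, var = v, fano = fano, time = Td)
}

#' Dwell-time-weighted statistics of a piecewise-constant series
#'
#' Helper for trajectories stored as (times, values) where each value holds
#' from its time until the next: computes the dwell-weighted mean, variance
#' and Fano factor over `[times[1], t_end]`. `NA` values mark undefined
#' intervals, which are excluded. Inserting redundant sampling points leaves
#' the results unchanged.
#'
#' @param times strictly increasing times (hours).
#' @param values observable values, one per time.
#' @param t_end end of the observation window (defaults to the last time).
#' @return List with `mean`, `var`, `fano`, `time`.
#' @export
dwell_stats <- function(times, values, t_end = NULL) {
  stopifnot(length(times) == length(values), !is.unsorted(times, strictly = TRUE))
  if (is.null(t_end)) t_end <- times[length(times)]
  w <- diff(c(times, t_end))
  keep <- !is.na(values) & w > 0
  w <- w[keep]; v <- values[keep]
  if (!length(w)) stop("no defined dwell time in series", call. = FALSE)
  Td <- sum(w)
  m <- sum(w * v) / Td
  var <- max(sum(w * v^2) / Td - m^2, 0)
  list(mean = m, var = var,
       fano = if (m > 0) var / m else NA_real_, time = Td)
}
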