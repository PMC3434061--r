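#' Deterministic right-hand side of a reaction network
#'
#' Evaluates the mass-action time derivatives of all species: for each
#' reaction the flux is `mult * k * prod(x^order)` and the derivative vector
#' is the net stoichiometry matrix applied to the fluxes. For the wild-type
#' network this reproduces, term for term, the printed rate equations of the
#' operon model, including the half factors on dimerization and complex
#' association/dissociation.
#'
#' @param state named or unnamed numeric vector of species amounts
#'   (molecules), in `network$species` order. Negative amounts are rejected.
#' @param params a `hipba_params` object.
#' @param network a `hipba_network`.
#' @return Numeric vector of derivatives (molecules/hour), named by species.
#' @examples
#' net <- build_network("wild_type")
#' s <- net$init_default          # one free promoter, nothing else
#' ode_rhs(s, hipba_params(), net)[["M"]]  # alpha * 1 = 60
#' @export
ode_rhs <- function(state, params, network) {
  assert_state(state, network)
  k <- reaction_rates(network, params)
  flux <- network$mult * k *
    apply(network$reactant, 2, function(r) prod(state^r))
  drop(network$net %*% flux)
}

# internal: rhs closure for deSolve (avoids re-validating every step).
# Each reaction's flux is a product of at most three reactant amounts
# (repeated for higher stoichiometry); slot index nS+1 points at a padded 1,
# so flux = k * x[s1] * x[s2] * x[s3] fully vectorized over reactions.
rhs_closure <- function(params, network) {
  k <- reaction_rates(network, params) * network$mult
  reactant <- network$reactant
  net <- network$net
  nS <- nrow(reactant)
  nR <- ncol(reactant)
  if (max(colSums(reactant)) > 3)
    stop("reactions above total order 3 are not supported", call. = FALSE)
  slots <- matrix(nS + 1L, nR, 3)
  for (j in seq_len(nR)) {
    idx <- rep(which(reactant[, j] > 0), reactant[reactant[, j] > 0, j])
    if (length(idx)) slots[j, seq_along(idx)] <- idx
  }
  s1 <- slots[, 1]; s2 <- slots[, 2]; s3 <- slots[, 3]
  function(t, y, parms) {
    y <- pmax(y, 0)  # guard tiny negative excursions of the integrator
    xx <- c(y, 1)
    flux <- k * xx[s1] * xx[s2] * xx[s3]
    list(drop(net %*% flux))
  }
}

#' Integrate the deterministic model
#'
#' Integrates the mass-action ODE system with a stiff solver
#' (\code{\link[deSolve]{ode}}, method `"lsoda"`). Promoter copy conservation
#' holds along the trajectory to within the absolute tolerance.
#'
#' @param network a `hipba_network`.
#' @param params a `hipba_params`.
#' @param init initial state (defaults to `network$init_default`).
#' @param t_end final time, hours.
#' @param n_out number of equally spaced output times (including 0).
#' @param rtol,atol relative/absolute integration tolerances.
#' @return A `hipba_trajectory`: list with `times`, `states`
#'   (time x species matrix), and metadata (`variant`, `backend = "ode"`,
#'   `params`, tolerances).
#' @export
simulate_deterministic <- function(network, params, init = NULL,
                                   t_end = 1000, n_out = 201,
                                   rtol = 1e-8, atol = 1e-10) {
  if (is.null(init)) init <- network$init_default
  assert_state(init, network)
  stopifnot(t_end > 0, rtol > 0, atol > 0)
  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::ode(y = stats::setNames(as.numeric(init), network$species),
                      times = times, func = rhs_closure(params, network),
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("stiff integrator failed (variant ", network$variant,
         "; init = ", paste(signif(init, 4), collapse = ", "), ")",
         call. = FALSE)
  structure(list(times = sol[, 1],
                 states = sol[, -1, drop = FALSE],
                 variant = network$variant, backend = "ode",
                 params = params, rtol = rtol, atol = atol),
            class = "hipba_trajectory")
}

#' @export
print.hipba_trajectory <- function(x, ...) {
  cat("HipBA trajectory (", x$backend, ", variant '", x$variant, "'): ",
      length(x$times), " time points over [",
      signif(min(x$times), 4), ", ", signif(max(x$times), 4), "] h\n",
      sep = "")
  invisible(x)
}

#' Find a deterministic equilibrium
#'
#' Locates a steady state by long integration followed by Newton polishing.
#' The Jacobian of the raw system is singular along promoter-conservation
#' directions, so during polishing the balance equation of the first species
#' of each conservation group is replaced by the conservation constraint
#' itself, giving a regular root problem.
#'
#' @param network,params as elsewhere.
#' @param init starting state; defaults to `network$init_default`.
#' @param t_max integration horizon before polishing (hours).
#' @param residual_tol maximum allowed infinity norm of the right-hand side
#'   at the returned state (molecules/hour).
#' @param polish if `FALSE`, return the integration endpoint (still subject
#'   to the residual check).
#' @return Named numeric vector: the equilibrium state, with attribute
#'   `residual` (infinity norm of the rhs there).
#' @export
find_equilibrium <- function(network, params, init = NULL, t_max = 1000,
                             residual_tol = 1e-6, polish = TRUE) {
  if (is.null(init)) init <- network$init_default
  traj <- simulate_deterministic(network, params, init, t_end = t_max,
                                 n_out = 11)
  x <- pmax(traj$states[nrow(traj$states), ], 0)

  cons <- network$conservations
  totals <- vapply(cons, function(cv) sum(init[match(cv$species,
                                                     network$species)]),
                   numeric(1))
  replace_rows <- vapply(cons, function(cv)
    match(cv$species[1], network$species), integer(1))
  resid_fn <- function(y) {
    f <- ode_rhs(pmax(y, 0), params, network)
    for (i in seq_along(cons)) {
      idx <- match(cons[[i]]$species, network$species)
      f[replace_rows[i]] <- sum(y[idx]) - totals[i]
    }
    f
  }

  if (polish) {
    for (iter in 1:50) {
      f <- resid_fn(x)
      if (max(abs(f)) < residual_tol / 10) break
      J <- num_jacobian(resid_fn, x)
      step <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(step)) break
      lambda <- 1
      repeat {
        x_new <- pmax(x + lambda * step, 0)
        if (max(abs(resid_fn(x_new))) < max(abs(f)) || lambda < 1e-6) break
        lambda <- lambda / 2
      }
      if (max(abs(x_new - x)) == 0) break
      x <- x_new
    }
  }

  res <- max(abs(ode_rhs(pmax(x, 0), params, network)))
  if (res > residual_tol)
    stop("equilibrium search did not converge: residual ", signif(res, 3),
         " molecules/hour exceeds ", residual_tol, " (variant ",
         network$variant, ")", call. = FALSE)
  structure(stats::setNames(pmax(x, 0), network$species), residual = res)
}

# internal: central-difference Jacobian
num_jacobian <- function(f, x, h_rel = 1e-7) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (i in seq_len(n)) {
    h <- max(h_rel, h_rel * abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- max(x[i] - h, 0)
    J[, i] <- (f(xp) - f(xm)) / (xp[i] - xm[i])
  }
  J
}
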