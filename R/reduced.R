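#' Quasi-steady-state values of the fast species
#'
#' The promoter states, mRNA, HipB monomer and HipB dimer equilibrate fast
#' relative to HipA (A) and the toxin-antitoxin complex (AB2A): promoter
#' binding/unbinding, mRNA turnover and HipB turnover all run on minute
#' timescales while free HipA turns over in hours. Setting their six balance
#' equations to zero at fixed (A, AB2A) collapses, after eliminating the
#' promoter and mRNA balances analytically, to a single scalar balance for
#' the dimer:
#' \deqn{g(B2) = \tfrac12 \beta_{B2} B(M(B2))^2
#'   - (\tfrac12 \mu A^2 + \delta_{B2}) B2 + \tfrac12 \mu_R AB2A = 0,}
#' where the promoter occupancies, mRNA and monomeric B follow from B2 in
#' closed form. `g` is strictly decreasing with `g(0) > 0`, so the
#' nonnegative root is unique; it is found by bracketed root finding.
#'
#' @param A,AB2A slow-variable amounts (molecules), nonnegative scalars.
#' @param params a `hipba_params`.
#' @param promoter_copies total promoter copies (default 1).
#' @return Named vector of the fast states `P`, `Pp`, `Ppp`, `M`, `B`, `B2`.
#' @export
qss_fast_states <- function(A, AB2A, params, promoter_copies = 1) {
  assert_params(params)
  stopifnot(length(A) == 1, length(AB2A) == 1, A >= 0, AB2A >= 0)
  v <- params$value
  n <- promoter_copies

  # promoter occupancies and mRNA at given B2 (and the fixed AB2A)
  fast_given_b2 <- function(B2) {
    P <- n / (1 + v[["theta_B2"]] * B2 / v[["gamma_B2"]] +
                v[["theta_AB2A"]] * AB2A / v[["gamma_AB2A"]])
    Pp <- v[["theta_B2"]] * P * B2 / v[["gamma_B2"]]
    Ppp <- v[["theta_AB2A"]] * P * AB2A / v[["gamma_AB2A"]]
    M <- (v[["alpha"]] * P + v[["alpha_B2"]] * Pp +
            v[["alpha_AB2A"]] * Ppp) / v[["delta_M"]]
    # positive root of beta_B2 B^2 + delta_B B - beta_B M = 0
    B <- (-v[["delta_B"]] +
            sqrt(v[["delta_B"]]^2 + 4 * v[["beta_B2"]] * v[["beta_B"]] * M)) /
      (2 * v[["beta_B2"]])
    c(P = unname(P), Pp = unname(Pp), Ppp = unname(Ppp),
      M = unname(M), B = unname(B))
  }
  g <- function(B2) {
    f <- fast_given_b2(B2)
    0.5 * v[["beta_B2"]] * f[["B"]]^2 -
      (0.5 * v[["mu"]] * A^2 + v[["delta_B2"]]) * B2 +
      0.5 * v[["mu_R"]] * AB2A
  }
  g0 <- g(0)
  if (g0 <= 0) return(c(fast_given_b2(0), B2 = 0))
  hi <- g0 / v[["delta_B2"]] + 1  # g(hi) <= -delta_B2 < 0 by monotonicity
  B2 <- stats::uniroot(g, c(0, hi), tol = 1e-13 * hi)$root
  c(fast_given_b2(B2), B2 = unname(B2))
}

#' Right-hand side of the reduced two-dimensional model
#'
#' Time derivatives of the slow variables (A, AB2A) with all fast species
#' replaced by their quasi-steady-state values: the A and AB2A lines of the
#' full mass-action system evaluated on the slow manifold.
#'
#' @inheritParams qss_fast_states
#' @return Numeric vector `c(dA, dAB2A)` in molecules/hour.
#' @export
reduced_rhs <- function(A, AB2A, params, promoter_copies = 1) {
  fast <- qss_fast_states(A, AB2A, params, promoter_copies)
  net <- reduced_cache_network(promoter_copies)
  full <- c(P = fast[["P"]], Pp = fast[["Pp"]], Ppp = fast[["Ppp"]],
            M = fast[["M"]], A = A, B = fast[["B"]], B2 = fast[["B2"]],
            AB2A = AB2A)
  d <- ode_rhs(full[net$species], params, net)
  c(dA = unname(d[["A"]]), dAB2A = unname(d[["AB2A"]]))
}

# memoised wild-type network (reduction is defined for the operon model)
reduced_cache <- new.env(parent = emptyenv())
reduced_cache_network <- function(n) {
  key <- as.character(n)
  if (is.null(reduced_cache[[key]]))
    reduced_cache[[key]] <- build_network("wild_type", n)
  reduced_cache[[key]]
}

#' Count equilibria of a planar vector field by nullcline intersection
#'
#' Generic phase-plane worker: evaluates both components of `f` on a grid,
#' traces the two nullclines (sign changes along grid lines, refined by
#' bisection), starts a damped Newton iteration in every grid cell where
#' both components change sign, and merges the converged roots. Each root is
#' classified as stable or unstable from the eigenvalues of a
#' finite-difference Jacobian.
#'
#' @param f function `f(x, y)` returning `c(dx, dy)`.
#' @param xlim,ylim grid ranges.
#' @param n grid resolution per axis.
#' @param log_grid if `TRUE` the grid is geometric (ranges must be
#'   positive), appropriate for molecule counts spanning decades.
#' @param merge_tol relative distance below which two roots are the same
#'   equilibrium.
#' @param residual_tol maximum `|f|` at a reported intersection.
#' @return List of class `nullcline_set`: `n_equilibria`, `points` (data
#'   frame x, y, stable, residual), `nullclines` (data frame x, y,
#'   nullcline in `"dx"`/`"dy"`), and the grid specification.
#' @export
count_equilibria_2d <- function(f, xlim, ylim, n = 121, log_grid = TRUE,
                                merge_tol = 0.005, residual_tol = 1e-4) {
  gridline <- function(lim) {
    if (log_grid) {
      stopifnot(all(lim > 0))
      exp(seq(log(lim[1]), log(lim[2]), length.out = n))
    } else seq(lim[1], lim[2], length.out = n)
  }
  xs <- gridline(xlim); ys <- gridline(ylim)
  F1 <- matrix(NA_real_, n, n); F2 <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    v <- f(xs[i], ys[j]); F1[i, j] <- v[1]; F2[i, j] <- v[2]
  }
  if (any(!is.finite(F1)) || any(!is.finite(F2)))
    stop("vector field not finite on the requested grid", call. = FALSE)

  # trace each nullcline by bisection along grid columns/rows
  bisect <- function(g, lo, hi) {
    glo <- g(lo)
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      gm <- g(mid)
      if (glo * gm <= 0) hi <- mid else { lo <- mid; glo <- gm }
    }
    (lo + hi) / 2
  }
  trace_one <- function(Fm, comp) {
    pts <- list()
    for (i in seq_len(n)) {           # scan along y at fixed x
      s <- Fm[i, ]
      ch <- which(s[-n] * s[-1] < 0 | s[-n] == 0)
      for (j in ch) {
        yy <- bisect(function(y) f(xs[i], y)[comp], ys[j], ys[j + 1])
        pts[[length(pts) + 1]] <- c(xs[i], yy)
      }
    }
    for (j in seq_len(n)) {           # scan along x at fixed y
      s <- Fm[, j]
      ch <- which(s[-n] * s[-1] < 0 | s[-n] == 0)
      for (i in ch) {
        xx <- bisect(function(x) f(x, ys[j])[comp], xs[i], xs[i + 1])
        pts[[length(pts) + 1]] <- c(xx, ys[j])
      }
    }
    if (!length(pts)) return(data.frame(x = numeric(0), y = numeric(0)))
    m <- do.call(rbind, pts)
    data.frame(x = m[, 1], y = m[, 2])
  }
  nc1 <- trace_one(F1, 1); nc2 <- trace_one(F2, 2)
  nullclines <- rbind(
    if (nrow(nc1)) cbind(nc1, nullcline = "dx"),
    if (nrow(nc2)) cbind(nc2, nullcline = "dy"))

  # Newton starts: cells where both components change sign among corners
  sgn_span <- function(Fm, i, j) {
    v <- c(Fm[i, j], Fm[i + 1, j], Fm[i, j + 1], Fm[i + 1, j + 1])
    min(v) <= 0 && max(v) >= 0
  }
  roots <- list()
  scale_xy <- c(mean(abs(xs)), mean(abs(ys)))
  for (i in seq_len(n - 1)) for (j in seq_len(n - 1)) {
    if (!(sgn_span(F1, i, j) && sgn_span(F2, i, j))) next
    x0 <- c(sqrt(xs[i] * xs[i + 1]), sqrt(ys[j] * ys[j + 1]))
    if (!log_grid) x0 <- c((xs[i] + xs[i + 1]) / 2, (ys[j] + ys[j + 1]) / 2)
    r <- newton_2d(f, x0, residual_tol)
    if (!is.null(r)) roots[[length(roots) + 1]] <- r
  }
  pts <- merge_roots(roots, merge_tol)
  points <- if (length(pts)) {
    do.call(rbind, lapply(pts, function(p) {
      J <- jac_2d(f, p)
      data.frame(x = p[1], y = p[2],
                 stable = all(Re(eigen(J, only.values = TRUE)$values) < 0),
                 residual = max(abs(f(p[1], p[2]))))
    }))
  } else data.frame(x = numeric(0), y = numeric(0),
                    stable = logical(0), residual = numeric(0))

  structure(list(n_equilibria = length(pts), points = points,
                 nullclines = nullclines,
                 grid = list(xlim = xlim, ylim = ylim, n = n,
                             log_grid = log_grid)),
            class = "nullcline_set")
}

jac_2d <- function(f, p) {
  h <- pmax(1e-6, 1e-6 * abs(p))
  J <- matrix(0, 2, 2)
  for (k in 1:2) {
    pp <- p; pm <- p
    pp[k] <- p[k] + h[k]; pm[k] <- max(p[k] - h[k], 0)
    J[, k] <- (f(pp[1], pp[2]) - f(pm[1], pm[2])) / (pp[k] - pm[k])
  }
  J
}

newton_2d <- function(f, x0, residual_tol, max_iter = 40) {
  x <- x0
  for (it in seq_len(max_iter)) {
    fv <- f(x[1], x[2])
    if (max(abs(fv)) < residual_tol / 10) return(x)
    J <- jac_2d(f, x)
    step <- tryCatch(solve(J, -fv), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lambda <- 1
    repeat {
      xn <- pmax(x + lambda * step, 0)
      if (max(abs(f(xn[1], xn[2]))) < max(abs(fv)) || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    if (max(abs(xn - x)) == 0) break
    x <- xn
  }
  if (max(abs(f(x[1], x[2]))) < residual_tol) x else NULL
}

merge_roots <- function(roots, merge_tol) {
  out <- list()
  for (r in roots) {
    dup <- FALSE
    for (q in out) {
      rel <- max(abs(r - q) / pmax(abs(r), abs(q), 1e-6))
      if (rel < merge_tol) { dup <- TRUE; break }
    }
    if (!dup) out[[length(out) + 1]] <- r
  }
  out
}

#' @export
print.nullcline_set <- function(x, ...) {
  cat("Phase-plane analysis: ", x$n_equilibria, " equilibrium point(s)\n",
      sep = "")
  if (nrow(x$points)) print(x$points, ...)
  invisible(x)
}

#' Count equilibria of the reduced HipBA model
#'
#' Traces the nullclines of the quasi-steady-state-reduced (A, AB2A) model
#' on a geometric grid and counts their intersection points. At the nominal
#' rate constants the two nullclines cross exactly once: the circuit is
#' monostable, so coexisting persister and normal states cannot arise from
#' deterministic bistability. The default grid brackets the nominal
#' equilibrium (A about 1, AB2A about 5 molecules) by more than a factor of
#' 30 in each direction.
#'
#' @param params a `hipba_params`.
#' @param A_range,AB2A_range grid ranges (molecules), positive.
#' @param n grid resolution per axis.
#' @param promoter_copies promoter copy number.
#' @param merge_tol,residual_tol see \code{\link{count_equilibria_2d}}.
#' @return A `nullcline_set` (see \code{\link{count_equilibria_2d}});
#'   element `n_equilibria` is the intersection count.
#' @export
count_equilibria <- function(params, A_range = c(0.01, 1000),
                             AB2A_range = c(0.01, 1000), n = 121,
                             promoter_copies = 1,
                             merge_tol = 0.005, residual_tol = 1e-4) {
  f <- function(A, AB2A) reduced_rhs(A, AB2A, params, promoter_copies)
  count_equilibria_2d(f, A_range, AB2A_range, n = n, log_grid = TRUE,
                      merge_tol = merge_tol, residual_tol = residual_tol)
}

#' Export nullcline and intersection data as CSV
#'
#' @param ncs a `nullcline_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
nullclines_to_csv <- function(ncs, path) {
  stopifnot(inherits(ncs, "nullcline_set"))
  df <- ncs$nullclines
  names(df) <- c("A", "AB2A", "which_nullcline")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
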