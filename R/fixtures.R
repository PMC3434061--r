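#' Synthetic bistable control network (Schlogl model)
#'
#' Builds the classic one-species mass-action bistable system
#' `2X -> 3X` (k1), `3X -> 2X` (k2), `0 -> X` (k3), `X -> 0` (k4),
#' used as a planted positive control: unlike the HipBA circuit it has two
#' stable equilibria, so any multistability-detection machinery (equilibrium
#' clustering, the 1\% metric, parameter scans) must flag it. The network is
#' entirely synthetic — it carries its own rate values and does not read a
#' `hipba_params` object.
#'
#' With the default rates the deterministic model
#' `dX/dt = (k1/2) X^2 - (k2/6) X^3 + k3 - k4 X` has stable states near
#' X = 87 and X = 563 with an unstable point near 247.
#'
#' @param k1,k2,k3,k4 rate constants (per hour, molecule units).
#' @return A `hipba_network`-structured object with a single species `X`
#'   and fixed `rate_values`.
#' @export
schlogl_network <- function(k1 = 0.03, k2 = 1e-4, k3 = 200, k4 = 3.5) {
  reactions <- list(
    rx("k1", from = c(X = 2), to = c(X = 3), mult = 1 / 2),
    rx("k2", from = c(X = 3), to = c(X = 2), mult = 1 / 6),
    rx("k3", to = c(X = 1)),
    rx("k4", from = c(X = 1))
  )
  net <- make_network("schlogl_fixture", species = "X",
                      roles = c(X = "protein"), reactions,
                      conservations = list(),
                      init = c(X = 0))
  net$rate_values <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4)
  net
}

#' Synthetic bistable two-dimensional toggle right-hand side
#'
#' Returns the vector field of a standard mutually repressing two-gene
#' toggle, `dx/dt = a / (1 + y^n) - x`, `dy/dt = a / (1 + x^n) - y`.
#' For `a` large enough at `n = 2` the system has two stable equilibria and
#' one unstable saddle, so the phase-plane equilibrium counter must report
#' three intersections. Used as a planted control for the nullcline
#' machinery; this is not a mass-action HipBA object.
#'
#' @param a maximal synthesis rate; @param n Hill coefficient.
#' @return A function `f(x, y)` returning `c(dx, dy)`.
#' @export
toggle_rhs <- function(a = 10, n = 2) {
  function(x, y) c(a / (1 + y^n) - x, a / (1 + x^n) - y)
}

# internal: constitutive transcription fixture P -> P + M (alpha),
# M -> 0 (delta_M): stationary M is Poisson with mean alpha/delta_M
birth_death_network <- function() {
  reactions <- list(
    rx("alpha", from = c(P = 1), to = c(P = 1, M = 1)),
    rx("delta_M", from = c(M = 1))
  )
  make_network("birth_death_fixture", species = c("P", "M"),
               roles = c(P = "promoter", M = "mrna"), reactions,
               conservations = list(list(species = "P", total = 1)),
               init = c(P = 1, M = 0))
}

# internal: two-state promoter fixture P + B2 <-> P' with B2 held constant
# (catalytic form); stationary occupancy of P' is
# theta_B2*B2 / (theta_B2*B2 + gamma_B2)
two_state_promoter_network <- function(b2 = 1) {
  reactions <- list(
    rx("theta_B2", from = c(P = 1, B2 = 1), to = c(Pp = 1, B2 = 1)),
    rx("gamma_B2", from = c(Pp = 1), to = c(P = 1))
  )
  make_network("two_state_fixture", species = c("P", "Pp", "B2"),
               roles = c(P = "promoter", Pp = "promoter", B2 = "protein"),
               reactions,
               conservations = list(list(species = c("P", "Pp"), total = 1)),
               init = c(P = 1, Pp = 0, B2 = b2))
}
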