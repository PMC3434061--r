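# Independent oracles used across tests.

# Literal hand-coded transcription of the wild-type rate equations
# (promoter switching, transcription from all three states, translation,
# dimerization, complex formation/dissociation, degradation), written
# directly from the printed equations and independent of the ReactionNetwork
# machinery. State order: P, Pp, Ppp, M, A, B, B2, AB2A.
eq1_rhs_oracle <- function(s, p) {
  v <- p$value
  P <- s[1]; Pp <- s[2]; Ppp <- s[3]; M <- s[4]
  A <- s[5]; B <- s[6]; B2 <- s[7]; AB2A <- s[8]
  c(
    v[["gamma_B2"]] * Pp + v[["gamma_AB2A"]] * Ppp -
      v[["theta_B2"]] * P * B2 - v[["theta_AB2A"]] * P * AB2A,
    v[["theta_B2"]] * P * B2 - v[["gamma_B2"]] * Pp,
    v[["theta_AB2A"]] * P * AB2A - v[["gamma_AB2A"]] * Ppp,
    v[["alpha"]] * P + v[["alpha_B2"]] * Pp + v[["alpha_AB2A"]] * Ppp -
      v[["delta_M"]] * M,
    v[["beta_A"]] * M - v[["mu"]] * A^2 * B2 + v[["mu_R"]] * AB2A -
      v[["delta_A"]] * A,
    v[["beta_B"]] * M - v[["beta_B2"]] * B^2 - v[["delta_B"]] * B,
    0.5 * v[["beta_B2"]] * B^2 - 0.5 * v[["mu"]] * A^2 * B2 +
      0.5 * v[["mu_R"]] * AB2A - v[["theta_B2"]] * P * B2 +
      v[["gamma_B2"]] * Pp - v[["delta_B2"]] * B2,
    0.5 * v[["mu"]] * A^2 * B2 - 0.5 * v[["mu_R"]] * AB2A -
      v[["theta_AB2A"]] * P * AB2A + v[["gamma_AB2A"]] * Ppp -
      v[["delta_AB2A"]] * AB2A
  )
}

# random valid wild-type state (promoter copies summing to 1)
random_wt_state <- function() {
  pr <- stats::runif(3)
  pr <- pr / sum(pr)
  c(pr, stats::runif(5, 0, 1000))
}

# relative difference with a floor, the metric used throughout
rel_diff <- function(x, y, eps = 1e-6) max(abs(x - y) / pmax(x, y, eps))

# a minimal ssa_run-shaped object for unit-testing the ratio statistics
# without running the simulator
fake_run <- function(times, A, B, B2 = 0, t_end = max(times) + 1,
                     burn_in = 0) {
  states <- cbind(A = A, B = B, B2 = B2)
  structure(list(times = times, states = states,
                 species = colnames(states), variant = "synthetic",
                 backend = "ssa", record = "events",
                 n_events = length(times) - 1, absorbed = FALSE,
                 truncated_store = FALSE,
                 final_state = states[nrow(states), ],
                 t_end = t_end, burn_in = burn_in, seed = NA,
                 antitoxin = "with_dimer", threshold = 0.5,
                 acc = NULL),
            class = "ssa_run")
}
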