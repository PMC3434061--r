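p_nom <- hipba_params()
wt <- build_network("wild_type")

test_that("propensities use combinatorial counting with the half factors", {
  s <- setNames(c(1, 0, 0, 0, 0, 2, 0, 0), wt$species)  # B = 2
  j_dim <- which(wt$rate_names == "beta_B2")
  expect_equal(propensity(j_dim, s, p_nom, wt), 60)  # 60 * 2*1/2
  s["B"] <- 5
  expect_equal(propensity(j_dim, s, p_nom, wt), 60 * 5 * 4 / 2)
  # association needs two free toxins
  j_as <- which(wt$rate_names == "mu")
  s2 <- setNames(c(1, 0, 0, 0, 1, 0, 10, 0), wt$species)  # A = 1
  expect_equal(propensity(j_as, s2, p_nom, wt), 0)
  s2["A"] <- 3
  expect_equal(propensity(j_as, s2, p_nom, wt), 60 * 3 * 2 / 2 * 10)
  # transcription from the repressed promoter state
  j_tr <- which(wt$rate_names == "alpha_B2")
  s3 <- setNames(c(0, 1, 0, 0, 0, 0, 0, 0), wt$species)
  expect_equal(propensity(j_tr, s3, p_nom, wt), 6)
  expect_error(propensity(j_tr, s3 - 1, p_nom, wt), "nonnegative")
  expect_error(propensity(j_tr, s3 + 0.5, p_nom, wt), "integer")
})

test_that("identical seeds give identical event sequences", {
  r1 <- gillespie_run(wt, p_nom, t_end = 50, seed = 99, burn_in = 10)
  r2 <- gillespie_run(wt, p_nom, t_end = 50, seed = 99, burn_in = 10)
  expect_identical(r1$times, r2$times)
  expect_identical(r1$states, r2$states)
  expect_identical(r1$acc, r2$acc)
  r3 <- gillespie_run(wt, p_nom, t_end = 50, seed = 100, burn_in = 10)
  expect_false(identical(r1$times, r3$times))
})

test_that("promoter copies are conserved exactly at every event", {
  run <- gillespie_run(wt, p_nom, t_end = 100, seed = 17, burn_in = 0)
  ptot <- rowSums(run$states[, c("P", "Pp", "Ppp")])
  expect_true(all(ptot == 1))
  expect_true(all(run$states >= 0))
  expect_true(all(run$states == round(run$states)))
  expect_true(all(diff(run$times) >= 0))
})

test_that("constitutive transcription recovers the Poisson stationary law", {
  bd <- hipbasim:::birth_death_network()
  means <- fanos <- numeric(10)
  for (s in 1:10) {
    run <- gillespie_run(bd, p_nom, init = c(P = 1, M = 0), t_end = 600,
                         seed = 400 + s, burn_in = 100)
    st <- time_weighted_stats(run, "M")
    means[s] <- st$mean; fanos[s] <- st$fano
  }
  se_m <- sd(means) / sqrt(10)
  se_f <- sd(fanos) / sqrt(10)
  expect_lt(abs(mean(means) - 10), 3 * se_m)   # alpha / delta_M
  expect_lt(abs(mean(fanos) - 1), 3 * se_f)    # Poisson Fano factor
})

test_that("two-state promoter occupancy matches its closed form", {
  ts <- hipbasim:::two_state_promoter_network(b2 = 1)
  occ <- numeric(10)
  for (s in 1:10) {
    run <- gillespie_run(ts, p_nom, init = c(P = 1, Pp = 0, B2 = 1),
                         t_end = 60, seed = 500 + s, burn_in = 10,
                         record = "grid", n_grid = 10)
    occ[s] <- time_weighted_stats(run, "Pp")$mean
  }
  theo <- 1500 / (1500 + 60)   # theta*B2 / (theta*B2 + gamma)
  expect_lt(abs(mean(occ) - theo), 3 * sd(occ) / sqrt(10) + 1e-6)
})

test_that("ensemble statistics agree between disjoint seed batches", {
  bd <- hipbasim:::birth_death_network()
  fano_batch <- function(seeds) {
    f <- vapply(seeds, function(s)
      time_weighted_stats(gillespie_run(bd, p_nom, init = c(P = 1, M = 0),
                                        t_end = 400, seed = s,
                                        burn_in = 100), "M")$fano,
      numeric(1))
    c(mean(f), sd(f) / sqrt(length(f)))
  }
  b1 <- fano_batch(1:8)
  b2 <- fano_batch(101:108)
  expect_lt(abs(b1[1] - b2[1]), 3 * sqrt(b1[2]^2 + b2[2]^2))
})

test_that("dwell-weighted statistics ignore redundant sampling points", {
  tt <- c(0, 1, 3, 6)
  vv <- c(2, 5, 2, 7)
  s1 <- dwell_stats(tt, vv, t_end = 10)
  # insert redundant breakpoints carrying the same piecewise-constant values
  tt2 <- c(0, 0.5, 1, 2, 3, 4.5, 6, 8)
  vv2 <- c(2, 2, 5, 5, 2, 2, 7, 7)
  s2 <- dwell_stats(tt2, vv2, t_end = 10)
  expect_equal(s1$mean, s2$mean)
  expect_equal(s1$var, s2$var)
  # constant observable has zero variance
  expect_equal(dwell_stats(tt, rep(4, 4))$var, 0)
})

test_that("volume-scaled stochastic means approach the deterministic equilibrium", {
  # extensive 10x scaling: gene copies x10, second-order constants /10,
  # the third-order association /100. All counts then scale up tenfold,
  # intrinsic fluctuations shrink, and time-averaged counts approach the
  # mass-action fixed point
  omega <- 10
  big <- build_network("wild_type", promoter_copies = omega)
  p_big <- hipba_params(theta_B2 = 1500 / omega, theta_AB2A = 1500 / omega,
                        beta_B2 = 60 / omega, mu = 60 / omega^2)
  eq <- find_equilibrium(big, p_big)
  sp <- c("M", "A", "B", "B2", "AB2A")
  avg <- matrix(NA_real_, 10, length(sp), dimnames = list(NULL, sp))
  for (s in 1:10) {
    run <- gillespie_run(big, p_big, t_end = 400, seed = 700 + s,
                         burn_in = 100, record = "grid", n_grid = 10)
    avg[s, ] <- vapply(sp, function(x) time_weighted_stats(run, x)$mean,
                       numeric(1))
  }
  for (x in sp) {
    se <- sd(avg[, x]) / sqrt(10)
    expect_lt(abs(mean(avg[, x]) - eq[[x]]), 3 * se + 0.01 * eq[[x]])
  }
})

test_that("grid recording reproduces the dwell statistics of full storage", {
  run_e <- gillespie_run(wt, p_nom, t_end = 150, seed = 31, burn_in = 50)
  run_g <- gillespie_run(wt, p_nom, t_end = 150, seed = 31, burn_in = 50,
                         record = "grid", n_grid = 100)
  # same underlying event sequence, so exact accumulators are identical
  expect_equal(run_e$acc, run_g$acc)
  # and stats computed from the fully stored trajectory match them
  # (the state holding at burn-in was set by the last event before it)
  i0 <- max(which(run_e$times <= 50))
  later <- run_e$times > 50
  manual <- dwell_stats(c(50, run_e$times[later]),
                        c(run_e$states[i0, "A"], run_e$states[later, "A"]),
                        t_end = 150)
  expect_equal(manual$mean, time_weighted_stats(run_e, "A")$mean,
               tolerance = 1e-10)
  expect_equal(manual$var, time_weighted_stats(run_e, "A")$var,
               tolerance = 1e-8)
})
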