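p_nom <- hipba_params()
wt <- build_network("wild_type")

test_that("quasi-steady states zero the fast balances of the full model", {
  set.seed(4)
  cases <- rbind(c(0, 0), c(1, 5), c(0.1, 50), c(30, 0.2),
                 cbind(runif(6, 0, 20), runif(6, 0, 20)))
  for (i in seq_len(nrow(cases))) {
    A <- cases[i, 1]; AB2A <- cases[i, 2]
    fast <- qss_fast_states(A, AB2A, p_nom)
    full <- c(P = fast[["P"]], Pp = fast[["Pp"]], Ppp = fast[["Ppp"]],
              M = fast[["M"]], A = A, B = fast[["B"]], B2 = fast[["B2"]],
              AB2A = AB2A)
    d <- ode_rhs(full, p_nom, wt)
    expect_lt(max(abs(d[c("P", "Pp", "Ppp", "M", "B", "B2")])), 1e-6)
    expect_true(all(fast >= 0))
  }
})

test_that("with no slow species the dimer balance has the brute-force root", {
  # at A = AB2A = 0 the fast system collapses to one equation in B2;
  # locate its root by dense grid sign change, independent of the solver
  fast <- qss_fast_states(0, 0, p_nom)
  g <- function(B2) {
    f <- sapply(B2, function(b2) {
      P <- 1 / (1 + p_nom$value[["theta_B2"]] * b2 / p_nom$value[["gamma_B2"]])
      M <- (p_nom$value[["alpha"]] * P + p_nom$value[["alpha_B2"]] *
              (1 - P)) / p_nom$value[["delta_M"]]
      B <- (-p_nom$value[["delta_B"]] + sqrt(p_nom$value[["delta_B"]]^2 +
             4 * p_nom$value[["beta_B2"]] * p_nom$value[["beta_B"]] * M)) /
        (2 * p_nom$value[["beta_B2"]])
      0.5 * p_nom$value[["beta_B2"]] * B^2 - p_nom$value[["delta_B2"]] * b2
    })
    f
  }
  grid <- seq(0, 30, by = 1e-3)
  gv <- g(grid)
  sign_change <- which(gv[-length(gv)] * gv[-1] <= 0)[1]
  expect_equal(fast[["B2"]], grid[sign_change], tolerance = 1e-3)
  expect_equal(fast[["Ppp"]], 0)
})

test_that("the slow manifold passes through the full-model equilibrium", {
  eq <- find_equilibrium(wt, p_nom)
  fast <- qss_fast_states(eq[["A"]], eq[["AB2A"]], p_nom)
  expect_lt(rel_diff(fast[c("P", "Pp", "Ppp", "M", "B", "B2")],
                     eq[c("P", "Pp", "Ppp", "M", "B", "B2")]), 1e-3)
  d <- reduced_rhs(eq[["A"]], eq[["AB2A"]], p_nom)
  expect_lt(max(abs(d)), 1e-4)
})

test_that("the toxin derivative changes sign across its nullcline", {
  eq <- find_equilibrium(wt, p_nom)
  AB2A <- eq[["AB2A"]]
  dA_low <- reduced_rhs(eq[["A"]] / 50, AB2A, p_nom)[["dA"]]
  dA_high <- reduced_rhs(eq[["A"]] * 50, AB2A, p_nom)[["dA"]]
  expect_gt(dA_low, 0)
  expect_lt(dA_high, 0)
})

test_that("toxin translation off leaves no toxin source at the origin", {
  p_off <- hipba_params(beta_A = 1e-12)
  d <- reduced_rhs(0, 0, p_off)
  expect_lt(abs(d[["dA"]]), 1e-9)
})

test_that("nominal nullclines intersect exactly once, stably under grid refinement", {
  ncs <- count_equilibria(p_nom, n = 61)
  expect_equal(ncs$n_equilibria, 1L)
  expect_true(ncs$points$stable[1])
  # intersection lifts to a full-model equilibrium
  fast <- qss_fast_states(ncs$points$x[1], ncs$points$y[1], p_nom)
  full <- c(P = fast[["P"]], Pp = fast[["Pp"]], Ppp = fast[["Ppp"]],
            M = fast[["M"]], A = ncs$points$x[1], B = fast[["B"]],
            B2 = fast[["B2"]], AB2A = ncs$points$y[1])
  expect_lt(max(abs(ode_rhs(full, p_nom, wt))), 1e-4)
  # and matches the equilibrium found by long integration
  eq <- find_equilibrium(wt, p_nom)
  expect_lt(rel_diff(c(ncs$points$x[1], ncs$points$y[1]),
                     c(eq[["A"]], eq[["AB2A"]])), 0.005)
  # doubling the grid leaves the count unchanged
  ncs2 <- count_equilibria(p_nom, n = 121)
  expect_equal(ncs2$n_equilibria, 1L)
})

test_that("a planted bistable toggle yields three intersections, two stable", {
  tg <- count_equilibria_2d(toggle_rhs(10, 2), c(0.01, 20), c(0.01, 20),
                            n = 81, log_grid = FALSE)
  expect_equal(tg$n_equilibria, 3L)
  expect_equal(sum(tg$points$stable), 2L)
  expect_equal(sum(!tg$points$stable), 1L)
  # the two stable states are symmetric partners of each other
  st <- tg$points[tg$points$stable, ]
  expect_equal(sort(round(st$x, 3)), sort(round(st$y, 3)))
})

test_that("nullcline data export has the documented CSV schema", {
  ncs <- count_equilibria_2d(toggle_rhs(10, 2), c(0.01, 20), c(0.01, 20),
                             n = 41, log_grid = FALSE)
  f <- tempfile(fileext = ".csv")
  nullclines_to_csv(ncs, f)
  df <- read.csv(f)
  expect_named(df, c("A", "AB2A", "which_nullcline"))
  expect_setequal(unique(df$which_nullcline), c("dx", "dy"))
})
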