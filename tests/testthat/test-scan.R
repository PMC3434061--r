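p_nom <- hipba_params()
wt <- build_network("wild_type")

test_that("single-parameter sampling varies only the named constant", {
  set.seed(8)
  for (nm in c("delta_A", "alpha", "mu")) {
    s <- sample_parameters(p_nom, "single_parameter", nm)
    expect_true(s$value[[nm]] != p_nom$value[[nm]])
    other <- setdiff(names(s$value), nm)
    expect_equal(s$value[other], p_nom$value[other])
    expect_true(all(s$value > 0))
  }
  expect_error(sample_parameters(p_nom, "single_parameter", "nope"),
               "which_parameter")
})

test_that("log-normal draws have the nominal median and decade-wide 95% band", {
  set.seed(9)
  draws <- replicate(1e4,
    sample_parameters(p_nom, "single_parameter", "alpha")$value[["alpha"]])
  expect_lt(abs(median(draws) - 60) / 60, 0.05)
  inside <- mean(draws >= 6 & draws <= 600)
  expect_gt(inside, 0.93)
  expect_lt(inside, 0.97)
})

test_that("all-parameter draws move every constant", {
  set.seed(10)
  s <- sample_parameters(p_nom, "all_parameters")
  expect_true(all(s$value != p_nom$value))
  expect_true(all(s$value > 0))
})

test_that("initial conditions respect ranges and hold promoters fixed", {
  set.seed(12)
  draws <- t(replicate(1e4, sample_initial_conditions(wt)))
  expect_true(all(draws[, "M"] >= 0 & draws[, "M"] <= 100))
  for (sp in c("A", "B", "B2", "AB2A"))
    expect_true(all(draws[, sp] >= 0 & draws[, sp] <= 1000))
  expect_true(all(draws[, "P"] == 1 & draws[, "Pp"] == 0 &
                    draws[, "Ppp"] == 0))
  expect_equal(mean(draws[, "M"]), 50, tolerance = 1 / 50)
})

test_that("the 1% clustering metric separates and merges as specified", {
  base <- c(1, 0, 0, 10, 1.2, 0.9, 3.6, 4.6)
  expect_equal(cluster_final_states(matrix(rep(base, 50), 50, byrow = TRUE)),
               1L)
  far <- base; far[5] <- base[5] * 1.5
  expect_equal(cluster_final_states(rbind(base, far), rel_tol = 0.01), 2L)
  set.seed(13)
  jitter <- t(replicate(40, base * runif(8, 1 - 0.009, 1)))
  expect_equal(cluster_final_states(jitter, rel_tol = 0.01), 1L)
  expect_error(cluster_final_states(matrix(numeric(0), 0, 8)), "no states")
})

test_that("scans are reproducible and the wild type scans monostable", {
  s1 <- run_scan(wt, p_nom, n_draws = 3, n_ic = 8, seed = 21)
  s2 <- run_scan(wt, p_nom, n_draws = 3, n_ic = 8, seed = 21)
  expect_identical(s1$draws, s2$draws)
  expect_identical(s1$parameter_values, s2$parameter_values)
  expect_equal(s1$verdict, "monostable")
  expect_true(all(s1$draws$clusters == 1))
})

test_that("single-parameter mode records one row per parameter per draw", {
  s <- run_scan(wt, p_nom, mode = "single_parameter",
                parameters = c("alpha", "delta_B"), n_draws = 2, n_ic = 5,
                seed = 5)
  expect_equal(nrow(s$draws), 4)
  expect_equal(s$draws$parameter, rep(c("alpha", "delta_B"), each = 2))
  # non-sampled constants stay nominal within each draw
  row1 <- s$parameter_values[1, ]
  expect_equal(row1[setdiff(names(row1), "alpha")],
               p_nom$value[setdiff(names(row1), "alpha")])
})

test_that("the planted bistable control is always detected", {
  sch <- schlogl_network()
  for (seed in c(1, 77, 301)) {
    s <- run_scan(sch, p_nom, n_draws = 2, n_ic = 20, sample = FALSE,
                  seed = seed, t_end = 200)
    expect_equal(s$verdict, "multistable")
    expect_true(any(s$draws$clusters >= 2))
  }
})

test_that("scan results persist to JSON and CSV", {
  s <- run_scan(wt, p_nom, n_draws = 2, n_ic = 4, seed = 2)
  jf <- tempfile(fileext = ".json"); cf <- tempfile(fileext = ".csv")
  scan_to_files(s, jf, cf)
  doc <- jsonlite::fromJSON(jf)
  expect_equal(doc$verdict, "monostable")
  expect_length(doc$clusters, 2)
  df <- read.csv(cf)
  expect_equal(nrow(df), 2)
  expect_true(all(hipba_param_names() %in% names(df)))
})
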