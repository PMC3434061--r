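p_nom <- hipba_params()

test_that("the ratio follows its definition on constructed states", {
  run <- fake_run(times = 0:3, A = c(10, 0, 3, 0), B = c(10, 5, 1, 0))
  ser <- compute_R(run, antitoxin = "monomer")
  expect_equal(ser$R, c(0.5, 0, 0.75, NA))
  # R = 0.5 is the boundary: not a persister
  pers <- detect_persistence(ser)
  expect_equal(pers$n_events, 1)           # only the R = 0.75 interval
  # dimer accounting counts each unbound dimer as two antitoxins
  run2 <- fake_run(times = 0:1, A = c(4, 4), B = c(2, 2), B2 = c(1, 0))
  ser2 <- compute_R(run2, antitoxin = "with_dimer")
  expect_equal(ser2$R, c(4 / 8, 4 / 6))
})

test_that("the threshold rule agrees with the raw toxin-antitoxin comparison", {
  set.seed(14)
  A <- rpois(200, 3); B <- rpois(200, 2); B2 <- rpois(200, 2)
  run <- fake_run(times = seq_along(A) - 1, A = A, B = B, B2 = B2)
  ser <- compute_R(run)
  defined <- !is.na(ser$R)
  expect_equal(ser$R[defined] > 0.5,
               (A > B + 2 * B2)[defined])
  expect_true(all(ser$R[defined] >= 0 & ser$R[defined] <= 1))
})

test_that("persistence episodes and dwell fractions match a constructed series", {
  # R: 0.3 for 2 h, 0.7 for 2 h, 0.3 for 6 h
  run <- fake_run(times = c(0, 2, 4), A = c(3, 7, 3), B = c(7, 3, 7),
                  t_end = 10)
  ser <- compute_R(run, antitoxin = "monomer")
  pers <- detect_persistence(ser)
  expect_equal(pers$n_events, 1)
  expect_equal(pers$events$start, 2)
  expect_equal(pers$events$end, 4)
  expect_equal(pers$fraction, 2 / 10)
  # a series never above threshold has no events
  flat <- compute_R(fake_run(times = 0:4, A = rep(2, 5), B = rep(3, 5)),
                    antitoxin = "monomer")
  p0 <- detect_persistence(flat)
  expect_equal(p0$n_events, 0)
  expect_equal(p0$fraction, 0)
  # an all-undefined series is flagged
  empty <- compute_R(fake_run(times = 0:2, A = rep(0, 3), B = rep(0, 3)))
  expect_error(detect_persistence(empty), "no defined ratio")
})

test_that("ratio histograms are dwell-weighted and normalized", {
  run <- fake_run(times = c(0, 1), A = c(1, 1), B = c(4, 4), t_end = 5)
  h <- r_histogram(compute_R(run, antitoxin = "monomer"), bins = 10)
  expect_equal(sum(h$mass), 1, tolerance = 1e-12)
  expect_equal(h$mass[h$lower <= 0.2 & h$upper > 0.2], 1)
  # dwell weighting: 1 h at R = 0.8, then 9 h at R = 0.2
  run2 <- fake_run(times = c(0, 1), A = c(4, 1), B = c(1, 4), t_end = 10)
  h2 <- r_histogram(compute_R(run2, antitoxin = "monomer"), bins = 10)
  expect_equal(h2$mass[h2$lower <= 0.2 & h2$upper > 0.2], 0.9)
  expect_equal(h2$mass[h2$lower <= 0.8 & h2$upper > 0.8], 0.1)
})

test_that("series statistics agree with the exact in-run accumulators", {
  wt <- build_network("wild_type")
  run <- gillespie_run(wt, p_nom, t_end = 150, seed = 8, burn_in = 50)
  ser <- compute_R(run)
  pers <- detect_persistence(ser)
  expect_equal(pers$fraction, pers$fraction_exact, tolerance = 1e-9)
  st <- time_weighted_stats(run, "R")
  i0 <- max(which(run$times <= 50))
  later <- run$times > 50
  manual <- dwell_stats(c(50, run$times[later]),
                        c(ser$R[i0], ser$R[later]), t_end = 150)
  expect_equal(manual$mean, st$mean, tolerance = 1e-9)
  expect_equal(manual$fano, st$fano, tolerance = 1e-7)
})

test_that("architecture comparison is deterministic given its seed list", {
  c1 <- compare_architectures(p_nom, seeds = 1:3, t_end = 120, burn_in = 20)
  c2 <- compare_architectures(p_nom, seeds = 1:3, t_end = 120, burn_in = 20)
  expect_identical(c1$replicates, c2$replicates)
  expect_identical(c1$summary, c2$summary)
  expect_setequal(unique(c1$replicates$variant),
                  c("wild_type", "uncoupled", "no_feedback"))
  expect_error(compare_architectures(p_nom, seeds = 1:2), "at least 3")
  expect_error(test_orderings(c1), ">= 10 replicates")
})
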