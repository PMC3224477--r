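test_that("patient resampling is deterministic given a seed and preserves size", {
  co <- simulate_cohort(sim_scenario(n = 40), seed = 61)
  b1 <- resample_patients(co, seed = 7)
  b2 <- resample_patients(co, seed = 7)
  expect_identical(b1, b2)
  expect_equal(length(unique(b1$patient_id)), 40)
  b3 <- resample_patients(co, seed = 8)
  expect_false(identical(b1$time, b3$time))
})

test_that("patient resampling draws indices uniformly with replacement", {
  co <- build_histories(events(
    ev("a", 1, "achieve"), ev("a", 9, "censor"),
    ev("b", 2, "achieve"), ev("b", 8, "censor"),
    ev("c", 3, "achieve"), ev("c", 7, "censor")))
  set.seed(67)
  draws <- table(factor(unlist(lapply(1:600, function(i) {
    rs <- resample_patients(co)
    sub("\\.b[0-9]+$", "", rs$patient_id[rs$event == "achieve"])
  })), levels = c("a", "b", "c")))
  # 1800 draws over three equiprobable patients
  expect_gt(stats::chisq.test(draws)$p.value, 1e-4)
})

test_that("a cohort of identical patients yields zero-width bands at the point estimate", {
  rows <- lapply(1:25, function(k) {
    events(ev(sprintf("p%02d", k), 2, "achieve"),
           ev(sprintf("p%02d", k), 6, "lose"),
           ev(sprintf("p%02d", k), 10, "censor"))
  })
  co <- build_histories(dplyr::bind_rows(rows))
  cc <- cci(co, grid = c(1, 3, 7), B = 50, seed = 3)
  expect_equal(cc$lower, cc$estimate, tolerance = 1e-12)
  expect_equal(cc$upper, cc$estimate, tolerance = 1e-12)
})

test_that("nearest-rank percentile limits with B = 2 are the replicate min and max", {
  reps <- rbind(c(0.2, 0.5), c(0.4, 0.3))
  out <- currentsurv:::percentile_from_matrix(reps, level = 0.95)
  expect_equal(out$lower, c(0.2, 0.3))
  expect_equal(out$upper, c(0.4, 0.5))
  # invariance to replicate ordering
  out2 <- currentsurv:::percentile_from_matrix(reps[2:1, ], level = 0.95)
  expect_equal(out2, out)
})

test_that("bootstrap bands are reproducible and ordered", {
  co <- simulate_cohort(sim_scenario(n = 60), seed = 71)
  g <- c(6, 12, 24, 48)
  c1 <- cci(co, grid = g, B = 100, seed = 11)
  c2 <- cci(co, grid = g, B = 100, seed = 11)
  expect_identical(tidy(c1), tidy(c2))
  expect_true(all(c1$lower <= c1$upper))
  l1 <- clfs(co, grid = g, B = 100, seed = 11)
  expect_true(all(l1$lower <= l1$upper))
})

test_that("the generic percentile_band path matches the built-in fast path", {
  co <- simulate_cohort(sim_scenario(n = 50), seed = 73)
  g <- c(6, 12, 24)
  fast <- cci(co, grid = g, B = 60, seed = 5)
  slow <- percentile_band(co, function(h, grid) cci(h, grid = grid)$estimate,
                          grid = g, B = 60, seed = 5)
  expect_equal(slow$lower, fast$lower, tolerance = 1e-12)
  expect_equal(slow$upper, fast$upper, tolerance = 1e-12)
  expect_equal(slow$estimate, fast$estimate, tolerance = 1e-12)
})

test_that("replicates where the statistic fails are tolerated up to one percent", {
  reps <- matrix(rep(c(0.1, 0.2), each = 100), ncol = 2)
  reps[1:3, ] <- NA # 3% failed: too fragile
  expect_error(currentsurv:::percentile_from_matrix(reps, 0.95), "failed")
  reps2 <- matrix(rep(0.1, 300 * 2), ncol = 2)
  reps2[1, ] <- NA # 0.33% failed: tolerated
  out <- currentsurv:::percentile_from_matrix(reps2, 0.95)
  expect_equal(out$n_failed, 1)
})

test_that("Efron procedure I reduces to plain resampling without censoring", {
  tm <- c(1, 2, 5, 7)
  st <- c(1, 1, 1, 1)
  rs <- resample_efron1(tm, st, seed = 13)
  expect_true(all(rs$time %in% tm))
  expect_true(all(rs$status == 1))

  rs0 <- suppressMessages(resample_efron1(tm, c(0, 0, 0, 0), seed = 13))
  expect_true(all(rs0$status == 0))
})

test_that("Efron procedure I event indicators match the analytic minimum probability", {
  # event KM: atom at 2 (mass 1/2) plus defective mass beyond follow-up;
  # censoring KM: all mass at 5. So a resampled observation is either an
  # event at 2 or, when the event draw lies beyond follow-up, censored at 5
  tm <- c(2, 2, 5, 5)
  st <- c(1, 1, 0, 0)
  rs <- suppressMessages(resample_efron1(tm, st, seed = 17))
  expect_true(all((rs$time == 2 & rs$status == 1) |
                    (rs$time == 5 & rs$status == 0)))

  # mixed atoms: enumerate the exact indicator probability over the two
  # empirical (Kaplan-Meier) distributions, including defective mass
  # beyond follow-up which can never produce an event
  tm2 <- c(1, 4, 2, 6)
  st2 <- c(1, 1, 0, 0)
  set.seed(19)
  draws <- dplyr::bind_rows(lapply(1:400, function(i) {
    suppressMessages(resample_efron1(tm2, st2))
  }))
  # analytic: P(status = 1) = sum_x P(X = x) P(C >= x) with X,C independent
  ev_rc <- currentsurv:::risk_counts(tm2, st2)
  S <- cumprod(1 - ev_rc$c1 / ev_rc$n_risk)
  mass_x <- c(1, S[-length(S)]) - S
  atoms_x <- ev_rc$ut # defective event mass (S > 0 at the end) is never an event
  cn_rc <- currentsurv:::risk_counts(tm2, 1 - st2)
  Sc <- cumprod(1 - cn_rc$c1 / cn_rc$n_risk)
  mass_c <- c(1, Sc[-length(Sc)]) - Sc
  atoms_c <- cn_rc$ut
  if (Sc[length(Sc)] > 1e-12) { atoms_c <- c(atoms_c, Inf); mass_c <- c(mass_c, Sc[length(Sc)]) }
  p_event <- sum(vapply(seq_along(atoms_x), function(i) {
    mass_x[i] * sum(mass_c[atoms_c >= atoms_x[i]])
  }, 0))
  p_hat <- mean(draws$status)
  se <- sqrt(p_event * (1 - p_event) / nrow(draws))
  expect_lt(abs(p_hat - p_event), 4 * se + 1e-9)
})
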