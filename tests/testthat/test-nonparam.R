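test_that("risk table counts at-risk sets and tied censoring by the standard convention", {
  rt <- risk_table(c(1, 2, 3), c(1, 2, 0))
  expect_equal(rt$time, c(1, 2))
  expect_equal(rt$n_risk, c(3, 2))
  expect_equal(rt$n_interest, c(1, 0))
  expect_equal(rt$n_event, c(1, 1))

  expect_equal(nrow(risk_table(c(1, 2), c(0, 0))), 0)

  # censoring tied with an event stays in the risk set at that time
  rt2 <- risk_table(c(2, 2), c(1, 0))
  expect_equal(rt2$n_risk, 2)
  expect_equal(rt2$n_interest, 1)

  expect_error(risk_table(c(-1, 2), c(1, 1)), "non-negative")
  expect_error(risk_table(c(1, 2), c(1, 7)), "Cause")
})

test_that("Kaplan-Meier matches the hand-computed product limit", {
  km <- kaplan_meier(c(1, 2, 3, 4), c(1, 1, 0, 1), interest = 1)
  expect_equal(km$time, c(1, 2, 4))
  expect_equal(km$estimate, c(0.75, 0.5, 0), tolerance = 1e-12)
  expect_equal(step_value(km, c(0.5, 1, 3, 10)), c(1, 0.75, 0.5, 0))

  # no events: flat at one
  km0 <- kaplan_meier(c(1, 2), c(0, 0))
  expect_equal(step_value(km0, c(0, 5)), c(1, 1))

  # uncensored data: empirical survivor function
  set.seed(9)
  t_obs <- round(rweibull(40, 1.3, 10), 6)
  km_u <- kaplan_meier(t_obs, rep(1, 40), interest = 1)
  grid <- c(0.5, 2, 5, 9, 20)
  expect_equal(step_value(km_u, grid), oracle_survivor(t_obs, grid),
               tolerance = 1e-12)
})

test_that("Kaplan-Meier agrees with survival::survfit on censored data", {
  skip_if_not_installed("survival")
  set.seed(11)
  t_obs <- rweibull(60, 1.2, 8)
  status <- rbinom(60, 1, 0.7)
  km <- kaplan_meier(t_obs, status, interest = 1)
  fit <- survival::survfit(survival::Surv(t_obs, status) ~ 1)
  sm <- summary(fit, times = km$time)
  expect_equal(step_value(km, sm$time), sm$surv, tolerance = 1e-10)
})

test_that("Nelson-Aalen increments are cause counts over risk sets", {
  rt <- risk_table(c(1, 2, 3), c(1, 2, 0))
  inc <- na_increments(rt)
  expect_equal(inc$increment, c(1 / 3, 0), tolerance = 1e-12)

  inc1 <- na_increments(risk_table(3, 1))
  expect_equal(inc1$increment, 1)

  # whole risk set fails at the first time
  inc2 <- na_increments(risk_table(c(1, 1), c(1, 1)))
  expect_equal(inc2$increment, 1)
})

test_that("cumulative incidence matches hand computation and the complement identity", {
  ci1 <- cumulative_incidence(c(1, 2, 3), c(1, 2, 0), interest = 1)
  expect_equal(step_value(ci1, c(1, 2.5, 10)), c(1 / 3, 1 / 3, 1 / 3),
               tolerance = 1e-12)
  ci2 <- cumulative_incidence(c(1, 2, 3), c(1, 2, 0), interest = 2)
  expect_equal(step_value(ci2, 2), (1 / 2) * (2 / 3), tolerance = 1e-12)

  # single cause, censored: CIF = 1 - KM exactly
  set.seed(13)
  t_obs <- rweibull(50, 1, 6)
  status <- rbinom(50, 1, 0.6)
  ci <- cumulative_incidence(t_obs, status, interest = 1)
  km <- kaplan_meier(t_obs, status, interest = 1)
  grid <- sort(unique(t_obs))
  expect_equal(step_value(ci, grid), 1 - step_value(km, grid),
               tolerance = 1e-12)
})

test_that("cause-specific incidences add up to one minus all-cause survival", {
  set.seed(17)
  t_obs <- rweibull(80, 1.4, 9)
  cause <- sample(0:2, 80, replace = TRUE, prob = c(0.3, 0.4, 0.3))
  i1 <- cumulative_incidence(t_obs, cause, interest = 1)
  i2 <- cumulative_incidence(t_obs, cause, interest = 2)
  km <- kaplan_meier(t_obs, cause, interest = c(1, 2))
  grid <- sort(unique(t_obs))
  expect_equal(step_value(i1, grid) + step_value(i2, grid),
               1 - step_value(km, grid), tolerance = 1e-12)
})

test_that("competing-risks incidence agrees with survival::survfit pstate", {
  skip_if_not_installed("survival")
  set.seed(19)
  t_obs <- rweibull(70, 1.2, 10)
  cause <- sample(0:2, 70, replace = TRUE)
  f <- factor(cause, levels = 0:2, labels = c("censor", "ev1", "ev2"))
  fit <- survival::survfit(survival::Surv(t_obs, f) ~ 1)
  ci1 <- cumulative_incidence(t_obs, cause, interest = 1)
  tms <- sort(unique(t_obs[cause != 0]))
  sm <- summary(fit, times = tms)
  col <- which(fit$states == "ev1")
  expect_equal(step_value(ci1, tms), unname(sm$pstate[, col]),
               tolerance = 1e-10)
})

test_that("uncensored KM and CIF equal brute-force patient counting", {
  set.seed(23)
  t_obs <- rweibull(50, 1.5, 12)
  cause <- sample(1:2, 50, replace = TRUE)
  grid <- c(2, 5, 8, 15, 30)
  km <- kaplan_meier(t_obs, cause, interest = c(1, 2))
  expect_equal(step_value(km, grid), oracle_survivor(t_obs, grid),
               tolerance = 1e-12)
  i1 <- cumulative_incidence(t_obs, cause, interest = 1)
  brute <- vapply(grid, function(u) mean(t_obs <= u & cause == 1), 0)
  expect_equal(step_value(i1, grid), brute, tolerance = 1e-12)
})

test_that("step curves are right-continuous with last-value extrapolation", {
  sc <- step_curve(c(1, 3), c(0.4, 0.1), origin = 1)
  expect_equal(step_value(sc, c(0, 1 - 1e-9, 1, 2.999, 3, 100)),
               c(1, 1, 0.4, 0.4, 0.1, 0.1))
  expect_error(step_curve(c(2, 1), c(0.5, 0.2), origin = 1), "increasing")
})
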