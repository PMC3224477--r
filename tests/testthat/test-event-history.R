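test_that("read_long_events parses rows, applies alias maps, and reports format errors", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,time,event",
               "p1,1.0,achieve", "p1,3.0,lose", "p1,6.0,censor"), f)
  rec <- read_long_events(f)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$time, c(1, 3, 6))
  expect_equal(rec$event, c("achieve", "lose", "censor"))

  f2 <- tempfile(fileext = ".csv")
  writeLines(c("id,months,status", "p1,2,remission", "p1,8,end"), f2)
  rec2 <- read_long_events(
    f2,
    cols = c(patient_id = "id", time = "months", event = "status"),
    event_map = c(remission = "achieve", end = "censor"))
  expect_equal(rec2$event, c("achieve", "censor"))

  f3 <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,event", "p1,achieve"), f3)
  expect_error(read_long_events(f3), "time")

  f4 <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,time,event", "p1,abc,achieve"), f4)
  expect_error(read_long_events(f4), "row")

  f5 <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,time,event", "p1,1,flare"), f5)
  expect_error(read_long_events(f5), "flare")
  unlink(c(f, f2, f3, f4, f5))
})

test_that("build_histories accepts valid cohorts and enforces every invariant", {
  h <- build_histories(events(
    ev("p1", 1, "achieve"), ev("p1", 3, "lose"),
    ev("p1", 5, "achieve"), ev("p1", 8, "censor"),
    ev("p2", 2, "achieve"), ev("p2", 4, "death")))
  expect_s3_class(h, "event_history")
  expect_equal(max_remission_count(h), 2)

  # two achievements in a row
  expect_error(build_histories(events(
    ev("p3", 1, "achieve"), ev("p3", 2, "achieve"), ev("p3", 3, "censor"))),
    "p3")
  # tied within-patient times
  expect_error(build_histories(events(
    ev("p4", 1, "achieve"), ev("p4", 1, "lose"), ev("p4", 3, "censor"))),
    "tied")
  # missing terminal
  expect_error(build_histories(events(ev("p5", 1, "achieve"))), "terminal")
  # two terminals
  expect_error(build_histories(events(
    ev("p6", 1, "censor"), ev("p6", 2, "death"))), "terminal")
  # event after terminal
  expect_error(build_histories(events(
    ev("p7", 1, "achieve"), ev("p7", 2, "death"), ev("p7", 3, "lose"))),
    "after")
  # starting with a loss on the origin clock
  expect_error(build_histories(events(
    ev("p8", 1, "lose"), ev("p8", 2, "censor"))), "achieve")
})

test_that("max_remission_count covers empty-remission and deep cohorts", {
  expect_equal(max_remission_count(build_histories(events(ev("q", 5, "censor")))), 0)
  h1 <- build_histories(events(ev("a", 1, "achieve"), ev("a", 2, "censor"),
                               ev("b", 3, "achieve"), ev("b", 4, "censor")))
  expect_equal(max_remission_count(h1), 1)
  h3 <- build_histories(events(
    ev("d", 1, "achieve"), ev("d", 2, "lose"), ev("d", 3, "achieve"),
    ev("d", 4, "lose"), ev("d", 5, "achieve"), ev("d", 6, "censor")))
  expect_equal(max_remission_count(h3), 3)
})

test_that("achievement vectors code censoring, achievement, and prior death", {
  h <- build_histories(events(
    ev("p", 1, "achieve"), ev("p", 3, "lose"), ev("p", 8, "censor")))
  av <- achievement_vectors(h, r = 2)
  expect_equal(av$time, c(1, 8))
  expect_equal(av$cause, c(1L, 0L))

  hd <- build_histories(events(ev("q", 4, "death")))
  avd <- achievement_vectors(hd, r = 2)
  expect_equal(avd$time, c(4, 4))
  expect_equal(avd$cause, c(2L, 2L))

  h3 <- build_histories(events(
    ev("s", 1, "achieve"), ev("s", 3, "lose"), ev("s", 5, "achieve"),
    ev("s", 7, "death")))
  av3 <- achievement_vectors(h3, r = 3)
  expect_equal(av3$time, c(1, 5, 7))
  expect_equal(av3$cause, c(1L, 1L, 2L))
})

test_that("loss vectors mark deaths in the i-th remission but not earlier deaths", {
  h <- build_histories(events(
    ev("p", 1, "achieve"), ev("p", 3, "lose"), ev("p", 8, "censor")))
  lv <- loss_vectors(h, r = 2)
  expect_equal(lv$time, c(3, 8))
  expect_equal(lv$cause, c(1L, 0L))
  expect_equal(lv$death_in_remission, c(FALSE, FALSE))

  h2 <- build_histories(events(ev("q", 2, "achieve"), ev("q", 4, "death")))
  lv2 <- loss_vectors(h2, r = 1)
  expect_equal(lv2$cause, 2L)
  expect_true(lv2$death_in_remission)

  h3 <- build_histories(events(ev("w", 4, "death")))
  lv3 <- loss_vectors(h3, r = 1)
  expect_equal(lv3$cause, 2L)
  expect_false(lv3$death_in_remission)
})

test_that("clock reset shifts times, drops the first achievement, and filters non-achievers", {
  h <- build_histories(events(
    ev("p", 2, "achieve"), ev("p", 5, "lose"), ev("p", 9, "censor"),
    ev("q", 4, "death")))
  rs <- reset_first_remission(h)
  expect_equal(unique(rs$patient_id), "p")
  expect_equal(rs$time, c(3, 7))
  expect_equal(rs$event, c("lose", "censor"))
  expect_identical(attr(rs, "clock"), "first_remission")

  no_rem <- build_histories(events(ev("x", 4, "death")))
  expect_error(reset_first_remission(no_rem), "undefined")
})

test_that("reset preserves event counts minus one achievement per retained patient", {
  set.seed(71)
  co <- simulate_cohort(sim_scenario(n = 60), seed = 71)
  achievers <- unique(co$patient_id[co$event == "achieve"])
  rs <- reset_first_remission(co)
  expect_setequal(unique(rs$patient_id), achievers)
  n_before <- nrow(co[co$patient_id %in% achievers, ])
  expect_equal(nrow(rs), n_before - length(achievers))
})

test_that("achievement and loss vectors interleave over simulated cohorts", {
  co <- simulate_cohort(sim_scenario(n = 80), seed = 5)
  r <- max_remission_count(co)
  av <- achievement_vectors(co)
  lv <- loss_vectors(co)
  for (i in seq_len(r)) {
    a <- av[av$i == i, ]
    l <- lv[lv$i == i, ]
    both <- a$cause == 1 & l$cause == 1
    expect_true(all(a$time[both] < l$time[both]))
    if (i < r) {
      nxt <- av[av$i == i + 1, ]
      deeper <- both & nxt$cause == 1
      expect_true(all(l$time[deeper] < nxt$time[deeper]))
    }
  }
  # no later achievement without an earlier one
  for (i in seq_len(r - 1)) {
    expect_true(all(av$cause[av$i == i] == 1 | av$cause[av$i == i + 1] != 1))
  }
})

test_that("validation is idempotent on an already valid cohort", {
  h <- toy_cohort()
  h2 <- as_event_history(as.data.frame(h))
  expect_equal(tibble::as_tibble(h2), tibble::as_tibble(h))
})
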