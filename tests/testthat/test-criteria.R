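test_that("the five predicates match their definitions on boundary cases", {
  zero <- integer(24L)
  # gt0: any data whatsoever
  expect_false(valid_gt0(zero))
  expect_true(valid_gt0(make_hourly(c(23, 1))))
  expect_true(valid_gt0(make_hourly(c(5, 10000))))
  # gt500: strictly more than 500
  expect_false(valid_gt500(make_hourly(c(10, 500))))
  expect_true(valid_gt500(make_hourly(c(10, 501))))
  expect_false(valid_gt500(zero))
  # ge10_hours: ten distinct active clock hours, regardless of magnitude
  expect_true(valid_ge10_hours(rep(c(1L, 0L), c(10L, 14L))))
  nine_heavy <- integer(24L); nine_heavy[1:9] <- c(rep(1000L, 8L), 2000L)
  expect_false(valid_ge10_hours(nine_heavy))
  eleven <- integer(24L); eleven[8:18] <- 1L  # hours 7-17
  expect_true(valid_ge10_hours(eleven))
  # three_a_day: one step in each anchored window
  expect_true(valid_three_a_day(make_hourly(c(4, 1), c(12, 1), c(20, 1))))
  morning_only <- integer(24L); morning_only[4:11] <- 5L  # hours 3-10
  expect_false(valid_three_a_day(morning_only))
  # three_of_four: three of the four six-hour windows active
  expect_true(valid_three_of_four(make_hourly(c(7, 1), c(13, 1), c(19, 1))))
  expect_false(valid_three_of_four(make_hourly(c(1, 9), c(7, 9))))
  expect_true(valid_three_of_four(make_hourly(c(1, 1), c(7, 1), c(13, 1), c(19, 1))))
})

test_that("the 3 pm-3 am window wraps into the next day unless truncated", {
  day <- make_hourly(c(4, 1), c(12, 1))       # evening empty on the day
  nxt <- c(0L, 3L, 0L)                        # a step at 01:xx next day
  expect_true(valid_three_a_day(day, next_day_early = nxt, wrap = TRUE))
  expect_false(valid_three_a_day(day, next_day_early = nxt, wrap = FALSE))
  expect_false(valid_three_a_day(day, next_day_early = NULL))  # final day
  # hour 2 of the next day still counts, hour 3 would not (not passed in)
  expect_true(valid_three_a_day(day, next_day_early = c(0L, 0L, 1L)))
})

test_that("evaluate_matrix fills every patient-day-criterion cell", {
  zero57 <- matrix(0L, 57L, 24L)
  cohort <- cohort_from_hourly(list(zero57), small_meta())
  m <- evaluate_matrix(cohort)
  expect_equal(nrow(m), 57L * 5L)
  expect_false(any(m$valid))

  # 600 steps over 12 hours covering all windows -> valid everywhere
  spread <- matrix(0L, 57L, 24L)
  spread[16, c(1, 4, 6, 8, 9, 12, 13, 14, 16, 17, 19, 21) + 1] <- 50L
  c2 <- cohort_from_hourly(list(spread), small_meta())
  m2 <- evaluate_matrix(c2)
  d1 <- m2[m2$day_index == 1L, ]
  expect_true(all(d1$valid))

  # 3 steps at hours 4, 12, 20
  sparse <- matrix(0L, 57L, 24L)
  sparse[16, c(4, 12, 20) + 1] <- 1L
  m3 <- evaluate_matrix(cohort_from_hourly(list(sparse), small_meta()))
  d1 <- m3[m3$day_index == 1L, ]
  got <- setNames(d1$valid, d1$criterion)
  expect_true(all(got[c("gt0_steps", "three_a_day", "three_of_four")]))
  expect_false(any(got[c("gt500_steps", "ge10_hours")]))

  expect_warning(m0 <- evaluate_matrix(structure(list(timelines = list(),
                                                      meta = small_meta()[0, ]),
                                                 class = "pw_cohort")),
                 "empty cohort")
  expect_equal(nrow(m0), 0L)
})

test_that("evaluate_matrix wraps 3-a-day across consecutive days", {
  h <- matrix(0L, 57L, 24L)
  h[16, c(4, 12) + 1] <- 1L   # day 1: morning + midday only
  h[17, 2] <- 1L              # day 2, hour 1
  cohort <- cohort_from_hourly(list(h), small_meta())
  mw <- evaluate_matrix(cohort, "three_a_day", three_a_day_wrap = TRUE)
  mt <- evaluate_matrix(cohort, "three_a_day", three_a_day_wrap = FALSE)
  expect_true(mw$valid[mw$day_index == 1L])
  expect_false(mt$valid[mt$day_index == 1L])
  # the final day always truncates: no day 43 exists to borrow from
  h2 <- matrix(0L, 57L, 24L)
  h2[57, c(4, 12) + 1] <- 1L
  m42 <- evaluate_matrix(cohort_from_hourly(list(h2), small_meta()), "three_a_day")
  expect_false(m42$valid[m42$day_index == 42L])
})

test_that("dominance, implied minima and monotonicity hold on random days", {
  set.seed(101)
  preds <- list(gt500 = valid_gt500, ge10 = valid_ge10_hours,
                three4 = valid_three_of_four)
  for (i in 1:400) {
    h <- minutes_to_hourly(random_minutes())
    others <- c(vapply(preds, function(f) f(h), logical(1)),
                aday = valid_three_a_day(h))
    if (any(others)) expect_true(valid_gt0(h))
    if (valid_ge10_hours(h)) expect_gte(sum(h), 10)
    if (valid_three_of_four(h)) expect_gte(sum(h), 3)
    if (valid_three_a_day(h, next_day_early = NULL)) expect_gte(sum(h), 3)
    if (valid_three_a_day(h, next_day_early = c(5L, 0L, 0L))) expect_gte(sum(h), 2)
    # adding steps anywhere never invalidates any criterion
    h2 <- h
    j <- sample.int(24L, 1L)
    h2[j] <- h2[j] + sample.int(600L, 1L)
    for (f in preds) if (f(h)) expect_true(f(h2))
    if (valid_gt0(h)) expect_true(valid_gt0(h2))
  }
})

test_that("hour-vector predicates agree with the minute-level oracle", {
  set.seed(202)
  for (i in 1:1500) {
    mins <- random_minutes()
    nxt <- random_minutes()
    h <- minutes_to_hourly(mins)
    nxt_h <- minutes_to_hourly(nxt)[1:3]
    expect_identical(valid_gt0(h), o_gt0(mins))
    expect_identical(valid_gt500(h), o_gt500(mins))
    expect_identical(valid_ge10_hours(h), o_ge10_hours(mins))
    expect_identical(valid_three_of_four(h), o_three_of_four(mins))
    expect_identical(valid_three_a_day(h, nxt_h, wrap = TRUE),
                     o_three_a_day(mins, nxt, wrap = TRUE))
    expect_identical(valid_three_a_day(h, NULL),
                     o_three_a_day(mins, NULL))
  }
})

test_that("the registry accepts user criteria but protects the built-ins", {
  expect_error(register_criterion("gt0_steps", function(h, ...) TRUE),
               "built-in")
  register_criterion("ge4_hours",
                     function(hourly, ...) sum(hourly >= 1) >= 4L)
  expect_true("ge4_hours" %in% list_criteria())
  h <- matrix(0L, 57L, 24L)
  h[16, c(2, 8, 14, 20) + 1] <- 1L
  m <- evaluate_matrix(cohort_from_hourly(list(h), small_meta()),
                       c("gt0_steps", "ge4_hours"))
  expect_equal(nrow(m), 114L)
  expect_true(m$valid[m$day_index == 1L & m$criterion == "ge4_hours"])
  expect_error(evaluate_matrix(cohort_from_hourly(list(h), small_meta()),
                               "no_such"), "unknown criterion")
})
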