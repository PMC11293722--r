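test_that("RCT protocol yields one segment per target meal: 4 x 6 days = 24", {
  cohort <- simulate_cohort(standard_rct_spec(), seed = 1)
  segs <- segment_sessions(cohort)
  expect_equal(segs$n_segments, 24L)
  expect_equal(segs$n_persons, 4L)
  expect_equal(segs$n_dropped, 0L)
})

test_that("sessions without meals yield zero segments, empty cohort errors", {
  cohort <- simulate_cohort(cohort_spec("patient", n_persons = 2,
                                        exercise_fraction = 0), seed = 3)
  cohort$meals <- cohort$meals[0, ]
  expect_equal(segment_sessions(cohort)$n_segments, 0L)
  cohort$glucose <- cohort$glucose[0, ]
  expect_error(segment_sessions(cohort), "no glucose")
})

test_that("a single missing grid sample in the window excludes the segment", {
  cohort <- simulate_cohort(standard_rct_spec(), seed = 5)
  tau <- cohort$meals$time_min[1]
  pid <- cohort$meals$person_id[1]
  drop_at <- function(co, tt) {
    keep <- !(co$glucose$person_id == pid & co$glucose$time_min == tt)
    co$glucose <- co$glucose[keep, ]
    co
  }
  # missing postprandial sample at tau + 45
  segs <- segment_sessions(drop_at(cohort, tau + 45))
  expect_equal(segs$n_segments, 23L)
  expect_equal(segs$n_dropped, 1L)
  # missing preprandial sample also excludes
  segs2 <- segment_sessions(drop_at(cohort, tau - 10))
  expect_equal(segs2$n_segments, 23L)
})

test_that("retained segments have <= 4 pre and exactly 18 post grid samples", {
  segs <- segment_sessions(simulate_cohort(evaluation_patient_spec(),
                                           seed = 7))
  npre <- vapply(segs$segments, function(s) length(s$pre_values), integer(1))
  npost <- vapply(segs$segments, function(s) length(s$post_values), integer(1))
  expect_true(all(npre >= 1 & npre <= 4))
  expect_true(all(npost == 18L))
  gaps <- vapply(segs$segments, function(s) all(diff(s$post_times) == 5),
                 logical(1))
  expect_true(all(gaps))
})

test_that("segmentation is deterministic given the same cohort", {
  cohort <- simulate_cohort(cohort_spec("patient", n_persons = 3), seed = 9)
  expect_identical(segment_sessions(cohort), segment_sessions(cohort))
})

test_that("overlapping meals are each retained with successive meals listed", {
  co <- simulate_cohort(cohort_spec("patient", n_persons = 1,
                                    exercise_fraction = 0), seed = 13)
  tau <- co$meals$time_min[1]
  extra <- data.frame(person_id = co$meals$person_id[1],
                      session_id = co$meals$session_id[1],
                      time_min = tau + 60, carbs_g = 30)
  co$meals <- rbind(co$meals, extra)
  segs <- segment_sessions(co)
  anchored <- Filter(function(s) s$meal_time %in% c(tau, tau + 60),
                     segs$segments)
  expect_length(anchored, 2L)
  first <- Filter(function(s) s$meal_time == tau, anchored)[[1]]
  expect_equal(nrow(first$meals), 2L)
  expect_equal(first$meals$time[1], tau) # anchor meal is earliest
})

test_that("train/test split follows the 2+1 day rule per session", {
  co <- simulate_cohort(cohort_spec("patient", n_persons = 2,
                                    meals_per_day = 2), seed = 21)
  segs <- split_train_test(segment_sessions(co), 3)
  roles <- vapply(segs$segments, `[[`, "", "role")
  days <- vapply(segs$segments, `[[`, 1, "day")
  expect_true(all(roles[days <= 2] == "train"))
  expect_true(all(roles[days == 3] == "test"))
  # 2 meals/day x 3 days: 4 train, 2 test per person-session
  expect_equal(sum(roles == "train"), 8L)
  expect_equal(sum(roles == "test"), 4L)
  expect_equal(sum(roles == "train") + sum(roles == "test"), segs$n_segments)
})

test_that("6-day RCT sessions are entirely training data", {
  segs <- tiny_rct_segments(seed = 2)
  expect_true(all(vapply(segs$segments, `[[`, "", "role") == "train"))
})

test_that("day index outside the session length errors", {
  segs <- segment_sessions(simulate_cohort(cohort_spec("patient",
                                                       n_persons = 1),
                                           seed = 2))
  expect_error(split_train_test(segs, 2), "outside session length")
})

test_that("exercise segments need strictly more than 60 postprandial kcal", {
  seg <- make_segment(exercises = data.frame(time = 1030, ee = 80))
  expect_true(is_exercise_segment(seg))
  seg$exercises$ee <- 60
  expect_false(is_exercise_segment(seg))
  # preprandial bout does not count
  seg <- make_segment(exercises = data.frame(time = 990, ee = 100))
  expect_false(is_exercise_segment(seg))
  # several small postprandial bouts accumulate
  seg <- make_segment(exercises = data.frame(time = c(1020, 1050),
                                             ee = c(35, 35)))
  expect_true(is_exercise_segment(seg))
})

test_that("segments round-trip through JSON lines", {
  segs <- split_train_test(segment_sessions(
    simulate_cohort(cohort_spec("patient", n_persons = 2,
                                exercise_fraction = 0.5), seed = 31)), 3)
  path <- tempfile(fileext = ".jsonl")
  write_segments_jsonl(segs, path)
  back <- read_segments_jsonl(path, group = "patient")
  expect_equal(back$n_segments, segs$n_segments)
  for (i in seq_along(segs$segments)) {
    a <- segs$segments[[i]]; b <- back$segments[[i]]
    expect_equal(b$post_values, a$post_values)
    expect_equal(b$meals$carbs, a$meals$carbs)
    expect_equal(b$exercises$ee, a$exercises$ee)
    expect_identical(b$role, a$role)
  }
})
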