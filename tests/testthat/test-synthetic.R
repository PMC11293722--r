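test_that("identical seeds give identical cohorts and byte-identical CSVs", {
  spec <- cohort_spec("patient", n_persons = 3)
  a <- simulate_cohort(spec, seed = 77)
  b <- simulate_cohort(spec, seed = 77)
  expect_identical(a$glucose, b$glucose)
  expect_identical(a$meals, b$meals)
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(a, d1); write_cohort(b, d2)
  for (f in c("glucose.csv", "meals.csv", "exercise.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  expect_false(identical(simulate_cohort(spec, seed = 78)$glucose, a$glucose))
})

test_that("degenerate spread puts every person at the group means", {
  spec <- cohort_spec("healthy", theta_sd = list(alpha_d = 0, beta_d = 0,
                                                 alpha_e = 0, beta_e = 0,
                                                 c_syn = 0))
  set.seed(1)
  pp <- draw_person_params(spec)
  expect_true(all(pp$alpha_d == spec$theta$alpha_d))
  expect_true(all(pp$beta_e == spec$theta$beta_e))
})

test_that("patient exercise strength defaults to half the healthy mean", {
  expect_equal(cohort_spec("patient")$theta$beta_e,
               0.5 * cohort_spec("healthy")$theta$beta_e)
})

test_that("RCT protocol: conditions, walk timing and condition-mapped EE", {
  co <- simulate_cohort(standard_rct_spec(), seed = 4)
  segs <- segment_sessions(co)
  days <- vapply(segs$segments, `[[`, 1, "day")
  ex <- vapply(segs$segments, is_exercise_segment, logical(1))
  # moderate/high days (2,5,3,6) are exercise segments; low days (1,4) are not
  expect_identical(ex, days %in% c(2, 3, 5, 6))
  for (s in segs$segments[ex]) {
    expect_equal(s$exercises$time, s$meal_time + 30)
    expect_true(s$exercises$ee %in% c(80, 130))
    expect_equal(s$exercises$ee, if (s$day %in% c(2, 5)) 80 else 130)
  }
  # near-constant carbohydrate within person
  carbs <- vapply(segs$segments, function(s) s$meals$carbs[1], numeric(1))
  pid <- vapply(segs$segments, `[[`, "", "person_id")
  expect_true(all(tapply(carbs, pid, function(x) diff(range(x))) < 15))
})

test_that("free-living imbalance: rare exercise, monotone in the fraction", {
  spec <- cohort_spec("patient", n_persons = 68, meals_per_day = 2)
  segs <- segment_sessions(simulate_cohort(spec, seed = 6))
  expect_equal(segs$n_segments, 68L * 6L)
  frac <- mean(vapply(segs$segments, is_exercise_segment, logical(1)))
  expect_lte(frac, 0.10)
  fracs <- vapply(c(0, 0.3, 0.9), function(f) {
    sp <- cohort_spec("patient", n_persons = 10, exercise_fraction = f)
    ss <- segment_sessions(simulate_cohort(sp, seed = 8))
    mean(vapply(ss$segments, is_exercise_segment, logical(1)))
  }, numeric(1))
  expect_equal(fracs[1], 0)
  expect_true(fracs[1] <= fracs[2] && fracs[2] <= fracs[3])
})

test_that("noise-free simulation matches the forward model for all kinds", {
  for (kind in c("single", "additive", "synergistic")) {
    spec <- cohort_spec("healthy", sigma = 0)
    co <- simulate_cohort(spec, seed = 15, model_kind = kind)
    segs <- segment_sessions(co)
    pp <- co$truth$persons
    for (s in segs$segments) {
      r <- pp[pp$person_id == s$person_id, ]
      par <- person_params(r$alpha_d, r$beta_d, r$alpha_e, r$beta_e, r$c_syn,
                           sigma = 0.1)
      tr <- glucose_trajectory(par, s, kind)
      # stored glucose is rounded to 4 decimals; equality up to that rounding
      expect_lt(max(abs(s$post_values - tr$y_hat)), 2e-4)
    }
  }
})

test_that("simulated noise has the specified standard deviation", {
  pp <- list(alpha_d = 12, beta_d = 0.04, alpha_e = 10, beta_e = -0.015,
             c_syn = 0.2, sigma = 0.3)
  meals <- data.frame(time_min = seq(720, by = 1440, length.out = 60),
                      carbs_g = 60)
  ex <- data.frame(time_min = numeric(0), ee_kcal = numeric(0))
  # identical seeds align the baseline draws, so the difference between the
  # noisy and the noise-free trace is exactly the observation noise
  set.seed(23)
  g0 <- simulate_glucose(pp, meals, ex, n_days = 60, sigma = 0)
  set.seed(23)
  g1 <- simulate_glucose(pp, meals, ex, n_days = 60, sigma = 0.3)
  res <- g1$glucose_mmol_l - g0$glucose_mmol_l
  expect_equal(sd(res), 0.3, tolerance = 0.01 / 0.3)
})

test_that("flat trace at baseline when there are no events and no noise", {
  pp <- list(alpha_d = 12, beta_d = 0.04, alpha_e = 10, beta_e = -0.015,
             c_syn = 0.2, sigma = 0)
  g <- simulate_glucose(pp, meals = data.frame(time_min = numeric(0),
                                               carbs_g = numeric(0)),
                        exercises = data.frame(time_min = numeric(0),
                                               ee_kcal = numeric(0)),
                        n_days = 1, sigma = 0)
  expect_equal(length(unique(g$glucose_mmol_l)), 1L)
})

test_that("child seeds are deterministic and leave the global RNG untouched", {
  set.seed(123); before <- .Random.seed
  s1 <- child_seeds(9, 5)
  expect_identical(.Random.seed, before)
  expect_identical(s1, child_seeds(9, 5))
  expect_true(all(s1 > 0 & s1 < 2^31))
})
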