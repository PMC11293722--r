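test_that("baseline is the median of the preprandial window", {
  expect_equal(baseline_glucose(make_segment(pre_values = c(5.0, 5.2, 5.4, 6.0))),
               5.3)
  expect_equal(baseline_glucose(make_segment(pre_values = 4.8)), 4.8)
  expect_equal(baseline_glucose(make_segment(pre_values = rep(6.1, 3))), 6.1)
  seg <- make_segment(); seg$pre_values <- numeric(0)
  expect_error(baseline_glucose(seg), "empty preprandial")
})

test_that("bell response peaks at height h a lag 3*alpha after the event", {
  expect_equal(bell_response(10, 5, 0, 30), 5)
  expect_equal(bell_response(10, 5, 0, 20), 5 * exp(-0.5))
  # causality: zero before the event
  expect_equal(bell_response(10, 5, 100, c(0, 50, 99)), c(0, 0, 0))
  # empty event list gives a zero series
  expect_equal(bell_response(10, numeric(0), numeric(0), 0:10), rep(0, 11))
  expect_error(bell_response(0, 5, 0, 1), "alpha")
  expect_error(bell_response(10, c(1, 2), 0, 1), "length")
})

test_that("dietary and exercise responses scale bells by dose", {
  p <- person_params(alpha_d = 10, beta_d = 0.1, alpha_e = 8, beta_e = -0.02)
  seg <- make_segment(meal_time = 0,
                      meals = data.frame(time = c(0, 60), carbs = c(30, 40)),
                      exercises = data.frame(time = 0, ee = 100))
  seg$post_times <- seq(5, 90, by = 5)
  # two-term oracle sum at t = 70
  expect_equal(dietary_response(p, seg, 70),
               3 * exp(-8) + 4 * exp(-2), tolerance = 1e-12)
  # peak of a single meal: beta_d * carbs at tau + 3 alpha_d
  seg1 <- make_segment(meal_time = 0, meals = data.frame(time = 0, carbs = 50))
  expect_equal(dietary_response(p, seg1, 30), 5)
  expect_equal(exercise_response(p, seg, 16), -2 * exp(-0.5), tolerance = 1e-12)
  # zero doses give zero series
  seg0 <- make_segment(meals = data.frame(time = 1000, carbs = 0))
  expect_true(all(dietary_response(p, seg0) == 0))
  expect_true(all(exercise_response(p, make_segment()) == 0))
})

test_that("trajectory components add up exactly and match hand arithmetic", {
  p <- person_params(alpha_d = 10, beta_d = 0.1, alpha_e = 8, beta_e = -0.02,
                     c_syn = 0.3)
  # engineered so R_d = 2, R_e = -1 at the evaluated point
  seg <- make_segment(meal_time = 0,
                      pre_values = c(5.0, 5.2, 5.4, 6.0),
                      meals = data.frame(time = 0, carbs = 20),
                      exercises = data.frame(time = 6, ee = 50))
  tr <- glucose_trajectory(p, seg, "synergistic", grid = 30)
  expect_equal(tr$r_diet, 2)
  expect_equal(tr$r_exercise, -1)
  expect_equal(tr$y_hat, 5.3 + 2 - 1 + 0.3 * (2 * -1))
  expect_equal(tr$y_hat, tr$y_base + tr$r_diet + tr$r_exercise + tr$synergy)
})

test_that("model nesting holds exactly over random segments", {
  set.seed(404)
  for (i in 1:50) {
    p <- random_params()
    seg <- random_segment()
    syn0 <- p; syn0$c_syn <- 0
    expect_identical(glucose_trajectory(syn0, seg, "synergistic")$y_hat,
                     glucose_trajectory(p, seg, "additive")$y_hat)
    seg_noex <- seg
    seg_noex$exercises <- data.frame(time = numeric(0), ee = numeric(0))
    expect_identical(glucose_trajectory(p, seg_noex, "additive")$y_hat,
                     glucose_trajectory(p, seg_noex, "single")$y_hat)
  }
})

test_that("responses are linear in dose and superpose across events", {
  set.seed(99)
  for (i in 1:25) {
    p <- random_params()
    seg <- random_segment(n_meals = 2, n_ex = 2)
    grid <- seg$post_times
    doubled <- seg
    doubled$meals$carbs <- 2 * doubled$meals$carbs
    expect_equal(dietary_response(p, doubled, grid),
                 2 * dietary_response(p, seg, grid), tolerance = 1e-12)
    # superposition: sum of single-event responses
    one <- seg; one$meals <- seg$meals[1, ]
    two <- seg; two$meals <- seg$meals[2, ]
    expect_equal(dietary_response(p, one, grid) + dietary_response(p, two, grid),
                 dietary_response(p, seg, grid), tolerance = 1e-12)
  }
})

test_that("each bell term attains its amplitude at the stated lag", {
  set.seed(17)
  for (i in 1:20) {
    alpha <- runif(1, 2, 30); h <- runif(1, 0.5, 6); tau <- runif(1, 0, 500)
    dense <- sort(c(seq(tau, tau + 6 * 3 * alpha, by = 0.1), tau + 3 * alpha))
    r <- bell_response(alpha, h, tau, dense)
    expect_lt(abs(dense[which.max(r)] - (tau + 3 * alpha)), 0.1 + 1e-9)
    expect_lt(abs(max(r) - h) / h, 1e-9)
  }
})

test_that("trajectory JSON serialization carries the decomposition", {
  p <- person_params(alpha_d = 12, beta_d = 0.05, alpha_e = 10,
                     beta_e = -0.01, c_syn = 0.1)
  tr <- glucose_trajectory(p, make_segment(), "synergistic")
  obj <- jsonlite::fromJSON(trajectory_to_json(tr))
  expect_equal(obj$y_hat, tr$y_hat, tolerance = 1e-12)
  expect_equal(obj$components$y_base, tr$y_base)
})
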