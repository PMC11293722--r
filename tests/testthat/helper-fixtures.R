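# Shared test fixtures, all built in code.

# A hand-made segment on the 5-minute grid with controllable events.
make_segment <- function(meal_time = 1000,
                         pre_values = c(5.0, 5.2, 5.4, 6.0),
                         post_values = rep(5.5, 18),
                         meals = data.frame(time = 1000, carbs = 50),
                         exercises = data.frame(time = numeric(0),
                                                ee = numeric(0)),
                         person_id = "P01", day = 1, role = NA_character_) {
  list(person_id = person_id, session_id = "S1", day = day,
       meal_time = meal_time,
       pre_times = seq(meal_time - 15, meal_time, by = 5),
       pre_values = pre_values,
       post_times = seq(meal_time + 5, meal_time + 90, by = 5),
       post_values = post_values,
       meals = meals, exercises = exercises, role = role)
}

# Random person parameters and a random segment, for property-style loops.
random_params <- function() {
  person_params(alpha_d = runif(1, 4, 25), beta_d = runif(1, 0.01, 0.1),
                alpha_e = runif(1, 4, 20), beta_e = runif(1, -0.05, 0),
                c_syn = runif(1, -0.5, 0.5), sigma = runif(1, 0.1, 1))
}

random_segment <- function(n_meals = sample(1:2, 1),
                           n_ex = sample(0:2, 1)) {
  tau <- 5 * sample(100:200, 1)
  make_segment(
    meal_time = tau,
    pre_values = runif(4, 4, 7),
    post_values = runif(18, 4, 9),
    meals = data.frame(time = tau + sort(c(0, 5 * sample(1:17, n_meals - 1))),
                       carbs = runif(n_meals, 20, 90)),
    exercises = if (n_ex == 0) data.frame(time = numeric(0), ee = numeric(0))
                else data.frame(time = tau + 5 * sample(-3:17, n_ex),
                                ee = runif(n_ex, 10, 140)))
}

# Small seeded cohorts reused across tests.
tiny_rct_segments <- function(seed = 42) {
  split_train_test(segment_sessions(simulate_cohort(standard_rct_spec(),
                                                    seed = seed)), 6)
}

tiny_patient_segments <- function(seed = 11, n_persons = 6,
                                  exercise_fraction = 0.15, ...) {
  spec <- cohort_spec("patient", n_persons = n_persons,
                      exercise_fraction = exercise_fraction, ...)
  split_train_test(segment_sessions(simulate_cohort(spec, seed = seed)), 3)
}

# Reduced sampler settings for unit tests (not convergence claims).
quick_control <- function(seed = 1, n_chains = 2, n_iter = 700,
                          n_burnin = 300, n_adapt = 300)
  sampler_control(n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
                  n_adapt = n_adapt, seed = seed)
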