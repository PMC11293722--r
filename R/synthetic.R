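#' Specification of a synthetic cohort
#'
#' Describes the study design and generative truth of a synthetic cohort. Two
#' profiles are emulated: a balanced healthy-group RCT (one target meal per
#' day over 6-day sessions, postprandial-walk intensity randomized across
#' low/moderate/high conditions) and an imbalanced free-living patient cohort
#' (3-day sessions, several meals per day, postprandial exercise present in
#' only a small fraction of meals and mostly of low energy expenditure).
#'
#' Default generative parameters (healthy group): \code{alpha_d = 12} min,
#' \code{beta_d = 0.04} mmol/L/g, \code{alpha_e = 10} min, \code{beta_e =
#' -0.02} mmol/L/kcal, \code{c_syn = 0.2}, noise \code{sigma = 0.4} mmol/L,
#' giving 2-4 mmol/L rises for 50-80 g meals and 1.6-2.6 mmol/L drops for
#' 80-130 kcal walks -- the largest exercise strength that keeps trajectories
#' positive under the RCT walk intensities. The patient group defaults to an
#' exercise strength of half the healthy mean (attenuated glucose uptake in
#' the diabetic group); all values are simulator inputs.
#'
#' @param group \code{"healthy"} or \code{"patient"}.
#' @param n_persons Number of persons.
#' @param n_sessions Sessions per person (patients are observed in monthly
#'   sessions; the RCT has one).
#' @param n_days Days per session: 6 for the RCT, 3 free-living.
#' @param theta Named list of group-mean parameters
#'   (\code{alpha_d, beta_d, alpha_e, beta_e, c_syn}).
#' @param theta_sd Named list of between-person SDs for the same parameters.
#' @param sigma Observation-noise SD, mmol/L.
#' @param baseline_mean,baseline_sd Per-segment baseline glucose law, mmol/L.
#' @param meals_per_day Meals per day (free-living; the RCT records one target
#'   meal per day).
#' @param carb_mean,carb_sd Carbohydrate dose law, grams.
#' @param exercise_fraction Fraction of free-living meals followed by a
#'   postprandial exercise bout (default 0.05, mirroring the rarity of
#'   postprandial exercise in free-living patients).
#' @param ee_shape,ee_mean Gamma law (shape, mean in kcal) of free-living bout
#'   energy expenditure; the default mostly stays below the 60 kcal
#'   exercise-segment threshold.
#' @param rct_ee Named EE mapping (kcal) for the RCT walk conditions.
#' @return An object of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(group = c("healthy", "patient"),
                        n_persons = if (group[1] == "healthy") 4L else 20L,
                        n_sessions = 1L,
                        n_days = if (group[1] == "healthy") 6L else 3L,
                        theta = NULL, theta_sd = NULL,
                        sigma = 0.4,
                        baseline_mean = 5.5, baseline_sd = 0.4,
                        meals_per_day = if (group[1] == "healthy") 1L else 3L,
                        carb_mean = 60, carb_sd = 10,
                        exercise_fraction = 0.05,
                        ee_shape = 2, ee_mean = 60,
                        rct_ee = c(low = 0, moderate = 80, high = 130)) {
  group <- match.arg(group)
  th <- list(alpha_d = 12, beta_d = 0.04, alpha_e = 10,
             beta_e = if (group == "healthy") -0.02 else -0.01, c_syn = 0.2)
  th[names(theta)] <- theta
  # the patient attenuation multiplies each person's exercise strength, so the
  # between-person spread of beta_e scales with its mean
  ts <- list(alpha_d = 2, beta_d = 0.006, alpha_e = 1.5,
             beta_e = if (group == "healthy") 0.003 else 0.0015,
             c_syn = 0.05)
  ts[names(theta_sd)] <- theta_sd
  stopifnot(n_persons >= 1L, all(unlist(ts) >= 0), sigma >= 0,
            exercise_fraction >= 0, exercise_fraction <= 1)
  if (group == "healthy" && n_days != 6L && meals_per_day == 1L)
    stopifnot(n_days >= 1L)
  structure(list(group = group, n_persons = as.integer(n_persons),
                 n_sessions = as.integer(n_sessions),
                 n_days = as.integer(n_days),
                 theta = th, theta_sd = ts, sigma = sigma,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 meals_per_day = as.integer(meals_per_day),
                 carb_mean = carb_mean, carb_sd = carb_sd,
                 exercise_fraction = exercise_fraction,
                 ee_shape = ee_shape, ee_mean = ee_mean, rct_ee = rct_ee),
            class = "cohort_spec")
}

#' Draw person-specific parameters from the group law
#'
#' Gaussian draws at the spec's group means and between-person SDs, with the
#' response speeds redrawn until positive (truncation). Uses the current RNG
#' state; seed via [set.seed()] or [simulate_cohort()].
#'
#' @param spec A [cohort_spec()].
#' @return data.frame with one row per person.
#' @export
draw_person_params <- function(spec) {
  n <- spec$n_persons
  draw_pos <- function(mean, sd) {
    x <- stats::rnorm(n, mean, sd)
    while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
    x
  }
  data.frame(
    person_id = sprintf("%s%02d", if (spec$group == "healthy") "H" else "P",
                        seq_len(n)),
    alpha_d = draw_pos(spec$theta$alpha_d, spec$theta_sd$alpha_d),
    beta_d = stats::rnorm(n, spec$theta$beta_d, spec$theta_sd$beta_d),
    alpha_e = draw_pos(spec$theta$alpha_e, spec$theta_sd$alpha_e),
    beta_e = stats::rnorm(n, spec$theta$beta_e, spec$theta_sd$beta_e),
    c_syn = stats::rnorm(n, spec$theta$c_syn, spec$theta_sd$c_syn),
    sigma = spec$sigma,
    stringsAsFactors = FALSE)
}

# One person-session's events for the RCT protocol: one target meal per day at
# lunch time, near-constant carbs, and on moderate/high days a 20-min walk
# starting 30 min after the meal, summarized as a single (time, EE) event.
rct_session_events <- function(spec, person_id, session_id) {
  cond <- rep(c("low", "moderate", "high"), length.out = 3)[c(1, 2, 3, 1, 2, 3)]
  cond <- cond[seq_len(spec$n_days)]
  carbs_base <- stats::rnorm(1, spec$carb_mean, spec$carb_sd)
  meal_t <- (seq_len(spec$n_days) - 1) * 1440 + 720  # 12:00 each day
  meals <- data.frame(person_id = person_id, session_id = session_id,
                      time_min = meal_t,
                      carbs_g = pmax(10, carbs_base +
                                       stats::rnorm(spec$n_days, 0, 2)))
  has_ex <- cond != "low"
  exercises <- data.frame(person_id = person_id, session_id = session_id,
                          time_min = meal_t[has_ex] + 30,
                          ee_kcal = unname(spec$rct_ee[cond[has_ex]]))
  list(meals = meals, exercises = exercises, condition = cond)
}

# One person-session's events for the free-living protocol: meals_per_day
# meals at jittered habitual times, carb draws, and a postprandial bout after
# a random small fraction of meals with mostly low EE.
freeliving_session_events <- function(spec, person_id, session_id) {
  slots <- round(seq(480, 1110, length.out = max(spec$meals_per_day, 1)))
  meal_t <- unlist(lapply(seq_len(spec$n_days) - 1, function(d)
    d * 1440 + slots + 5 * sample.int(7, length(slots), replace = TRUE) - 20))
  meal_t <- sort(meal_t)
  meals <- data.frame(person_id = person_id, session_id = session_id,
                      time_min = meal_t,
                      carbs_g = pmax(10, stats::rnorm(length(meal_t),
                                                      spec$carb_mean,
                                                      spec$carb_sd * 1.5)))
  has_ex <- stats::runif(length(meal_t)) < spec$exercise_fraction
  exercises <- data.frame(person_id = character(0), session_id = character(0),
                          time_min = numeric(0), ee_kcal = numeric(0))
  if (any(has_ex)) {
    ee <- stats::rgamma(sum(has_ex), shape = spec$ee_shape,
                        scale = spec$ee_mean / spec$ee_shape)
    exercises <- data.frame(person_id = person_id, session_id = session_id,
                            time_min = meal_t[has_ex] +
                              5 * sample(3:9, sum(has_ex), replace = TRUE),
                            ee_kcal = round(ee, 1))
  }
  list(meals = meals, exercises = exercises)
}

#' Generate RCT sessions (events only)
#'
#' Six-day healthy-group sessions under the randomized postprandial-walk
#' protocol: conditions low/moderate/high on days (1,4)/(2,5)/(3,6), one
#' target meal per day with near-constant carbohydrate, and on
#' moderate/high days one walk event 30 minutes after meal start with
#' condition-mapped energy expenditure. No other exercise near meals.
#'
#' @param spec A healthy-group [cohort_spec()] with \code{n_days = 6}.
#' @return list(meals, exercises) data.frames covering all persons/sessions.
#' @export
generate_rct_sessions <- function(spec) {
  if (spec$group != "healthy" || spec$n_days != 6L)
    stop("RCT protocol requires group='healthy' and n_days=6")
  out <- list(meals = NULL, exercises = NULL)
  for (p in seq_len(spec$n_persons)) for (s in seq_len(spec$n_sessions)) {
    ev <- rct_session_events(spec, sprintf("H%02d", p), sprintf("S%d", s))
    out$meals <- rbind(out$meals, ev$meals)
    out$exercises <- rbind(out$exercises, ev$exercises)
  }
  out
}

#' Generate free-living sessions (events only)
#'
#' Three-day patient sessions with several meals per day and rare, mostly
#' low-EE postprandial exercise, emulating the pronounced imbalance of
#' postprandial exercise in free-living patient data.
#'
#' @param spec A patient-group [cohort_spec()] with \code{n_days = 3}.
#' @return list(meals, exercises) data.frames.
#' @export
generate_freeliving_sessions <- function(spec) {
  if (spec$group != "patient") stop("free-living protocol requires group='patient'")
  out <- list(meals = NULL, exercises = NULL)
  for (p in seq_len(spec$n_persons)) for (s in seq_len(spec$n_sessions)) {
    ev <- freeliving_session_events(spec, sprintf("P%02d", p), sprintf("S%d", s))
    out$meals <- rbind(out$meals, ev$meals)
    out$exercises <- rbind(out$exercises, ev$exercises)
  }
  if (is.null(out$exercises))
    out$exercises <- data.frame(person_id = character(0),
                                session_id = character(0),
                                time_min = numeric(0), ee_kcal = numeric(0))
  out
}

#' Simulate CGM glucose for one person-session
#'
#' Fills the 5-minute grid with a piecewise-constant baseline (a fresh
#' baseline is drawn at each meal, taking effect 15 minutes before the meal so
#' the preprandial window sits on it), plus the model-kind response to all
#' events, plus i.i.d. Gaussian noise. With \code{sigma = 0} the postprandial
#' samples equal the noise-free forward prediction exactly.
#'
#' @param params One row of [draw_person_params()] (or a list with the same
#'   fields).
#' @param meals,exercises Event data.frames for one person-session
#'   (\code{time_min}, \code{carbs_g} / \code{ee_kcal}).
#' @param n_days Session length in days.
#' @param model_kind Forward model used for the responses.
#' @param sigma Noise SD; overrides \code{params$sigma} when given.
#' @param baseline_mean,baseline_sd Per-segment baseline law.
#' @return data.frame(time_min, glucose_mmol_l, day).
#' @export
simulate_glucose <- function(params, meals, exercises, n_days,
                             model_kind = c("synergistic", "additive", "single"),
                             sigma = params$sigma,
                             baseline_mean = 5.5, baseline_sd = 0.4) {
  model_kind <- match.arg(model_kind)
  grid <- seq(0, n_days * 1440 - 5, by = 5)
  mt <- meals$time_min
  base <- rep(stats::rnorm(1, baseline_mean, baseline_sd), length(grid))
  if (length(mt)) {
    seg_base <- stats::rnorm(length(mt), baseline_mean, baseline_sd)
    for (i in seq_along(mt)) base[grid >= mt[i] - 15] <- seg_base[i]
  }
  r_d <- if (length(mt))
    bell_response(params$alpha_d, params$beta_d * meals$carbs_g, mt, grid)
  else numeric(length(grid))
  r_e <- numeric(length(grid))
  if (model_kind != "single" && nrow(exercises) > 0L)
    r_e <- bell_response(params$alpha_e, params$beta_e * exercises$ee_kcal,
                         exercises$time_min, grid)
  syn <- if (model_kind == "synergistic") params$c_syn * r_d * r_e
         else numeric(length(grid))
  y <- base + r_d + r_e + syn
  if (sigma > 0) y <- y + stats::rnorm(length(grid), 0, sigma)
  data.frame(time_min = grid, glucose_mmol_l = pmax(y, 0.1),
             day = grid %/% 1440 + 1L)
}

#' Simulate a full synthetic cohort
#'
#' Draws person parameters, generates the protocol's events, and simulates the
#' CGM streams. Identical seeds yield identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @param model_kind Generative forward model.
#' @return A \code{"glucose_cohort"} whose \code{truth} records the person
#'   parameters and the spec.
#' @export
simulate_cohort <- function(spec, seed = 1L,
                            model_kind = c("synergistic", "additive", "single")) {
  model_kind <- match.arg(model_kind)
  set.seed(seed)
  persons <- draw_person_params(spec)
  glucose <- NULL; meals <- NULL; exercises <- NULL
  for (p in seq_len(spec$n_persons)) {
    pid <- persons$person_id[p]
    for (s in seq_len(spec$n_sessions)) {
      sid <- sprintf("S%d", s)
      ev <- if (spec$group == "healthy")
        rct_session_events(spec, pid, sid)
      else freeliving_session_events(spec, pid, sid)
      g <- simulate_glucose(persons[p, ], ev$meals, ev$exercises, spec$n_days,
                            model_kind = model_kind, sigma = spec$sigma,
                            baseline_mean = spec$baseline_mean,
                            baseline_sd = spec$baseline_sd)
      g$person_id <- pid; g$session_id <- sid
      glucose <- rbind(glucose, g[, c("person_id", "session_id", "day",
                                      "time_min", "glucose_mmol_l")])
      meals <- rbind(meals, ev$meals)
      exercises <- rbind(exercises, ev$exercises)
    }
  }
  if (is.null(exercises))
    exercises <- data.frame(person_id = character(0), session_id = character(0),
                            time_min = numeric(0), ee_kcal = numeric(0))
  glucose$glucose_mmol_l <- round(glucose$glucose_mmol_l, 4)
  glucose_cohort(glucose, meals, exercises, group = spec$group,
                 truth = list(model_kind = model_kind, seed = seed,
                              spec = unclass(spec), persons = persons))
}

#' Derive stage-specific child seeds from one global seed
#'
#' A single run seed fans out deterministically to per-stage seeds
#' (simulation, each MCMC chain, replicates) so end-to-end runs are
#' reproducible from one integer.
#'
#' @param seed Global integer seed.
#' @param n Number of child seeds.
#' @return Integer vector of length \code{n}, each below 2^31.
#' @export
child_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
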