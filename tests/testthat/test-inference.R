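test_that("fits are reproducible given the same seed and config", {
  segs <- filter_role(tiny_patient_segments(seed = 51, n_persons = 3), "train")
  ctl <- quick_control(seed = 5, n_iter = 500, n_burnin = 200)
  f1 <- fit_glucose(segs, "additive", control = ctl)
  f2 <- fit_glucose(segs, "additive", control = ctl)
  expect_identical(lapply(f1$samples, as.matrix), lapply(f2$samples, as.matrix))
  f3 <- fit_glucose(segs, "additive", control = quick_control(seed = 6,
                                                              n_iter = 500,
                                                              n_burnin = 200))
  expect_false(identical(as.matrix(f1$samples[[1]]), as.matrix(f3$samples[[1]])))
})

test_that("the single model carries no exercise parameters", {
  segs <- filter_role(tiny_patient_segments(seed = 52, n_persons = 3), "train")
  fit <- fit_glucose(segs, "single", control = quick_control(n_iter = 500,
                                                             n_burnin = 200))
  expect_false(any(grepl("ae|be|c_tilde|Cp", fit$summary$parameter)))
  est <- point_estimates(fit)
  expect_true(all(is.na(est$alpha_e)))
  expect_true(all(!is.na(est$alpha_d)))
})

test_that("with no exercise anywhere the exercise prior is returned unchanged", {
  segs <- filter_role(tiny_patient_segments(seed = 53, n_persons = 4,
                                            exercise_fraction = 0), "train")
  pr <- prior_spec("gaussian", mu = c(10, -0.02), sigma2 = c(1, 1e-4))
  fit <- fit_glucose(segs, "additive", prior = pr,
                     control = quick_control(n_iter = 1200, n_burnin = 400))
  draws <- do.call(rbind, lapply(fit$samples, as.matrix))
  # posterior of the exercise-strength group mean ~ its prior N(-0.02, 0.01^2)
  expect_lt(abs(mean(draws[, "be_tilde"]) - (-0.02)), 3 * 0.01 / sqrt(100))
  expect_gt(sd(draws[, "be_tilde"]), 0.7 * 0.01)
  expect_lt(sd(draws[, "be_tilde"]), 1.3 * 0.01)
})

test_that("posterior medians lie within the draw range and drive prediction", {
  segs <- tiny_patient_segments(seed = 54, n_persons = 3)
  train <- filter_role(segs, "train")
  fit <- fit_glucose(train, "synergistic",
                     control = quick_control(n_iter = 500, n_burnin = 200))
  draws <- do.call(rbind, lapply(fit$samples, as.matrix))
  for (p in fit$summary$parameter) {
    expect_gte(fit$summary$median[fit$summary$parameter == p], min(draws[, p]))
    expect_lte(fit$summary$median[fit$summary$parameter == p], max(draws[, p]))
  }
  trajs <- predict(fit, filter_role(segs, "test"))
  expect_length(trajs, filter_role(segs, "test")$n_segments)
  expect_true(all(vapply(trajs, function(tr)
    all(is.finite(tr$y_hat)) && length(tr$y_hat) == 18, logical(1))))
  expect_length(residuals(fit), train$n_segments * 18)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2L)
  expect_length(sims[[1]], train$n_segments)
})

test_that("hierarchy with one person warns; invalid configs error", {
  segs <- filter_role(tiny_patient_segments(seed = 55, n_persons = 1), "train")
  expect_warning(fit_glucose(segs, "single",
                             control = quick_control(n_iter = 400,
                                                     n_burnin = 100)),
                 "fewer than 2 persons")
  expect_error(sampler_control(n_iter = 100, n_burnin = 100))
  expect_error(sampler_control(n_chains = 1))
})

test_that("fit artifacts persist to disk with draws, summary and config", {
  segs <- filter_role(tiny_patient_segments(seed = 56, n_persons = 3), "train")
  fit <- fit_glucose(segs, "additive", control = quick_control(n_iter = 400,
                                                               n_burnin = 200))
  dir <- tempfile()
  write_fit(fit, dir)
  expect_true(all(file.exists(file.path(dir, c("draws_chain1.csv",
                                               "draws_chain2.csv",
                                               "summary.json",
                                               "config.json")))))
  cfg <- jsonlite::fromJSON(file.path(dir, "config.json"))
  expect_equal(cfg$model_kind, "additive")
  expect_equal(cfg$control$seed, fit$control$seed)
  summ <- jsonlite::fromJSON(file.path(dir, "summary.json"))
  expect_true(all(c("parameter", "median", "rhat") %in% names(summ)))
})
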