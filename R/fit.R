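#' MCMC sampler configuration
#'
#' Defaults follow the study protocol: 4 chains, 4000 iterations per chain of
#' which the first 2000 are burn-in (so 2000 retained draws per chain), plus a
#' JAGS adaptation phase. At least 2 chains are required for the Gelman-Rubin
#' diagnostic.
#'
#' @param n_chains Number of chains (>= 2).
#' @param n_iter Total iterations per chain including burn-in.
#' @param n_burnin Burn-in iterations discarded from each chain.
#' @param n_adapt Sampler adaptation iterations (before burn-in).
#' @param thin Thinning interval.
#' @param seed Integer seed; fans out to one RNG seed per chain.
#' @return An object of class \code{"sampler_control"}.
#' @export
sampler_control <- function(n_chains = 4L, n_iter = 4000L, n_burnin = 2000L,
                            n_adapt = 1000L, thin = 1L, seed = 1L) {
  stopifnot(n_chains >= 2L, n_burnin < n_iter, n_burnin >= 0L, thin >= 1L)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), n_adapt = as.integer(n_adapt),
                 thin = as.integer(thin), seed = as.integer(seed),
                 backend = "rjags"),
            class = "sampler_control")
}

# Assemble the JAGS model string for a model kind and exercise-block prior.
# Diet block is identical everywhere: uniform hyperpriors on the group means,
# fixed person-level SDs 10 (alpha_d) and 0.1 (beta_d); person noise SD has a
# half-normal(2) prior. Exercise person-level SDs are learned under
# half-normal(1) hyperpriors.
jags_model_code <- function(model_kind, prior) {
  has_ex <- model_kind != "single"
  has_syn <- model_kind == "synergistic"
  obs <- c(
    "  for (n in 1:Nobs) {",
    "    for (i in 1:MMAX) {",
    "      rdt[n,i] <- step(t[n] - mt[seg[n],i]) * bd[pobs[n]] * mx[seg[n],i] *",
    "        exp(-0.5 * pow(t[n] - mt[seg[n],i] - 3 * ad[pobs[n]], 2) / pow(ad[pobs[n]], 2))",
    "    }",
    "    Rd[n] <- sum(rdt[n,])",
    if (has_ex) c(
      "    for (j in 1:EMAX) {",
      "      ret[n,j] <- step(t[n] - et[seg[n],j]) * be[pobs[n]] * ez[seg[n],j] *",
      "        exp(-0.5 * pow(t[n] - et[seg[n],j] - 3 * ae[pobs[n]], 2) / pow(ae[pobs[n]], 2))",
      "    }",
      "    Re[n] <- sum(ret[n,])"),
    if (has_syn)
      "    mu[n] <- base[n] + Rd[n] + Re[n] + Cp[pobs[n]] * Rd[n] * Re[n]"
    else if (has_ex)
      "    mu[n] <- base[n] + Rd[n] + Re[n]"
    else
      "    mu[n] <- base[n] + Rd[n]",
    "    y[n] ~ dnorm(mu[n], prec_y[pobs[n]])",
    "  }")
  person <- c(
    "  for (p in 1:P) {",
    "    ad[p] ~ dnorm(ad_tilde, 0.01) T(0,)",
    "    bd[p] ~ dnorm(bd_tilde, 100)",
    "    sigma_y[p] ~ dnorm(0, 0.25) T(0,)",
    "    prec_y[p] <- pow(sigma_y[p], -2)",
    if (has_ex) c(
      "    ae[p] ~ dnorm(ae_tilde, prec_ae_p) T(0,)",
      "    be[p] ~ dnorm(be_tilde, prec_be_p)"),
    if (has_syn)
      "    Cp[p] ~ dnorm(c_tilde, prec_c_p)",
    "  }",
    "  ad_tilde ~ dunif(0.5, 60)",
    "  bd_tilde ~ dunif(0, 1)")
  ex_sd <- if (has_ex) c(
    "  sd_ae ~ dnorm(0, 1) T(0,)",
    "  prec_ae_p <- pow(sd_ae, -2)",
    "  sd_be ~ dnorm(0, 1) T(0,)",
    "  prec_be_p <- pow(sd_be, -2)",
    if (has_syn) c(
      "  sd_c ~ dnorm(0, 1) T(0,)",
      "  prec_c_p <- pow(sd_c, -2)"))
  hyper <- if (!has_ex) NULL else switch(
    prior$mode,
    flat = c(
      "  ae_tilde ~ dunif(b_ae[1], b_ae[2])",
      "  be_tilde ~ dunif(b_be[1], b_be[2])",
      if (has_syn) "  c_tilde ~ dunif(b_c[1], b_c[2])"),
    gaussian = c(
      "  ae_tilde ~ dnorm(mu_t[1], 1 / s2_t[1])",
      "  be_tilde ~ dnorm(mu_t[2], 1 / s2_t[2])",
      if (has_syn) "  c_tilde ~ dnorm(mu_t[3], 1 / s2_t[3])"),
    extended = c(
      "  for (k in 1:K) {",
      "    eta[k] ~ dnorm(eta_m[k], prec_eta)",
      "  }",
      "  lambda ~ dnorm(lambda_m, prec_lambda) T(0,)",
      "  ae_tilde ~ dnorm(eta[1] * mu_s[1], 1 / (lambda * s2_s[1]))",
      "  be_tilde ~ dnorm(eta[2] * mu_s[2], 1 / (lambda * s2_s[2]))",
      if (has_syn) "  c_tilde ~ dnorm(eta[3] * mu_s[3], 1 / (lambda * s2_s[3]))"))
  paste(c("model {", obs, person, ex_sd, hyper, "}"), collapse = "\n")
}

# Flatten a segment set into the JAGS data list. Event times are re-expressed
# relative to each segment's meal time; padded events carry zero amplitude and
# a far-future time so they never contribute.
jags_data <- function(segments, model_kind, prior) {
  segs <- segments$segments
  if (length(segs) == 0L) stop("no segments to fit")
  has_ex <- model_kind != "single"
  person_ids <- sort(unique(vapply(segs, `[[`, "", "person_id")))
  pid <- match(vapply(segs, `[[`, "", "person_id"), person_ids)
  S <- length(segs)
  MMAX <- max(vapply(segs, function(s) nrow(s$meals), integer(1)), 1L)
  mt <- matrix(1e7, S, MMAX); mx <- matrix(0, S, MMAX)
  for (s in seq_len(S)) {
    m <- segs[[s]]$meals
    if (nrow(m)) {
      mt[s, seq_len(nrow(m))] <- m$time - segs[[s]]$meal_time
      mx[s, seq_len(nrow(m))] <- m$carbs
    }
  }
  y <- unlist(lapply(segs, `[[`, "post_values"))
  t_rel <- unlist(lapply(segs, function(s) s$post_times - s$meal_time))
  seg_idx <- rep(seq_len(S), vapply(segs, function(s) length(s$post_times),
                                    integer(1)))
  base <- vapply(segs, baseline_glucose, numeric(1))[seg_idx]
  dat <- list(Nobs = length(y), y = y, t = t_rel, seg = seg_idx,
              pobs = pid[seg_idx], base = base, P = length(person_ids),
              MMAX = MMAX, mt = mt, mx = mx)
  if (has_ex) {
    EMAX <- max(vapply(segs, function(s) nrow(s$exercises), integer(1)), 1L)
    et <- matrix(1e7, S, EMAX); ez <- matrix(0, S, EMAX)
    for (s in seq_len(S)) {
      e <- segs[[s]]$exercises
      if (nrow(e)) {
        et[s, seq_len(nrow(e))] <- e$time - segs[[s]]$meal_time
        ez[s, seq_len(nrow(e))] <- e$ee
      }
    }
    dat$EMAX <- EMAX; dat$et <- et; dat$ez <- ez
    k <- if (model_kind == "synergistic") 3L else 2L
    if (prior$mode == "flat") {
      dat$b_ae <- prior$bounds$alpha_e
      dat$b_be <- prior$bounds$beta_e
      if (model_kind == "synergistic") dat$b_c <- prior$bounds$c_syn
    } else {
      if (length(prior$mu) != k)
        stop(sprintf("prior has %d exercise components but the %s model needs %d",
                     length(prior$mu), model_kind, k))
      if (prior$mode == "gaussian") {
        dat$mu_t <- as.numeric(prior$mu); dat$s2_t <- as.numeric(prior$sigma2)
      } else {
        dat$K <- k
        dat$mu_s <- as.numeric(prior$mu); dat$s2_s <- as.numeric(prior$sigma2)
        dat$eta_m <- as.numeric(prior$eta_mean)
        dat$prec_eta <- 1 / prior$eta_sd^2
        dat$lambda_m <- prior$lambda_mean
        dat$prec_lambda <- 1 / prior$lambda_sd^2
      }
    }
  }
  list(data = dat, person_ids = person_ids)
}

jags_inits <- function(model_kind, prior, P, control) {
  seeds <- child_seeds(control$seed, control$n_chains)
  has_ex <- model_kind != "single"
  lapply(seq_len(control$n_chains), function(ch) {
    set.seed(seeds[ch])
    ini <- list(
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = seeds[ch],
      ad_tilde = stats::runif(1, 6, 25),
      bd_tilde = stats::runif(1, 0.01, 0.12),
      ad = pmax(stats::rnorm(P, 12, 2), 1),
      bd = stats::rnorm(P, 0.05, 0.01),
      sigma_y = stats::runif(P, 0.3, 1))
    if (has_ex) {
      ini$sd_ae <- stats::runif(1, 0.3, 1.5)
      ini$sd_be <- stats::runif(1, 0.005, 0.05)
      ini$ae <- pmax(stats::rnorm(P, 10, 2), 1)
      if (prior$mode == "flat") {
        ini$ae_tilde <- stats::runif(1, 5, 20)
        ini$be_tilde <- stats::runif(1, -0.05, -0.001)
      } else {
        ini$ae_tilde <- prior$mu[[1]] * stats::runif(1, 0.8, 1.2)
        ini$be_tilde <- prior$mu[[2]] * stats::runif(1, 0.4, 1.1)
      }
      ini$be <- rep(ini$be_tilde, P)
      if (model_kind == "synergistic") {
        ini$sd_c <- stats::runif(1, 0.05, 0.5)
        ini$c_tilde <- stats::runif(1, -0.2, 0.5)
        ini$Cp <- rep(ini$c_tilde, P)
      }
      if (prior$mode == "extended") {
        ini$eta <- prior$eta_mean * stats::runif(length(prior$eta_mean), 0.8, 1.2)
        ini$lambda <- stats::runif(1, 0.05, 0.2)
      }
    }
    ini
  })
}

jags_monitors <- function(model_kind, prior) {
  has_ex <- model_kind != "single"
  has_syn <- model_kind == "synergistic"
  c("ad_tilde", "bd_tilde", "ad", "bd", "sigma_y",
    if (has_ex) c("ae_tilde", "be_tilde", "sd_ae", "sd_be", "ae", "be"),
    if (has_syn) c("c_tilde", "sd_c", "Cp"),
    if (has_ex && prior$mode == "extended") c("eta", "lambda"))
}

#' Fit the hierarchical postprandial glucose model
#'
#' Bayesian fit by MCMC of the single, additive or synergistic model to a set
#' of meal-centered segments. Person-specific parameters are tied together by
#' group-level Gaussian priors whose means are the group hyperparameters;
#' the exercise-block hyperprior is controlled by \code{prior} (flat for no
#' transfer, Gaussian or shift-and-shrink hierarchical for transfer).
#'
#' @param segments A \code{"segment_set"} of training segments.
#' @param model_kind \code{"single"}, \code{"additive"} or
#'   \code{"synergistic"}.
#' @param prior A [prior_spec()] for the exercise hyperparameter block.
#' @param control A [sampler_control()].
#' @param quiet Suppress JAGS progress output.
#' @return An object of class \code{"glucofit"} with posterior draws
#'   (\code{coda::mcmc.list}), a summary table with medians, 95\% intervals
#'   and Gelman-Rubin statistics, and the training segments.
#' @export
fit_glucose <- function(segments,
                        model_kind = c("single", "additive", "synergistic"),
                        prior = flat_prior(),
                        control = sampler_control(), quiet = TRUE) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(segments, "segment_set"), inherits(prior, "prior_spec"))
  prep <- jags_data(segments, model_kind, prior)
  P <- prep$data$P
  if (P < 2L)
    warning("fewer than 2 persons: the hierarchy is weakly identified")
  code <- jags_model_code(model_kind, prior)
  inits <- jags_inits(model_kind, prior, P, control)
  jm <- tryCatch(
    rjags::jags.model(textConnection(code), data = prep$data, inits = inits,
                      n.chains = control$n_chains, n.adapt = control$n_adapt,
                      quiet = quiet),
    error = function(e) stop("JAGS model failure: ", conditionMessage(e)))
  if (control$n_burnin > 0)
    stats::update(jm, n.iter = control$n_burnin, progress.bar = "none")
  samples <- rjags::coda.samples(
    jm, variable.names = jags_monitors(model_kind, prior),
    n.iter = control$n_iter - control$n_burnin, thin = control$thin,
    progress.bar = "none")
  rhat <- gelman_rubin(samples)
  draws <- do.call(rbind, lapply(samples, as.matrix))
  qs <- t(apply(draws, 2, stats::quantile, probs = c(0.5, 0.025, 0.975)))
  summ <- data.frame(parameter = colnames(draws),
                     median = qs[, 1], q025 = qs[, 2], q975 = qs[, 3],
                     mean = colMeans(draws), sd = apply(draws, 2, stats::sd),
                     rhat = rhat[colnames(draws)], row.names = NULL)
  structure(list(samples = samples, summary = summ, rhat = rhat,
                 model_kind = model_kind, prior = prior, control = control,
                 person_ids = prep$person_ids,
                 n_segments = segments$n_segments, group = segments$group,
                 segments = segments),
            class = "glucofit")
}

#' Gelman-Rubin convergence diagnostic
#'
#' Classic (non-split) potential scale reduction factor: the square root of
#' the ratio of the pooled between/within-chain variance estimate to the mean
#' within-chain variance, computed per parameter.
#'
#' @param chains A \code{coda::mcmc.list}, or a list of equal-dimension draw
#'   matrices (iterations x parameters), one per chain.
#' @return Named numeric vector of R-hat values.
#' @export
gelman_rubin <- function(chains) {
  if (inherits(chains, "mcmc.list")) chains <- lapply(chains, as.matrix)
  if (is.matrix(chains) || length(chains) < 2L)
    stop("at least two chains are required for the Gelman-Rubin statistic")
  chains <- lapply(chains, as.matrix)
  dims <- vapply(chains, dim, integer(2))
  if (any(dims != dims[, 1])) stop("chains must have equal dimensions")
  n <- nrow(chains[[1]])
  means <- sapply(chains, colMeans)
  vars <- sapply(chains, function(m) apply(m, 2, stats::var))
  if (is.null(dim(means))) { # single parameter
    means <- matrix(means, nrow = 1); vars <- matrix(vars, nrow = 1)
  }
  W <- rowMeans(vars)
  B_over_n <- apply(means, 1, stats::var)
  var_plus <- (n - 1) / n * W + B_over_n
  r <- sqrt(var_plus / W)
  r[W == 0 & B_over_n == 0] <- 1
  stats::setNames(r, colnames(chains[[1]]))
}

#' Per-person posterior point estimates
#'
#' Elementwise marginal posterior medians of every person-specific parameter,
#' the values plugged into the forward model for prediction.
#'
#' @param fit A \code{"glucofit"}.
#' @return data.frame with one row per person (\code{alpha_d, beta_d,
#'   alpha_e, beta_e, c_syn, sigma}); exercise columns are \code{NA} where the
#'   model has no such parameter.
#' @export
point_estimates <- function(fit) {
  stopifnot(inherits(fit, "glucofit"))
  med <- stats::setNames(fit$summary$median, fit$summary$parameter)
  P <- length(fit$person_ids)
  get <- function(stub) {
    nm <- sprintf("%s[%d]", stub, seq_len(P))
    if (!all(nm %in% names(med))) return(rep(NA_real_, P))
    unname(med[nm])
  }
  data.frame(person_id = fit$person_ids,
             alpha_d = get("ad"), beta_d = get("bd"),
             alpha_e = get("ae"), beta_e = get("be"),
             c_syn = get("Cp"), sigma = get("sigma_y"),
             stringsAsFactors = FALSE)
}

#' @export
coef.glucofit <- function(object, ...) point_estimates(object)

#' @export
print.glucofit <- function(x, ...) {
  cat(sprintf("Hierarchical postprandial glucose fit (%s model, %s group)\n",
              x$model_kind, x$group))
  cat(sprintf("  %d segments, %d persons; %d chains x %d retained draws; exercise prior: %s\n",
              x$n_segments, length(x$person_ids), x$control$n_chains,
              x$control$n_iter - x$control$n_burnin, x$prior$mode))
  hyper <- grep("_tilde$|^sd_|^eta|^lambda$", x$summary$parameter)
  cat(sprintf("  max R-hat (all parameters): %.4f\n", max(x$rhat)))
  print(x$summary[hyper, c("parameter", "median", "q025", "q975", "rhat")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.glucofit <- function(object, ...) {
  out <- list(model_kind = object$model_kind, group = object$group,
              n_segments = object$n_segments,
              persons = object$person_ids,
              hyper = object$summary[grep("\\[", object$summary$parameter,
                                          invert = TRUE), ],
              point_estimates = point_estimates(object),
              max_rhat = max(object$rhat), control = object$control)
  class(out) <- "summary.glucofit"
  out
}

#' @export
print.summary.glucofit <- function(x, ...) {
  cat(sprintf("%s model, %s group: %d segments, %d persons (max R-hat %.4f)\n",
              x$model_kind, x$group, x$n_segments, length(x$persons), x$max_rhat))
  cat("\nGroup-level parameters:\n")
  print(x$hyper, row.names = FALSE, digits = 4)
  cat("\nPer-person posterior medians:\n")
  print(x$point_estimates, row.names = FALSE, digits = 4)
  invisible(x)
}

person_params_row <- function(est, person_id) {
  r <- est[est$person_id == person_id, ]
  if (nrow(r) != 1L) stop("no fitted parameters for person ", person_id)
  person_params(alpha_d = r$alpha_d, beta_d = r$beta_d, alpha_e = r$alpha_e,
                beta_e = r$beta_e, c_syn = r$c_syn,
                sigma = if (is.na(r$sigma)) 0.4 else r$sigma)
}

#' Predict postprandial trajectories from a fit
#'
#' Plugs each person's posterior-median parameters into the forward model for
#' the supplied segments.
#'
#' @param object A \code{"glucofit"}.
#' @param newdata A \code{"segment_set"}; defaults to the training segments.
#' @param ... Unused.
#' @return List of \code{"glucose_trajectory"} objects, one per segment.
#' @export
predict.glucofit <- function(object, newdata = object$segments, ...) {
  est <- point_estimates(object)
  lapply(newdata$segments, function(s)
    glucose_trajectory(person_params_row(est, s$person_id), s,
                       model_kind = object$model_kind))
}

#' @export
fitted.glucofit <- function(object, ...)
  unlist(lapply(predict(object), `[[`, "y_hat"))

#' @export
residuals.glucofit <- function(object, ...) {
  obs <- unlist(lapply(object$segments$segments, `[[`, "post_values"))
  obs - fitted(object)
}

#' @export
plot.glucofit <- function(x, segment = x$segments$segments[[1]], ...) {
  tr <- glucose_trajectory(person_params_row(point_estimates(x),
                                             segment$person_id),
                           segment, model_kind = x$model_kind)
  plot(tr, segment = segment, ...)
}

#' Simulate postprandial observations from a fitted model
#'
#' Draws noisy postprandial series from the plug-in (posterior-median) model:
#' mean trajectory plus i.i.d. Gaussian noise at each person's posterior
#' median noise SD.
#'
#' @param object A \code{"glucofit"}.
#' @param nsim Number of replicate datasets.
#' @param seed Optional seed.
#' @param newdata A \code{"segment_set"}; defaults to the training segments.
#' @param ... Unused.
#' @return List of length \code{nsim}; each element is a list of numeric
#'   vectors parallel to the segments' postprandial grids.
#' @export
simulate.glucofit <- function(object, nsim = 1, seed = NULL,
                              newdata = object$segments, ...) {
  if (!is.null(seed)) set.seed(seed)
  est <- point_estimates(object)
  trajs <- predict(object, newdata)
  sig <- stats::setNames(est$sigma, est$person_id)
  lapply(seq_len(nsim), function(k)
    lapply(seq_along(trajs), function(i) {
      s <- newdata$segments[[i]]
      trajs[[i]]$y_hat + stats::rnorm(length(trajs[[i]]$y_hat), 0,
                                      sig[[s$person_id]])
    }))
}

#' Persist a fit to a directory
#'
#' Writes one CSV of draws per chain, a \code{summary.json} (medians,
#' intervals, R-hat) and a \code{config.json} echoing the sampler and prior
#' settings.
#'
#' @param fit A \code{"glucofit"}.
#' @param dir Output directory.
#' @export
write_fit <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (ch in seq_along(fit$samples))
    utils::write.csv(as.matrix(fit$samples[[ch]]),
                     file.path(dir, sprintf("draws_chain%d.csv", ch)),
                     row.names = FALSE)
  jsonlite::write_json(fit$summary, file.path(dir, "summary.json"),
                       digits = NA, dataframe = "rows", pretty = TRUE)
  jsonlite::write_json(list(model_kind = fit$model_kind,
                            prior = unclass(fit$prior),
                            control = unclass(fit$control),
                            person_ids = fit$person_ids,
                            n_segments = fit$n_segments, group = fit$group),
                       file.path(dir, "config.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(dir)
}
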