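#' Gaussian summary of a fit's exercise hyperparameter block
#'
#' Moment-matches the marginal posteriors of the exercise group means
#' (\code{alpha_e, beta_e} and, for the synergistic model, \code{c_syn}) with
#' independent Gaussians. The default uses posterior means and variances;
#' medians with squared MAD are available as a robust alternative.
#'
#' @param fit A \code{"glucofit"} for an additive or synergistic model.
#' @param method \code{"moments"} or \code{"median_mad"}.
#' @return A [source_summary()].
#' @export
exercise_block_summary <- function(fit, method = c("moments", "median_mad")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "glucofit"))
  if (fit$model_kind == "single")
    stop("the single model has no exercise block")
  pars <- c("ae_tilde", "be_tilde",
            if (fit$model_kind == "synergistic") "c_tilde")
  draws <- do.call(rbind, lapply(fit$samples, function(m) as.matrix(m)[, pars]))
  if (method == "moments") {
    mu <- colMeans(draws); s2 <- apply(draws, 2, stats::var)
  } else {
    mu <- apply(draws, 2, stats::median)
    s2 <- apply(draws, 2, stats::mad)^2
  }
  source_summary(mu, s2,
                 components = c("alpha_e", "beta_e", "c_syn")[seq_along(pars)])
}

#' Fit the source task (healthy RCT domain)
#'
#' Pretraining step of the transfer workflow: fits the model to the balanced
#' RCT segments of the healthy group with entirely uninformative (flat)
#' exercise-block priors, and attaches the Gaussian summary
#' (\code{mu_S, Sigma_S}) of the exercise hyperparameter posterior that the
#' rescaling step consumes.
#'
#' @param rct_train Healthy-group training \code{"segment_set"}.
#' @param model_kind \code{"additive"} or \code{"synergistic"}.
#' @param control A [sampler_control()].
#' @param ... Passed to [fit_glucose()].
#' @return A \code{"glucofit"} with an added \code{source} element
#'   (a [source_summary()]).
#' @export
fit_source_task <- function(rct_train,
                            model_kind = c("synergistic", "additive"),
                            control = sampler_control(), ...) {
  model_kind <- match.arg(model_kind)
  fit <- fit_glucose(rct_train, model_kind, prior = flat_prior(),
                     control = control, ...)
  fit$source <- exercise_block_summary(fit)
  fit
}

#' Fit the target task (patient domain)
#'
#' Joint learning of all group hyperparameters and per-patient parameters from
#' observational patient data, under the exercise-block prior produced by
#' [rescale_prior()] (flat when no transfer is used).
#'
#' @param patient_train Patient-group training \code{"segment_set"}.
#' @param model_kind Model kind.
#' @param prior A [prior_spec()].
#' @param control A [sampler_control()].
#' @param ... Passed to [fit_glucose()].
#' @return A \code{"glucofit"}.
#' @export
fit_target_task <- function(patient_train,
                            model_kind = c("synergistic", "additive", "single"),
                            prior = flat_prior(),
                            control = sampler_control(), ...) {
  model_kind <- match.arg(model_kind)
  fit_glucose(patient_train, model_kind, prior = prior, control = control, ...)
}

#' Two-step transfer-learning pipeline
#'
#' Runs the full prior-rescaling workflow: (1) pretrain on the healthy-group
#' RCT segments with flat exercise priors and summarize the exercise
#' hyperparameter posterior as a Gaussian; (2) rescale it under the policy
#' (shift by eta, shrink by lambda) and fit the patient data with the result
#' as the informative exercise-block prior. With \code{policy$mode = "none"}
#' the source step is skipped and the target fit uses flat priors. In
#' extended mode eta and lambda are sampled jointly with all target-task
#' parameters.
#'
#' @param rct_train Healthy-group training segments (ignored when
#'   \code{policy$mode = "none"} or \code{source} is supplied).
#' @param patient_train Patient-group training segments.
#' @param model_kind Model kind (transfer requires an exercise block).
#' @param policy A [rescale_policy()].
#' @param control Sampler settings for the target fit.
#' @param control_source Sampler settings for the source fit (defaults to
#'   \code{control}).
#' @param source Optional precomputed source: a \code{"glucofit"} from
#'   [fit_source_task()] or a [source_summary()], reused instead of refitting.
#' @return An object of class \code{"transfer_fit"}: list with
#'   \code{target_fit}, \code{source_fit} (\code{NULL} if skipped or supplied
#'   as a summary), \code{prior} (the rescaled prior with provenance) and
#'   \code{policy}.
#' @export
run_transfer_pipeline <- function(rct_train, patient_train,
                                  model_kind = c("synergistic", "additive"),
                                  policy = rescale_policy("extended"),
                                  control = sampler_control(),
                                  control_source = control,
                                  source = NULL) {
  model_kind <- match.arg(model_kind)
  source_fit <- NULL
  src_summary <- NULL
  if (policy$mode != "none") {
    if (inherits(source, "source_summary")) {
      src_summary <- source
    } else if (inherits(source, "glucofit")) {
      source_fit <- source
      src_summary <- if (!is.null(source$source)) source$source
                     else exercise_block_summary(source)
    } else {
      source_fit <- fit_source_task(rct_train, model_kind,
                                    control = control_source)
      src_summary <- source_fit$source
    }
  }
  prior <- rescale_prior(src_summary, policy)
  target_fit <- fit_target_task(patient_train, model_kind, prior = prior,
                                control = control)
  structure(list(target_fit = target_fit, source_fit = source_fit,
                 source_summary = src_summary, prior = prior, policy = policy),
            class = "transfer_fit")
}

#' @export
print.transfer_fit <- function(x, ...) {
  cat(sprintf("<transfer_fit> mode=%s\n", x$policy$mode))
  if (!is.null(x$source_summary)) {
    cat("source exercise-block summary:\n")
    print(x$source_summary)
  }
  cat("target fit:\n")
  print(x$target_fit)
  invisible(x)
}

#' @export
coef.transfer_fit <- function(object, ...) coef(object$target_fit)

#' @export
predict.transfer_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) predict(object$target_fit)
  else predict(object$target_fit, newdata)
}
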