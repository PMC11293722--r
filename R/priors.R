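#' Prior specification for the exercise hyperparameter block
#'
#' The diet-block priors are the same in every configuration: uniform
#' hyperpriors on the group means (\code{alpha_d ~ U(0.5, 60)} minutes,
#' \code{beta_d ~ U(0, 1)} mmol/L/g) with fixed person-level SDs of 10 minutes
#' and 0.1 mmol/L/g. Only the exercise block (\code{alpha_e, beta_e, c_syn}
#' group means) changes with the transfer mode:
#' \describe{
#'   \item{flat}{wide proper uniforms: \code{alpha_e in (0.5, 60)},
#'     \code{beta_e in (-1, 1)}, \code{c_syn in (-5, 5)} (no transfer).}
#'   \item{gaussian}{independent Gaussians \code{N(mu, sigma2)} per component
#'     (normal transfer, or extended transfer with fixed eta/lambda).}
#'   \item{extended}{hierarchical: the group means are
#'     \code{N(eta * mu, lambda * sigma2)} with latent \code{eta} (one per
#'     component) and a scalar latent \code{lambda > 0} under Gaussian
#'     hyperpriors.}
#' }
#' Person-level exercise SDs are always learned under half-normal(1)
#' hyperpriors.
#'
#' @param mode \code{"flat"}, \code{"gaussian"} or \code{"extended"}.
#' @param mu,sigma2 Numeric vectors over the exercise components, in the order
#'   \code{alpha_e, beta_e[, c_syn]} (gaussian/extended modes).
#' @param eta_mean,eta_sd Hyperprior means/SD of the mean-shift \code{eta}
#'   (extended mode); defaults: 1 for \code{alpha_e} and \code{c_syn}, 0.5 for
#'   \code{beta_e}, SD 0.25.
#' @param lambda_mean,lambda_sd Hyperprior mean/SD of the variance-shrink
#'   \code{lambda} (extended mode), truncated positive; defaults 0.1 and 0.05.
#' @param bounds Named list of flat-prior bounds, overridable.
#' @return An object of class \code{"prior_spec"}.
#' @export
prior_spec <- function(mode = c("flat", "gaussian", "extended"),
                       mu = NULL, sigma2 = NULL,
                       eta_mean = NULL, eta_sd = 0.25,
                       lambda_mean = 0.1, lambda_sd = 0.05,
                       bounds = list(alpha_e = c(0.5, 60), beta_e = c(-1, 1),
                                     c_syn = c(-5, 5))) {
  mode <- match.arg(mode)
  if (mode != "flat") {
    if (is.null(mu) || is.null(sigma2)) stop("mode '", mode,
                                             "' requires mu and sigma2")
    if (length(mu) != length(sigma2)) stop("mu and sigma2 lengths differ")
    if (any(sigma2 <= 0)) stop("sigma2 must be positive")
    if (!length(mu) %in% 2:3) stop("exercise block has 2 or 3 components")
  }
  if (mode == "extended") {
    if (is.null(eta_mean)) eta_mean <- c(1, 0.5, 1)[seq_along(mu)]
    if (length(eta_mean) != length(mu)) stop("eta_mean length mismatch")
    if (eta_sd <= 0 || lambda_sd <= 0) stop("hyperprior SDs must be positive")
  }
  structure(list(mode = mode, mu = mu, sigma2 = sigma2, eta_mean = eta_mean,
                 eta_sd = eta_sd, lambda_mean = lambda_mean,
                 lambda_sd = lambda_sd, bounds = bounds),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("<prior_spec> exercise-block mode: %s\n", x$mode))
  if (x$mode != "flat") {
    cat("  mu:     ", paste(signif(x$mu, 4), collapse = ", "), "\n")
    cat("  sigma2: ", paste(signif(x$sigma2, 4), collapse = ", "), "\n")
  }
  if (x$mode == "extended")
    cat(sprintf("  eta ~ N((%s), %.2f), lambda ~ N(%.2f, %.2f) [lambda > 0]\n",
                paste(x$eta_mean, collapse = ", "), x$eta_sd,
                x$lambda_mean, x$lambda_sd))
  invisible(x)
}

#' Flat (no-transfer) prior
#' @inheritParams prior_spec
#' @return A flat \code{"prior_spec"}.
#' @export
flat_prior <- function(bounds = list(alpha_e = c(0.5, 60), beta_e = c(-1, 1),
                                     c_syn = c(-5, 5)))
  prior_spec("flat", bounds = bounds)

#' Gaussian summary of the source-task exercise posterior
#'
#' Moment-matched Gaussian over the exercise hyperparameter block learned in
#' the source (RCT/healthy) task: posterior means and diagonal posterior
#' variances of the group means of \code{alpha_e, beta_e} and, for the
#' synergistic model, \code{c_syn}.
#'
#' @param mu Posterior means.
#' @param sigma2 Posterior variances (diagonal), same order.
#' @param components Component names.
#' @return An object of class \code{"source_summary"}.
#' @export
source_summary <- function(mu, sigma2,
                           components = c("alpha_e", "beta_e", "c_syn")[seq_along(mu)]) {
  if (length(mu) != length(sigma2)) stop("mu and sigma2 lengths differ")
  if (!length(mu) %in% 2:3) stop("exercise block has 2 or 3 components")
  if (any(sigma2 <= 0)) stop("variances must be positive")
  structure(list(mu = stats::setNames(as.numeric(mu), components),
                 sigma2 = stats::setNames(as.numeric(sigma2), components)),
            class = "source_summary")
}

#' @export
print.source_summary <- function(x, ...) {
  cat("<source_summary> exercise-block Gaussian (posterior moments):\n")
  print(data.frame(mean = x$mu, var = x$sigma2))
  invisible(x)
}

#' Transfer-mode policy
#'
#' Specifies how the pretrained source distribution is rescaled into the
#' target-task prior. \code{"none"} ignores the source (flat priors);
#' \code{"normal"} uses the source Gaussian as-is, i.e. fixed \code{eta = 1},
#' \code{lambda = 1} (other fixed values may be supplied); \code{"extended"}
#' treats \code{eta} (mean shift) and \code{lambda} (variance shrink) as
#' latent with Gaussian hyperpriors -- mean 0.5 for the \code{beta_e}
#' component of \code{eta} (the diabetic-group glucose uptake of leg muscle is
#' about half the healthy group's), 1 for the others, and mean 0.1 for
#' \code{lambda}.
#'
#' @param mode \code{"none"}, \code{"normal"} or \code{"extended"}.
#' @param eta Fixed mean-shift vector used when \code{mode = "normal"}
#'   (default all 1); recycled to the block length.
#' @param lambda Fixed variance-shrink scalar when \code{mode = "normal"}
#'   (default 1).
#' @param eta_mean,eta_sd,lambda_mean,lambda_sd Hyperprior settings for
#'   \code{mode = "extended"}; \code{eta_mean = NULL} means the per-component
#'   defaults (1, with 0.5 for \code{beta_e}).
#' @return An object of class \code{"rescale_policy"}.
#' @export
rescale_policy <- function(mode = c("none", "normal", "extended"),
                           eta = 1, lambda = 1,
                           eta_mean = NULL, eta_sd = 0.25,
                           lambda_mean = 0.1, lambda_sd = 0.05) {
  mode <- match.arg(mode)
  if (mode == "normal" && (any(lambda <= 0) || length(lambda) != 1L))
    stop("lambda must be a positive scalar")
  structure(list(mode = mode, eta = eta, lambda = lambda, eta_mean = eta_mean,
                 eta_sd = eta_sd, lambda_mean = lambda_mean,
                 lambda_sd = lambda_sd),
            class = "rescale_policy")
}

#' Rescale the source posterior into the target-task prior
#'
#' Implements the shift-and-shrink prior rescaling: the target prior for the
#' exercise hyperparameter block is Gaussian with mean \code{eta * mu_S} and
#' variance \code{lambda * Sigma_S} (elementwise; \code{lambda} scalar). With
#' \code{mode = "none"} the source is ignored and flat priors are returned;
#' with \code{mode = "normal"} eta and lambda are fixed (unity by default);
#' with \code{mode = "extended"} they are latent and learned jointly with the
#' target-task parameters. Only the exercise block is ever transferred; the
#' diet-block priors are identical across all modes.
#'
#' @param source A [source_summary()] (may be \code{NULL} when
#'   \code{mode = "none"}).
#' @param policy A [rescale_policy()].
#' @return A \code{"prior_spec"} with a \code{provenance} attribute recording
#'   the policy and source moments.
#' @export
rescale_prior <- function(source, policy = rescale_policy("normal")) {
  stopifnot(inherits(policy, "rescale_policy"))
  if (policy$mode == "none") {
    out <- flat_prior()
  } else {
    stopifnot(inherits(source, "source_summary"))
    k <- length(source$mu)
    if (policy$mode == "normal") {
      eta <- rep_len(policy$eta, k)
      out <- prior_spec("gaussian", mu = eta * source$mu,
                        sigma2 = policy$lambda * source$sigma2)
      names(out$mu) <- names(out$sigma2) <- names(source$mu)
    } else {
      em <- policy$eta_mean
      if (is.null(em)) em <- ifelse(names(source$mu) == "beta_e", 0.5, 1)
      if (length(em) != k) stop("eta_mean length does not match source block")
      out <- prior_spec("extended", mu = source$mu, sigma2 = source$sigma2,
                        eta_mean = em, eta_sd = policy$eta_sd,
                        lambda_mean = policy$lambda_mean,
                        lambda_sd = policy$lambda_sd)
    }
  }
  attr(out, "provenance") <- list(
    policy = unclass(policy),
    source = if (is.null(source)) NULL else unclass(source))
  out
}
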