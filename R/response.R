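#' Person-specific response parameters
#'
#' Container for the parameters of one person's glucose response model:
#' response speeds (minutes), response strengths per unit dose, the synergy
#' weight and the observation-noise standard deviation.
#'
#' @param alpha_d Dietary response speed in minutes (> 0); the dietary
#'   response to a meal peaks \code{3 * alpha_d} minutes after meal start.
#' @param beta_d Dietary response strength, mmol/L per gram of carbohydrate.
#' @param alpha_e Exercise response speed in minutes (> 0); \code{NA} for the
#'   single (diet-only) model.
#' @param beta_e Exercise response strength, mmol/L per kcal of energy
#'   expenditure. Expected negative (exercise lowers glucose) but not
#'   constrained: the sign is learned, not imposed.
#' @param c_syn Dimensionless synergy weight on the elementwise product of the
#'   dietary and exercise responses; \code{NA} unless the model is synergistic.
#' @param sigma Observation noise standard deviation, mmol/L (> 0).
#' @return An object of class \code{"person_params"}.
#' @export
person_params <- function(alpha_d, beta_d, alpha_e = NA_real_,
                          beta_e = NA_real_, c_syn = NA_real_, sigma = 0.4) {
  if (!is.finite(alpha_d) || alpha_d <= 0) stop("alpha_d must be > 0")
  if (!is.na(alpha_e) && alpha_e <= 0) stop("alpha_e must be > 0")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  structure(list(alpha_d = alpha_d, beta_d = beta_d, alpha_e = alpha_e,
                 beta_e = beta_e, c_syn = c_syn, sigma = sigma),
            class = "person_params")
}

#' @export
print.person_params <- function(x, ...) {
  cat("Person-specific glucose response parameters:\n")
  v <- unlist(x)
  print(signif(v, 4))
  invisible(x)
}

#' Baseline glucose of a segment
#'
#' The baseline is the median of the preprandial glucose history (the 15
#' minutes up to and including meal start) and is treated as constant over the
#' 90-minute postprandial window.
#'
#' @param segment A segment as produced by [segment_sessions()].
#' @return Baseline glucose, mmol/L.
#' @export
baseline_glucose <- function(segment) {
  v <- segment$pre_values
  if (is.null(v) || length(v) == 0L)
    stop("segment has an empty preprandial window; it should have been excluded")
  stats::median(v)
}

#' Bell-shaped treatment response
#'
#' Sum of Gaussian-bell response terms, one per treatment event. Each term
#' peaks at height \code{h} a lag of \code{3 * alpha} minutes after its event
#' and is truncated to zero before the event (causality), so responses never
#' precede their treatment.
#'
#' @param alpha Response speed in minutes (> 0).
#' @param amplitudes Numeric vector of peak heights \code{h}, one per event
#'   (strength parameter times dose).
#' @param event_times Numeric vector of event start times (minutes), parallel
#'   to \code{amplitudes}.
#' @param grid Numeric vector of evaluation times (minutes).
#' @return Numeric vector of the summed response on \code{grid}.
#' @export
bell_response <- function(alpha, amplitudes, event_times, grid) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  if (length(amplitudes) != length(event_times))
    stop("amplitudes and event_times must have the same length")
  out <- numeric(length(grid))
  for (i in seq_along(amplitudes)) {
    delta <- grid - event_times[i]
    out <- out + ifelse(delta < 0, 0,
                        amplitudes[i] * exp(-0.5 * (delta - 3 * alpha)^2 / alpha^2))
  }
  out
}

#' Dietary response of a segment
#'
#' Bell response driven by the carbohydrate doses of all meals in the segment
#' window: each meal of \code{x} grams contributes a bell of height
#' \code{beta_d * x} peaking \code{3 * alpha_d} minutes after meal start.
#'
#' @inheritParams baseline_glucose
#' @param params A [person_params()] object.
#' @param grid Evaluation times (minutes, session clock); defaults to the
#'   segment's postprandial CGM grid.
#' @return Numeric response series, mmol/L.
#' @export
dietary_response <- function(params, segment, grid = segment$post_times) {
  m <- segment$meals
  if (is.null(m) || nrow(m) == 0L) return(numeric(length(grid)))
  bell_response(params$alpha_d, params$beta_d * m$carbs, m$time, grid)
}

#' Exercise response of a segment
#'
#' Bell response driven by the energy expenditure of exercise bouts in the
#' segment window, with height \code{beta_e * z} for a bout of \code{z} kcal.
#' Bouts starting before the meal still contribute at postprandial times
#' through their positive lag.
#'
#' @inheritParams dietary_response
#' @return Numeric response series, mmol/L.
#' @export
exercise_response <- function(params, segment, grid = segment$post_times) {
  e <- segment$exercises
  if (is.null(e) || nrow(e) == 0L) return(numeric(length(grid)))
  if (is.na(params$alpha_e) || is.na(params$beta_e))
    stop("params carry no exercise block (alpha_e/beta_e are NA)")
  bell_response(params$alpha_e, params$beta_e * e$ee, e$time, grid)
}

#' Noise-free predicted glucose trajectory for one segment
#'
#' Forward model: baseline plus dietary response (single), plus exercise
#' response (additive), plus the synergy term \code{c_syn * (R_d * R_e)}
#' (synergistic). Components are returned so the prediction can be decomposed.
#'
#' @inheritParams dietary_response
#' @param model_kind One of \code{"single"}, \code{"additive"},
#'   \code{"synergistic"}.
#' @return An object of class \code{"glucose_trajectory"}: list with
#'   \code{times}, \code{y_hat}, \code{y_base}, \code{r_diet},
#'   \code{r_exercise}, \code{synergy}.
#' @export
glucose_trajectory <- function(params, segment,
                               model_kind = c("single", "additive", "synergistic"),
                               grid = segment$post_times) {
  model_kind <- match.arg(model_kind)
  y_base <- baseline_glucose(segment)
  r_d <- dietary_response(params, segment, grid)
  r_e <- numeric(length(grid))
  syn <- numeric(length(grid))
  if (model_kind != "single") {
    r_e <- exercise_response(params, segment, grid)
    if (model_kind == "synergistic") {
      if (is.na(params$c_syn)) stop("synergistic model requires c_syn")
      syn <- params$c_syn * r_d * r_e
    }
  }
  structure(list(times = grid, y_hat = y_base + r_d + r_e + syn,
                 y_base = y_base, r_diet = r_d, r_exercise = r_e,
                 synergy = syn, model_kind = model_kind),
            class = "glucose_trajectory")
}

#' @export
print.glucose_trajectory <- function(x, ...) {
  cat(sprintf("Predicted postprandial trajectory (%s model), %d points\n",
              x$model_kind, length(x$times)))
  cat(sprintf("  baseline %.2f mmol/L, range [%.2f, %.2f]\n",
              x$y_base, min(x$y_hat), max(x$y_hat)))
  invisible(x)
}

#' Plot a predicted trajectory and its components
#'
#' Layered decomposition: observed postprandial samples (if the segment is
#' given), the predicted trajectory, and the baseline/diet/exercise layers.
#'
#' @param x A \code{"glucose_trajectory"}.
#' @param segment Optional segment supplying observed values.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.glucose_trajectory <- function(x, segment = NULL, ...) {
  ylim <- range(x$y_hat, x$y_base + x$r_diet,
                if (!is.null(segment)) segment$post_values)
  graphics::plot(x$times, x$y_hat, type = "l", lwd = 2, col = "deeppink3",
                 xlab = "time (min, session clock)", ylab = "glucose (mmol/L)",
                 ylim = ylim, ...)
  graphics::abline(h = x$y_base, lty = 3, col = "grey40")
  graphics::lines(x$times, x$y_base + x$r_diet, col = "pink3", lty = 2)
  if (any(x$r_exercise != 0))
    graphics::lines(x$times, x$y_base + x$r_exercise, col = "seagreen", lty = 2)
  if (!is.null(segment))
    graphics::points(segment$post_times, segment$post_values, pch = 16, cex = 0.7)
  invisible(x)
}

#' Serialize a trajectory to JSON
#'
#' @param x A \code{"glucose_trajectory"}.
#' @param path Optional file path; if \code{NULL} the JSON string is returned.
#' @export
trajectory_to_json <- function(x, path = NULL) {
  obj <- list(model_kind = x$model_kind, times = x$times, y_hat = x$y_hat,
              components = list(y_base = x$y_base, r_diet = x$r_diet,
                                r_exercise = x$r_exercise, synergy = x$synergy))
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
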