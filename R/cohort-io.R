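#' Assemble a cohort object from its three event tables
#'
#' A cohort bundles the per-person CGM stream with the meal and exercise event
#' logs for one study group. Times are integer minutes since session start on
#' a 5-minute grid.
#'
#' @param glucose data.frame with columns \code{person_id, session_id, day,
#'   time_min, glucose_mmol_l}.
#' @param meals data.frame with columns \code{person_id, session_id, time_min,
#'   carbs_g}.
#' @param exercises data.frame with columns \code{person_id, session_id,
#'   time_min, ee_kcal}.
#' @param group \code{"healthy"} or \code{"patient"}.
#' @param truth Optional list of generating parameters (synthetic cohorts).
#' @return An object of class \code{"glucose_cohort"}.
#' @export
glucose_cohort <- function(glucose, meals, exercises,
                           group = c("healthy", "patient"), truth = NULL) {
  group <- match.arg(group)
  need <- function(df, cols, name) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(sprintf("%s is missing columns: %s", name,
                                   paste(miss, collapse = ", ")))
  }
  need(glucose, c("person_id", "session_id", "day", "time_min", "glucose_mmol_l"),
       "glucose")
  need(meals, c("person_id", "session_id", "time_min", "carbs_g"), "meals")
  need(exercises, c("person_id", "session_id", "time_min", "ee_kcal"), "exercises")
  if (any(glucose$glucose_mmol_l <= 0)) stop("glucose values must be positive")
  if (any(meals$carbs_g < 0)) stop("carbohydrate intake must be nonnegative")
  if (any(exercises$ee_kcal < 0)) stop("energy expenditure must be nonnegative")
  o <- order(glucose$person_id, glucose$session_id, glucose$time_min)
  glucose <- glucose[o, , drop = FALSE]
  by_ps <- split(glucose$time_min,
                 paste(glucose$person_id, glucose$session_id, sep = "\r"))
  if (any(vapply(by_ps, function(tt) any(diff(tt) <= 0), logical(1))))
    stop("glucose sample times must be strictly increasing within a session")
  structure(list(glucose = glucose, meals = meals, exercises = exercises,
                 group = group, truth = truth),
            class = "glucose_cohort")
}

#' @export
print.glucose_cohort <- function(x, ...) {
  np <- length(unique(x$glucose$person_id))
  ns <- nrow(unique(x$glucose[, c("person_id", "session_id")]))
  cat(sprintf("<glucose_cohort> group=%s: %d persons, %d sessions, %d CGM samples, %d meals, %d exercise bouts\n",
              x$group, np, ns, nrow(x$glucose), nrow(x$meals), nrow(x$exercises)))
  invisible(x)
}

#' Read a cohort from its three CSV files
#'
#' Expects \code{glucose.csv}, \code{meals.csv} and \code{exercise.csv} in
#' \code{dir} (UTF-8, comma-separated, header row), plus an optional
#' \code{truth.json} written by the synthetic generator.
#'
#' @param dir Directory holding the CSV files.
#' @param group Study group of the cohort.
#' @return A \code{"glucose_cohort"}.
#' @export
read_cohort <- function(dir, group = c("healthy", "patient")) {
  group <- match.arg(group)
  rd <- function(f) utils::read.csv(file.path(dir, f), fileEncoding = "UTF-8")
  truth <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) truth <- jsonlite::fromJSON(tj, simplifyDataFrame = TRUE)
  glucose_cohort(rd("glucose.csv"), rd("meals.csv"), rd("exercise.csv"),
                 group = group, truth = truth)
}

#' Write a cohort to a directory as CSV (plus truth.json when synthetic)
#'
#' @param cohort A \code{"glucose_cohort"}.
#' @param dir Output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, f)
    utils::write.csv(df, file.path(dir, f), row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  wr(cohort$glucose, "glucose.csv")
  wr(cohort$meals, "meals.csv")
  wr(cohort$exercises, "exercise.csv")
  if (!is.null(cohort$truth))
    jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
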