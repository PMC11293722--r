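#' Meal-centered segmentation of CGM sessions
#'
#' Partitions each person-session stream into one segment per meal: the
#' preprandial window is the closed interval \code{[meal - 15, meal]} and the
#' postprandial target window the half-open \code{(meal, meal + 90]}, both on
#' the 5-minute CGM grid (up to 4 preprandial and exactly 18 postprandial
#' samples). A segment whose pre or post window misses any grid sample is
#' excluded; exclusions are counted, never imputed. Overlapping segments from
#' meals less than 90 minutes apart are all retained, each anchored at its own
#' meal, with later meals appearing in the earlier segment's meal list.
#'
#' @param cohort A \code{"glucose_cohort"}.
#' @param post_horizon Postprandial horizon T in minutes (default 90).
#' @param pre_span Preprandial history span in minutes (default 15).
#' @param grid_step CGM sampling interval in minutes (default 5).
#' @return An object of class \code{"segment_set"}: list of segments plus
#'   counts (\code{n_segments}, \code{n_persons}, \code{n_dropped}).
#' @export
segment_sessions <- function(cohort, post_horizon = 90, pre_span = 15,
                             grid_step = 5) {
  stopifnot(inherits(cohort, "glucose_cohort"))
  gl <- cohort$glucose
  if (nrow(gl) == 0L) stop("cohort contains no glucose samples")
  key <- function(df) paste(df$person_id, df$session_id, sep = "\r")
  gl_split <- split(gl, key(gl))
  meals_split <- split(cohort$meals, key(cohort$meals))
  ex_split <- split(cohort$exercises, key(cohort$exercises))

  grid_times <- function(from, to) {
    # grid points t with from <= t <= to and t divisible by grid_step
    lo <- ceiling(from / grid_step) * grid_step
    hi <- floor(to / grid_step) * grid_step
    if (lo > hi) return(numeric(0))
    seq(lo, hi, by = grid_step)
  }

  segments <- list()
  n_dropped <- 0L
  for (k in names(gl_split)) {
    g <- gl_split[[k]]
    ms <- meals_split[[k]]
    if (is.null(ms) || nrow(ms) == 0L) next
    ms <- ms[order(ms$time_min), , drop = FALSE]
    ex <- ex_split[[k]]
    tt <- g$time_min
    val <- g$glucose_mmol_l
    for (i in seq_len(nrow(ms))) {
      tau <- ms$time_min[i]
      pre_want <- grid_times(tau - pre_span, tau)
      post_want <- setdiff(grid_times(tau, tau + post_horizon), tau)
      pre_idx <- match(pre_want, tt)
      post_idx <- match(post_want, tt)
      if (length(post_want) == 0L || length(pre_want) == 0L ||
          anyNA(pre_idx) || anyNA(post_idx)) {
        n_dropped <- n_dropped + 1L
        next
      }
      in_meals <- ms[ms$time_min >= tau & ms$time_min <= tau + post_horizon, ,
                     drop = FALSE]
      in_ex <- if (is.null(ex)) NULL else
        ex[ex$time_min >= tau - pre_span & ex$time_min <= tau + post_horizon, ,
           drop = FALSE]
      seg_day <- g$day[max(which(tt <= tau))]
      segments[[length(segments) + 1L]] <- list(
        person_id = as.character(ms$person_id[i]),
        session_id = ms$session_id[i],
        day = seg_day,
        meal_time = tau,
        pre_times = pre_want, pre_values = val[pre_idx],
        post_times = post_want, post_values = val[post_idx],
        meals = data.frame(time = in_meals$time_min, carbs = in_meals$carbs_g),
        exercises = if (is.null(in_ex) || nrow(in_ex) == 0L)
          data.frame(time = numeric(0), ee = numeric(0))
        else data.frame(time = in_ex$time_min, ee = in_ex$ee_kcal),
        role = NA_character_)
    }
  }
  new_segment_set(segments, group = cohort$group, n_dropped = n_dropped)
}

new_segment_set <- function(segments, group, n_dropped = 0L) {
  structure(list(segments = segments, group = group,
                 n_segments = length(segments),
                 n_persons = length(unique(vapply(segments, `[[`, "", "person_id"))),
                 n_dropped = n_dropped),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  roles <- vapply(x$segments, `[[`, "", "role")
  cat(sprintf("<segment_set> group=%s: %d segments from %d persons (%d dropped)\n",
              x$group, x$n_segments, x$n_persons, x$n_dropped))
  if (!all(is.na(roles)))
    cat(sprintf("  roles: %d train, %d test\n",
                sum(roles == "train", na.rm = TRUE),
                sum(roles == "test", na.rm = TRUE)))
  nex <- sum(vapply(x$segments, is_exercise_segment, logical(1)))
  cat(sprintf("  postprandial-exercise segments (EE > 60 kcal): %d\n", nex))
  invisible(x)
}

#' Assign train/test roles by session day
#'
#' For free-living sessions the first \code{session_length_days - 1} days are
#' training data and the last day is test data, split within each session
#' (month), never across sessions; with the 3-day protocol this is days 1-2
#' train, day 3 test. Six-day RCT sessions are entirely training data: the
#' source task has no test role.
#'
#' @param segment_set A \code{"segment_set"} whose segments carry day indices.
#' @param session_length_days Length of each session in days (3 for the
#'   free-living protocol, 6 for the RCT).
#' @return The segment set with \code{role} filled in.
#' @export
split_train_test <- function(segment_set, session_length_days) {
  stopifnot(inherits(segment_set, "segment_set"))
  segment_set$segments <- lapply(segment_set$segments, function(s) {
    if (is.na(s$day) || s$day < 1 || s$day > session_length_days)
      stop(sprintf("segment day %s outside session length %d",
                   s$day, session_length_days))
    s$role <- if (session_length_days == 6) "train"
      else if (s$day < session_length_days) "train" else "test"
    s
  })
  segment_set
}

#' Is a segment a postprandial-exercise segment?
#'
#' True when the total energy expenditure of exercise bouts starting strictly
#' after the meal exceeds the threshold (60 kcal, read strictly: exactly 60 is
#' not an exercise segment). Preprandial bouts are not counted.
#'
#' @param segment A segment.
#' @param threshold_kcal EE threshold in kcal (default 60).
#' @return Logical scalar.
#' @export
is_exercise_segment <- function(segment, threshold_kcal = 60) {
  e <- segment$exercises
  if (is.null(e) || nrow(e) == 0L) return(FALSE)
  sum(e$ee[e$time > segment$meal_time]) > threshold_kcal
}

#' Subset a segment set by role
#'
#' @param segment_set A \code{"segment_set"}.
#' @param role \code{"train"} or \code{"test"}.
#' @return A \code{"segment_set"} with only the requested role.
#' @export
filter_role <- function(segment_set, role) {
  keep <- vapply(segment_set$segments, function(s) identical(s$role, role),
                 logical(1))
  new_segment_set(segment_set$segments[keep], group = segment_set$group,
                  n_dropped = segment_set$n_dropped)
}

#' Serialize segments to JSON lines
#'
#' One JSON object per line; round-trippable with [read_segments_jsonl()].
#'
#' @param segment_set A \code{"segment_set"}.
#' @param path Output file path.
#' @export
write_segments_jsonl <- function(segment_set, path) {
  lines <- vapply(segment_set$segments, function(s)
    as.character(jsonlite::toJSON(s, digits = NA, auto_unbox = TRUE,
                                  dataframe = "columns", null = "null")),
    character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_segments_jsonl
#' @param group Group label for the reconstructed set.
#' @export
read_segments_jsonl <- function(path, group = c("healthy", "patient")) {
  group <- match.arg(group)
  segs <- lapply(readLines(path), function(l) {
    s <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    s$meals <- as.data.frame(s$meals)
    s$exercises <- if (length(s$exercises$time) == 0L)
      data.frame(time = numeric(0), ee = numeric(0)) else as.data.frame(s$exercises)
    if (is.null(s$role)) s$role <- NA_character_
    s
  })
  new_segment_set(segs, group = group)
}
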