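#' Segment-level prediction error metrics
#'
#' Four errors over the postprandial grid: RMSE, MAE, the absolute difference
#' of the summed series (an AUC discrepancy on the 5-minute grid) and the
#' absolute difference of the postprandial maxima. The outer differences of
#' the AUC and maximum errors are taken in absolute value so the metrics are
#' nonnegative and averageable.
#'
#' @param y Observed postprandial series, mmol/L.
#' @param y_hat Predicted series on the same grid.
#' @return Named list: \code{rmse}, \code{mae}, \code{err_auc},
#'   \code{err_max}.
#' @export
segment_metrics <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("series lengths differ")
  if (length(y) == 0L) stop("empty series")
  d <- y - y_hat
  list(rmse = sqrt(mean(d^2)), mae = mean(abs(d)),
       err_auc = abs(sum(y) - sum(y_hat)),
       err_max = abs(max(y) - max(y_hat)))
}

#' Evaluate a fit on test segments
#'
#' Computes the four metrics for every segment using posterior-median plug-in
#' predictions and flags postprandial-exercise segments (EE > 60 kcal).
#'
#' @param fit A \code{"glucofit"} or \code{"transfer_fit"}.
#' @param test_segments A \code{"segment_set"}.
#' @return data.frame with one row per segment: person_id, exercise flag and
#'   the four metrics.
#' @export
evaluate_fit <- function(fit, test_segments) {
  if (inherits(fit, "transfer_fit")) fit <- fit$target_fit
  trajs <- predict(fit, test_segments)
  rows <- lapply(seq_along(trajs), function(i) {
    s <- test_segments$segments[[i]]
    m <- segment_metrics(s$post_values, trajs[[i]]$y_hat)
    data.frame(person_id = s$person_id, exercise = is_exercise_segment(s),
               rmse = m$rmse, mae = m$mae, err_auc = m$err_auc,
               err_max = m$err_max, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aggregate segment metrics by exercise stratum
#'
#' Mean and standard error (SD/sqrt(n)) of each metric, stratified by the
#' postprandial-exercise flag. A stratum with a single segment reports SE = 0
#' and is flagged; an empty stratum is absent from the output.
#'
#' @param metrics data.frame from [evaluate_fit()] (columns \code{exercise},
#'   \code{rmse}, \code{mae}, \code{err_auc}, \code{err_max}).
#' @return data.frame with one row per stratum: n, mean and SE per metric,
#'   and \code{se_degenerate} when n = 1.
#' @export
aggregate_metrics <- function(metrics) {
  if (nrow(metrics) == 0L) stop("no segment metrics to aggregate")
  out <- lapply(split(metrics, metrics$exercise), function(g) {
    n <- nrow(g)
    se <- function(v) if (n > 1) stats::sd(v) / sqrt(n) else 0
    data.frame(stratum = if (g$exercise[1]) "with_exercise" else "without_exercise",
               n = n,
               rmse_mean = mean(g$rmse), rmse_se = se(g$rmse),
               mae_mean = mean(g$mae), mae_se = se(g$mae),
               err_auc_mean = mean(g$err_auc), err_auc_se = se(g$err_auc),
               err_max_mean = mean(g$err_max), err_max_se = se(g$err_max),
               se_degenerate = n == 1L, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(-as.integer(res$stratum == "with_exercise")), , drop = FALSE]
}

# The seven model x transfer configurations compared in the evaluation.
model_configurations <- function() {
  data.frame(
    config = c("Mbase", "Madd", "Msyn", "Madd+trans", "Msyn+trans",
               "Madd+trans_ext", "Msyn+trans_ext"),
    model_kind = c("single", "additive", "synergistic", "additive",
                   "synergistic", "additive", "synergistic"),
    transfer = c("none", "none", "none", "normal", "normal",
                 "extended", "extended"),
    stringsAsFactors = FALSE)
}

#' Run the model-by-transfer comparison
#'
#' Fits the requested configurations (the full set is the single model plus
#' the additive and synergistic models each with no, normal and extended
#' transfer), evaluates each on the patient test segments, and reports the
#' exercise-stratified mean and standard error of every metric. Source fits
#' are shared across configurations with the same model kind.
#'
#' @param rct_train Healthy-group training segments (needed by transfer
#'   configurations).
#' @param patient_segments Patient \code{"segment_set"} with roles assigned.
#' @param configs Character vector of configuration names; default all seven.
#' @param control Sampler settings for target fits.
#' @param control_source Sampler settings for source fits.
#' @param quiet Suppress progress messages.
#' @return An object of class \code{"metric_report"}: data.frame of per-config
#'   per-stratum aggregates, with the per-segment metrics in
#'   \code{attr(, "per_segment")}.
#' @export
run_comparison <- function(rct_train, patient_segments,
                           configs = model_configurations()$config,
                           control = sampler_control(),
                           control_source = control, quiet = TRUE) {
  all_cfg <- model_configurations()
  bad <- setdiff(configs, all_cfg$config)
  if (length(bad)) stop("unknown configurations: ", paste(bad, collapse = ", "))
  cfg <- all_cfg[match(configs, all_cfg$config), ]
  train <- filter_role(patient_segments, "train")
  test <- filter_role(patient_segments, "test")
  if (test$n_segments == 0L) stop("patient segments contain no test role")
  source_fits <- list()
  report <- NULL
  per_seg <- NULL
  for (i in seq_len(nrow(cfg))) {
    mk <- cfg$model_kind[i]; tr <- cfg$transfer[i]
    if (!quiet) message("fitting ", cfg$config[i])
    if (tr == "none") {
      fit <- fit_target_task(train, mk, prior = flat_prior(),
                             control = control)
    } else {
      if (is.null(source_fits[[mk]]))
        source_fits[[mk]] <- fit_source_task(rct_train, mk,
                                             control = control_source)
      fit <- run_transfer_pipeline(rct_train, train, mk,
                                   policy = rescale_policy(tr),
                                   control = control,
                                   source = source_fits[[mk]])
    }
    m <- evaluate_fit(fit, test)
    m$config <- cfg$config[i]
    per_seg <- rbind(per_seg, m)
    agg <- aggregate_metrics(m)
    agg <- cbind(config = cfg$config[i], agg)
    report <- rbind(report, agg)
  }
  rownames(report) <- NULL
  structure(report, per_segment = per_seg, class = c("metric_report",
                                                     class(report)))
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Average metric scores by configuration and exercise stratum (mean, SE):\n")
  df <- as.data.frame(x)
  df$rmse <- sprintf("%.3f (+/-%.3f)", df$rmse_mean, df$rmse_se)
  df$mae <- sprintf("%.3f (+/-%.3f)", df$mae_mean, df$mae_se)
  df$err_auc <- sprintf("%.2f (+/-%.2f)", df$err_auc_mean, df$err_auc_se)
  df$err_max <- sprintf("%.3f (+/-%.3f)", df$err_max_mean, df$err_max_se)
  print(df[, c("config", "stratum", "n", "rmse", "mae", "err_auc", "err_max")],
        row.names = FALSE)
  invisible(x)
}

#' Write a metric report to CSV and JSON
#'
#' @param report A \code{"metric_report"}.
#' @param path_csv,path_json Output paths (either may be \code{NULL}).
#' @export
write_metric_report <- function(report, path_csv = NULL, path_json = NULL) {
  df <- as.data.frame(report)
  if (!is.null(path_csv))
    utils::write.csv(df, path_csv, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(df, path_json, digits = NA, dataframe = "rows",
                         pretty = TRUE)
  invisible(report)
}
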