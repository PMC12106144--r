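#' Per-day prediction errors for a windowed dataset
#'
#' One mean-absolute-error entry per labeled day: the mean over the t
#' activities of the absolute gap between predicted and actual dedication.
#'
#' @param predictor a trained predictor.
#' @param data a non-empty `windowed_dataset`.
#' @return data.frame with `user`, `day`, `error` (percent units).
#' @export
compute_error_vector <- function(predictor, data) {
  if (n_samples(data) == 0) stop("empty dataset")
  pred <- stats::predict(predictor, data)
  data.frame(user = data$user, day = data$label_day,
             error = rowMeans(abs(pred - data$y)),
             stringsAsFactors = FALSE)
}

#' Fit the Gaussian model of prediction errors
#'
#' The error population is summarized by its mean and population-form
#' standard deviation (denominator n, not n - 1); the detection threshold Z
#' is the standard-normal quantile at the chosen p-value, so with p = 0.95
#' about 5% of in-distribution days exceed it.
#'
#' @param errors data.frame from [compute_error_vector()] or a numeric vector.
#' @param p_value tail probability in (0, 1); default 0.925.
#' @return A `normal_error_model` with `mu`, `sigma`, `p_value`, `Z`.
#' @export
fit_error_model <- function(errors, p_value = 0.925) {
  stopifnot(p_value > 0, p_value < 1)
  e <- if (is.data.frame(errors)) errors$error else as.numeric(errors)
  if (length(e) < 2) stop("need at least 2 errors")
  mu <- mean(e)
  sigma <- sqrt(mean((e - mu)^2))
  if (sigma == 0) stop("degenerate error distribution: all errors identical")
  structure(list(mu = mu, sigma = sigma, p_value = p_value,
                 Z = stats::qnorm(p_value), n = length(e)),
            class = "normal_error_model")
}

#' @export
print.normal_error_model <- function(x, ...) {
  cat(sprintf("Error model: mu %.4f, sigma %.4f (n = %d); p = %.3f -> Z = %.4f\n",
              x$mu, x$sigma, x$n, x$p_value, x$Z))
  invisible(x)
}

#' Step 1: flag days whose error z-score exceeds the threshold
#'
#' One-sided: a day is flagged when `(error - mu) / sigma > Z`, strictly.
#' Unusually small errors are never flagged.
#'
#' @param errors data.frame from [compute_error_vector()].
#' @param model a [fit_error_model()] fit.
#' @return The flagged subset of `errors`, with a `z` column.
#' @export
step1_flag <- function(errors, model) {
  z <- (errors$error - model$mu) / model$sigma
  out <- errors[z > model$Z, , drop = FALSE]
  out$z <- z[z > model$Z]
  rownames(out) <- NULL
  out
}

#' Per-activity boxplot-whisker limits
#'
#' For each activity, quartiles of the dedication distribution over all rows
#' of the reference table (type-7 linear interpolation between order
#' statistics) define the whiskers `upper = Q3 + 1.5 * IQR` and
#' `lower = Q1 - 1.5 * IQR`. Zero-dedication days are included.
#'
#' @param reference a `dedication_table` with at least 4 rows.
#' @return An `activity_limits` data.frame: `activity`, `q1`, `q3`, `lower`,
#'   `upper`.
#' @export
compute_activity_limits <- function(reference) {
  if (nrow(reference) == 0) stop("empty reference table")
  if (nrow(reference) < 4) stop("need at least 4 reference rows for quartiles")
  m <- dedication_matrix(reference)
  q <- apply(m, 2, stats::quantile, probs = c(0.25, 0.75), type = 7,
             names = FALSE)
  iqr <- q[2, ] - q[1, ]
  structure(data.frame(activity = activity_names(reference),
                       q1 = q[1, ], q3 = q[2, ],
                       lower = q[1, ] - 1.5 * iqr,
                       upper = q[2, ] + 1.5 * iqr,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("activity_limits", "data.frame"))
}

#' Step 2: which activities of a day violate the whisker limits
#'
#' Strict inequalities: a dedication exactly at a limit is not deviated.
#'
#' @param day either a named dedication vector or a one-row
#'   `dedication_table` slice.
#' @param limits an [compute_activity_limits()] result.
#' @return data.frame of deviated activities: `activity`, `dedication`,
#'   `direction` ("over"/"under"), `limit` (the violated whisker).
#' @export
explain_day <- function(day, limits) {
  ded <- if (is.data.frame(day)) {
    unlist(day[1, limits$activity, drop = FALSE])
  } else day[limits$activity]
  if (anyNA(ded)) stop("day vector does not cover the limits' vocabulary")
  over <- ded > limits$upper
  under <- ded < limits$lower
  out <- rbind(
    data.frame(activity = limits$activity[over],
               dedication = unname(ded[over]),
               direction = rep("over", sum(over)),
               limit = limits$upper[over], stringsAsFactors = FALSE),
    data.frame(activity = limits$activity[under],
               dedication = unname(ded[under]),
               direction = rep("under", sum(under)),
               limit = limits$lower[under], stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out[order(match(out$activity, limits$activity)), , drop = FALSE]
}

#' Two-step anomaly detection with explanations
#'
#' Step 1 flags days whose next-day prediction error is a z-score outlier;
#' step 2 keeps only flagged days in which at least one activity's dedication
#' lies outside its population boxplot whiskers, and reports those activities
#' as the explanation. Days passing step 1 but with no deviated activity are
#' discarded, so the final set is always a subset of the step-1 flags.
#'
#' @param predictor a trained next-day predictor.
#' @param data `windowed_dataset` of the days to screen.
#' @param reference `dedication_table` defining the normal population for
#'   both the error model and the whiskers (typically the training subset, to
#'   avoid test leakage; pass the pooled table to mirror a fit on all data).
#' @param p_value step-1 tail probability (default 0.925).
#' @param reference_windows optional `windowed_dataset` over `reference` used
#'   to fit the error model; defaults to `data` itself when omitted (i.e.,
#'   errors are standardized against the screened set).
#' @param error_model optionally, a pre-fitted [fit_error_model()].
#' @return An `anomaly_report`: list with `reports` (one element per anomalous
#'   day: user, day, day_ordinal, z, deviated data.frame), `flagged_step1`,
#'   `limits`, `model`, and `summary` (count, mean deviated activities,
#'   fraction with >= 3).
#' @export
detect_anomalies <- function(predictor, data, reference, p_value = 0.925,
                             reference_windows = NULL, error_model = NULL) {
  errors <- compute_error_vector(predictor, data)
  if (is.null(error_model)) {
    ref_err <- if (is.null(reference_windows)) errors
               else compute_error_vector(predictor, reference_windows)
    error_model <- fit_error_model(ref_err, p_value)
  }
  flagged <- step1_flag(errors, error_model)
  limits <- compute_activity_limits(reference)
  df <- as.data.frame(data$y)
  # per-user ordinal of each labeled day within the screened set
  ord_all <- stats::ave(as.numeric(data$label_day), data$user,
                        FUN = function(x) rank(x, ties.method = "first"))
  reports <- list()
  if (nrow(flagged) > 0) {
    for (i in seq_len(nrow(flagged))) {
      idx <- which(data$user == flagged$user[i] &
                     data$label_day == flagged$day[i])[1]
      deviated <- explain_day(data$y[idx, ], limits)
      if (nrow(deviated) == 0) next
      reports[[length(reports) + 1]] <- list(
        user = flagged$user[i], day = flagged$day[i],
        day_ordinal = ord_all[idx], z = flagged$z[i], deviated = deviated)
    }
  }
  ord <- order(vapply(reports, function(r) r$user, ""),
               as.Date(vapply(reports, function(r) as.character(r$day), "")))
  reports <- reports[ord]
  n_dev <- vapply(reports, function(r) nrow(r$deviated), 0)
  structure(list(
    reports = reports, flagged_step1 = flagged, limits = limits,
    model = error_model,
    summary = list(
      n_step1 = nrow(flagged), n_anomalies = length(reports),
      mean_deviated = if (length(reports)) mean(n_dev) else NA_real_,
      frac_three_plus = if (length(reports)) mean(n_dev >= 3) else NA_real_)),
    class = "anomaly_report")
}

#' @export
print.anomaly_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Two-step anomaly report: %d step-1 flags -> %d anomalies\n",
              s$n_step1, s$n_anomalies))
  if (s$n_anomalies > 0) {
    cat(sprintf("  mean deviated activities %.2f; %.0f%% with >= 3\n",
                s$mean_deviated, 100 * s$frac_three_plus))
  }
  invisible(x)
}

#' Write an anomaly report as CSV (one row per deviated activity)
#'
#' Columns `user,day_id,activity,dedication,description`, with description
#' text "Dedication over the X%" / "Dedication under the X%".
#'
#' @param report an `anomaly_report`.
#' @param path output CSV path.
#' @export
write_anomaly_csv <- function(report, path) {
  rows <- lapply(report$reports, function(r) {
    data.frame(user = r$user, day_id = r$day_ordinal,
               day = format(r$day, "%Y-%m-%d"),
               activity = r$deviated$activity,
               dedication = sprintf("%.2f%%", r$deviated$dedication),
               description = sprintf("Dedication %s the %.2f%%",
                                     r$deviated$direction, r$deviated$limit),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(user = character(), day_id = numeric(), day = character(),
               activity = character(), dedication = character(),
               description = character())
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an anomaly report as JSON (machine-readable, with z-scores/limits)
#' @param report an `anomaly_report`.
#' @param path output JSON path.
#' @export
write_anomaly_json <- function(report, path) {
  payload <- list(
    error_model = list(mu = report$model$mu, sigma = report$model$sigma,
                       p_value = report$model$p_value, Z = report$model$Z),
    summary = report$summary,
    anomalies = lapply(report$reports, function(r) {
      list(user = r$user, day = format(r$day, "%Y-%m-%d"),
           day_id = r$day_ordinal, z = r$z, deviated = r$deviated)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
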