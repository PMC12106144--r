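#' Read a CASAS-style labeled sensor-event log
#'
#' Each non-empty line carries five whitespace- or TAB-separated tokens:
#' date, time of day (with sub-second precision), sensor identifier, sensor
#' value, and the recognized activity label. Malformed lines are skipped with
#' a single warning reporting the count.
#'
#' @param path path to the event log.
#' @param user user identifier attached to the returned events.
#' @return data.frame with columns `timestamp` (POSIXct, sub-second),
#'   `sensor_id`, `value`, `activity`, in file order, with attributes `user`
#'   and `n_malformed`.
#' @export
read_casas_events <- function(path, user) {
  if (!file.exists(path)) stop("cannot read event log: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    ev <- data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                     sensor_id = character(), value = character(),
                     activity = character(), stringsAsFactors = FALSE)
    attr(ev, "user") <- user
    attr(ev, "n_malformed") <- 0L
    return(ev)
  }
  toks <- strsplit(lines, "[ \t]+")
  ok <- vapply(toks, length, 0L) >= 5L
  ts <- rep(as.POSIXct(NA), length(lines))
  ts[ok] <- as.POSIXct(
    vapply(toks[ok], function(x) paste(x[1], x[2]), ""),
    format = "%Y-%m-%d %H:%M:%OS", tz = "UTC")
  ok <- ok & !is.na(ts)
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    warning(sprintf("skipped %d malformed line(s) in %s", n_bad, path))
  }
  toks <- toks[ok]
  ev <- data.frame(
    timestamp = ts[ok],
    sensor_id = vapply(toks, `[`, "", 3L),
    value = vapply(toks, `[`, "", 4L),
    activity = vapply(toks, function(x) paste(x[-(1:4)], collapse = "_"), ""),
    stringsAsFactors = FALSE)
  attr(ev, "user") <- user
  attr(ev, "n_malformed") <- n_bad
  ev
}

#' Merge consecutive identically-labeled events into activity intervals
#'
#' Sensor events are instantaneous readings; the recognized activity persists
#' until the label changes. A maximal run of identical consecutive labels
#' becomes one interval. By default a run ends at the *next* run's first event
#' (half-open coverage, which tiles the observed span without gaps); the final
#' run ends at its own last event. `end_rule = "last_event"` instead ends every
#' run at its own last event.
#'
#' @param events data.frame as returned by [read_casas_events()].
#' @param user user identifier for the intervals.
#' @param end_rule `"next_start"` (default) or `"last_event"`.
#' @return data.frame with columns `user`, `activity`, `start`, `end`,
#'   `duration_s`; non-overlapping and ordered by start.
#' @export
merge_consecutive_runs <- function(events, user,
                                   end_rule = c("next_start", "last_event")) {
  end_rule <- match.arg(end_rule)
  empty <- data.frame(user = character(), activity = character(),
                      start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      duration_s = numeric(), stringsAsFactors = FALSE)
  if (nrow(events) == 0) return(empty)
  ord <- order(events$timestamp)  # stable; defensive re-sort
  ts <- events$timestamp[ord]
  act <- events$activity[ord]
  r <- rle(act)
  run_end_idx <- cumsum(r$lengths)
  run_start_idx <- run_end_idx - r$lengths + 1L
  start <- ts[run_start_idx]
  end <- if (end_rule == "next_start") {
    c(ts[run_start_idx[-1]], ts[run_end_idx[length(run_end_idx)]])
  } else {
    ts[run_end_idx]
  }
  data.frame(user = user, activity = r$values, start = start, end = end,
             duration_s = as.numeric(difftime(end, start, units = "secs")),
             stringsAsFactors = FALSE)
}

#' Split activity intervals at civil midnight
#'
#' Intervals crossing 00:00:00 are cut into per-day pieces whose durations sum
#' to the original, so every output interval lies within one calendar day.
#' Timestamps are treated as naive local time; no timezone or DST handling.
#'
#' @param intervals data.frame from [merge_consecutive_runs()].
#' @return data.frame with the same columns, no interval crossing a day
#'   boundary.
#' @export
split_intervals_at_midnight <- function(intervals) {
  if (nrow(intervals) == 0) return(intervals)
  pieces <- vector("list", nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]
    e <- intervals$end[i]
    d0 <- as.Date(s, tz = "UTC")
    d1 <- as.Date(e, tz = "UTC")
    if (d0 == d1) {
      pieces[[i]] <- intervals[i, , drop = FALSE]
      next
    }
    cuts <- as.POSIXct(paste(seq(d0 + 1, d1, by = "day"), "00:00:00"),
                       tz = "UTC")
    bounds <- c(s, cuts, e)
    # a piece ending exactly at midnight belongs to the earlier day
    keep <- which(diff(as.numeric(bounds)) > 0)
    pieces[[i]] <- data.frame(
      user = intervals$user[i], activity = intervals$activity[i],
      start = bounds[keep], end = bounds[keep + 1L],
      duration_s = as.numeric(bounds[keep + 1L]) - as.numeric(bounds[keep]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# Calendar day a day-framed interval belongs to: its start day.
.interval_day <- function(intervals) as.Date(intervals$start, tz = "UTC")

#' Aggregate day-framed intervals into daily dedication percentages
#'
#' For every (user, day, activity) the summed interval seconds are converted
#' to a percentage of the fixed 86,400-second day. Days inside a user's
#' observation range with no intervals become rows of zeros. The first and
#' last observed calendar day per user are dropped by default, since they are
#' usually only partially covered by the sensor log.
#'
#' @param intervals day-framed intervals (see [split_intervals_at_midnight()]).
#' @param activity_names activity vocabulary defining the column order; by
#'   default the union of observed labels, sorted lexicographically.
#' @param drop_boundary_days drop each user's first and last calendar day.
#' @return A [dedication_table()].
#' @export
compute_daily_dedication <- function(intervals, activity_names = NULL,
                                     drop_boundary_days = TRUE) {
  if (nrow(intervals) == 0) stop("no intervals to aggregate")
  if (any(intervals$duration_s < 0)) {
    stop("negative interval duration: corrupt input")
  }
  if (is.null(activity_names)) {
    # radix sort: locale-independent lexicographic vocabulary order
    activity_names <- sort(unique(intervals$activity), method = "radix")
  }
  day <- .interval_day(intervals)
  users <- sort(unique(intervals$user))
  rows <- list()
  for (u in users) {
    sel <- intervals$user == u
    d <- day[sel]
    all_days <- seq(min(d), max(d), by = "day")
    if (drop_boundary_days && length(all_days) > 2) {
      all_days <- all_days[-c(1, length(all_days))]
    } else if (drop_boundary_days) {
      next  # fewer than 3 observed days: nothing survives boundary dropping
    }
    keep <- sel & day %in% all_days
    mat <- matrix(0, nrow = length(all_days), ncol = length(activity_names),
                  dimnames = list(NULL, activity_names))
    if (any(keep)) {
      agg <- stats::aggregate(
        duration_s ~ dd + activity,
        data = data.frame(dd = as.character(day[keep]),
                          activity = intervals$activity[keep],
                          duration_s = intervals$duration_s[keep]),
        FUN = sum)
      known <- agg$activity %in% activity_names
      agg <- agg[known, , drop = FALSE]
      ri <- match(as.Date(agg$dd), all_days)
      ci <- match(agg$activity, activity_names)
      mat[cbind(ri, ci)] <- 100 * agg$duration_s / 86400
    }
    rows[[u]] <- data.frame(user = u, day = all_days, mat,
                            check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no complete days after boundary dropping")
  dedication_table(do.call(rbind, rows), activity_names)
}

#' Remove one activity column from a dedication table
#'
#' Used to discard the catch-all label (conventionally `Other_Activity`),
#' which has no predictable structure. Remaining values are untouched — no
#' renormalization — so a day's total may drop below 100.
#'
#' @param table a `dedication_table`.
#' @param label activity column to remove (must exist).
#' @return The table without that column.
#' @export
drop_activity <- function(table, label = "Other_Activity") {
  acts <- activity_names(table)
  if (!label %in% acts) stop("unknown activity label: ", label)
  keep <- setdiff(acts, label)
  df <- as.data.frame(table)[, c("user", "day", keep), drop = FALSE]
  dedication_table(df, keep)
}

#' Per-activity mean and standard deviation of dedication
#'
#' Summaries over all user-days, on the percentage scale; the standard
#' deviation uses the population form (denominator n).
#'
#' @param table a non-empty `dedication_table`.
#' @return data.frame with columns `activity`, `mean`, `sd`, ordered by
#'   decreasing mean.
#' @export
summarize_activities <- function(table) {
  if (nrow(table) == 0) stop("empty dedication table")
  m <- dedication_matrix(table)
  mu <- colMeans(m)
  sd_pop <- sqrt(colMeans(sweep(m, 2, mu)^2))
  out <- data.frame(activity = activity_names(table), mean = mu, sd = sd_pop,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$mean), ]
}

#' Full ingest pipeline: event logs to a dedication table
#'
#' Reads one log per user, merges runs, frames intervals within calendar days,
#' aggregates to daily dedication percentages over a global activity
#' vocabulary (union of labels across users, sorted lexicographically), and
#' optionally removes the catch-all activity.
#'
#' @param paths named character vector: `names(paths)` are user ids, values
#'   are log file paths.
#' @param drop_other drop the `Other_Activity` column after aggregation.
#' @param drop_boundary_days see [compute_daily_dedication()].
#' @param end_rule see [merge_consecutive_runs()].
#' @return A [dedication_table()].
#' @export
ingest_casas <- function(paths, drop_other = TRUE, drop_boundary_days = TRUE,
                         end_rule = "next_start") {
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    stop("`paths` must be named by user id")
  }
  per_user <- lapply(names(paths), function(u) {
    ev <- read_casas_events(paths[[u]], u)
    split_intervals_at_midnight(
      merge_consecutive_runs(ev, u, end_rule = end_rule))
  })
  intervals <- do.call(rbind, per_user)
  vocab <- sort(unique(intervals$activity), method = "radix")
  table <- compute_daily_dedication(intervals, vocab,
                                    drop_boundary_days = drop_boundary_days)
  if (drop_other && "Other_Activity" %in% vocab) {
    table <- drop_activity(table, "Other_Activity")
  }
  table
}
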