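#' Construct a dedication table
#'
#' A dedication table is the package's central container: one row per
#' (user, day) with the percentage of that calendar day dedicated to each
#' recognized activity. Values live in \[0, 100\] and a day's total over all
#' activities (including any catch-all label) never exceeds 100.
#'
#' @param df data.frame with columns `user` (character), `day` (`Date`) and
#'   one numeric column per activity.
#' @param activity_names character vector naming the activity columns, in the
#'   fixed column order shared by all rows.
#' @return A `dedication_table` (a data.frame subclass carrying the
#'   `activity_names` attribute).
#' @export
dedication_table <- function(df, activity_names) {
  stopifnot(is.data.frame(df), all(c("user", "day") %in% names(df)))
  activity_names <- as.character(activity_names)
  missing_cols <- setdiff(activity_names, names(df))
  if (length(missing_cols) > 0) {
    stop("dedication table lacks activity columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[, c("user", "day", activity_names), drop = FALSE]
  df$user <- as.character(df$user)
  df$day <- as.Date(df$day)
  if (anyDuplicated(df[, c("user", "day")])) {
    stop("duplicate (user, day) rows in dedication table")
  }
  vals <- as.matrix(df[, activity_names, drop = FALSE])
  if (length(vals) > 0) {
    if (any(!is.finite(vals))) stop("non-finite dedication values")
    if (any(vals < -1e-9) || any(vals > 100 + 1e-9)) {
      stop("dedication values must lie in [0, 100]")
    }
  }
  df <- df[order(df$user, df$day), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            activity_names = activity_names,
            class = c("dedication_table", "data.frame"))
}

#' Activity vocabulary of a dedication table
#' @param table a `dedication_table`.
#' @return Character vector of activity column names, in column order.
#' @export
activity_names <- function(table) attr(table, "activity_names")

#' Dedication values as a numeric matrix
#' @param table a `dedication_table`.
#' @return Numeric matrix, one row per (user, day), columns the activities.
#' @export
dedication_matrix <- function(table) {
  as.matrix(as.data.frame(table)[, activity_names(table), drop = FALSE])
}

#' @export
print.dedication_table <- function(x, ...) {
  cat(sprintf("Dedication table: %d user-days, %d users, %d activities\n",
              nrow(x), length(unique(x$user)), length(activity_names(x))))
  NextMethod()
}

#' Write a dedication table to CSV
#'
#' Layout: header `user,day,<activity...>`, ISO-8601 dates, percentages
#' rounded to 2 decimals on output (internal computations keep full
#' precision).
#'
#' @param table a `dedication_table`.
#' @param path output file path.
#' @param digits decimal places written; `NA` writes full precision.
#' @export
write_dedication_csv <- function(table, path, digits = 2) {
  out <- as.data.frame(table)
  acts <- activity_names(table)
  if (!is.na(digits)) out[acts] <- round(out[acts], digits)
  out$day <- format(out$day, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dedication table from CSV
#'
#' @param path CSV with header `user,day,<activity...>` as written by
#'   [write_dedication_csv()].
#' @return A `dedication_table`.
#' @export
read_dedication_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  acts <- setdiff(names(df), c("user", "day"))
  df$day <- as.Date(df$day)
  dedication_table(df, acts)
}
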