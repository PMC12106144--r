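#' Per-user chronological train/test split
#'
#' For each user with m days, the first `floor(train_fraction * m)` days go to
#' the training table and the rest to the test table, so both subsets contain
#' every user and the test set follows the train set in time. Users with fewer
#' than 2 days are excluded with a warning.
#'
#' @param table a `dedication_table` (per-user days sorted, enforced by the
#'   container).
#' @param train_fraction fraction of each user's days used for training,
#'   strictly between 0 and 1 (default 0.7).
#' @return list with `train` and `test` dedication tables.
#' @export
chronological_split <- function(table, train_fraction = 0.7) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  acts <- activity_names(table)
  df <- as.data.frame(table)
  counts <- table(df$user)
  tiny <- names(counts)[counts < 2]
  if (length(tiny) > 0) {
    warning("excluding user(s) with < 2 days: ", paste(tiny, collapse = ", "))
    df <- df[!df$user %in% tiny, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no users with >= 2 days")
  in_train <- unlist(lapply(split(seq_len(nrow(df)), df$user), function(idx) {
    m <- length(idx)
    n_train <- floor(train_fraction * m)
    seq_along(idx) <= n_train
  }), use.names = FALSE)
  # split() orders groups by user, matching the table's own ordering
  list(train = dedication_table(df[in_train, , drop = FALSE], acts),
       test = dedication_table(df[!in_train, , drop = FALSE], acts))
}

#' Build a sliding-window supervised dataset
#'
#' A window of `w` consecutive days slides one day at a time over each user's
#' series: the first `w - 1` days form the input block (oldest first) and day
#' `w` the label. A user with m consecutive days yields `max(0, m - w + 1)`
#' samples. By default windows never span a gap of missing calendar days (the
#' window restarts after a gap); `allow_gaps = TRUE` treats rows as consecutive
#' regardless of dates.
#'
#' @param table a `dedication_table`.
#' @param w window size, at least 2.
#' @param allow_gaps treat each user's rows as consecutive even across
#'   calendar gaps.
#' @return A `windowed_dataset`: list with `x` (n x (w-1) x t array), `y`
#'   (n x t matrix), `user`, `label_day`, `w`, `activity_names`.
#' @export
make_windows <- function(table, w, allow_gaps = FALSE) {
  if (!is.numeric(w) || w < 2) stop("window size w must be >= 2")
  w <- as.integer(w)
  acts <- activity_names(table)
  t_n <- length(acts)
  df <- as.data.frame(table)
  mat <- dedication_matrix(table)
  xs <- list(); ys <- list(); us <- character(); ld <- as.Date(character())
  for (idx in split(seq_len(nrow(df)), df$user)) {
    days <- df$day[idx]
    seg_id <- if (allow_gaps) rep(1L, length(idx)) else
      cumsum(c(1L, as.integer(diff(days) != 1)))
    for (seg in split(idx, seg_id)) {
      m <- length(seg)
      if (m < w) next
      for (s in seq_len(m - w + 1L)) {
        rows <- seg[s:(s + w - 1L)]
        xs[[length(xs) + 1L]] <- mat[rows[seq_len(w - 1L)], , drop = FALSE]
        ys[[length(ys) + 1L]] <- mat[rows[w], ]
        us <- c(us, df$user[rows[w]])
        ld <- c(ld, df$day[rows[w]])
      }
    }
  }
  n <- length(xs)
  x <- array(0, dim = c(n, w - 1L, t_n))
  if (n > 0) for (i in seq_len(n)) x[i, , ] <- xs[[i]]
  y <- if (n > 0) do.call(rbind, ys) else matrix(0, 0, t_n)
  colnames(y) <- acts
  structure(list(x = x, y = y, user = us, label_day = ld, w = w,
                 activity_names = acts),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("Windowed dataset: %d samples, w = %d (%d input days), %d activities\n",
              nrow(x$y), x$w, x$w - 1L, length(x$activity_names)))
  invisible(x)
}

#' Number of samples in a windowed dataset
#' @param dataset a `windowed_dataset`.
#' @return Integer sample count.
#' @export
n_samples <- function(dataset) nrow(dataset$y)

# Subset a windowed dataset by sample index (internal).
subset_windows <- function(dataset, idx) {
  structure(list(x = dataset$x[idx, , , drop = FALSE],
                 y = dataset$y[idx, , drop = FALSE],
                 user = dataset$user[idx],
                 label_day = dataset$label_day[idx],
                 w = dataset$w, activity_names = dataset$activity_names),
            class = "windowed_dataset")
}
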