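# Independent brute-force oracles and tiny fixture builders shared by tests.
# These deliberately re-derive quantities from first principles (explicit
# loops, textbook formulas) so they stay independent of the package's
# vectorized implementations.

brute_zscores <- function(e) {
  mu <- sum(e) / length(e)
  sigma <- sqrt(sum((e - mu)^2) / length(e))
  (e - mu) / sigma
}

# linear interpolation between closest order statistics (type-7 convention)
brute_quantile7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

brute_whiskers <- function(x) {
  q1 <- brute_quantile7(x, 0.25)
  q3 <- brute_quantile7(x, 0.75)
  c(lower = q1 - 1.5 * (q3 - q1), upper = q3 + 1.5 * (q3 - q1))
}

# direct-formula mean silhouette width, O(n^2) loops
brute_silhouette <- function(feats, labels) {
  n <- nrow(feats)
  d <- as.matrix(stats::dist(feats))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(d[i, labels == cl])
    }, 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# enumerate sliding windows over per-user day sequences by hand
brute_window_count <- function(days_per_user, w) {
  sum(vapply(days_per_user,
             function(m) max(0, as.numeric(m) - as.numeric(w) + 1), 0))
}

# small dedication table with named activities, values recycled row-wise
tiny_table <- function(values, activities = c("Sleep", "Watch_TV", "Cook"),
                       n_users = 1, n_days = nrow(values)) {
  stopifnot(is.matrix(values), ncol(values) == length(activities))
  rows <- do.call(rbind, lapply(seq_len(n_users), function(u) {
    data.frame(user = sprintf("u%02d", u),
               day = as.Date("2020-01-01") + seq_len(nrow(values)) - 1,
               values, check.names = FALSE, stringsAsFactors = FALSE)
  }))
  names(rows)[-(1:2)] <- activities
  dedication_table(rows, activities)
}

# a constant-label windowed dataset (predictable optimum) for model tests
constant_windows <- function(n = 12, w = 3, t = 4, value = 10) {
  tab <- tiny_table(matrix(value, n, t),
                    activities = paste0("A", seq_len(t)))
  make_windows(tab, w)
}

write_event_lines <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}
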