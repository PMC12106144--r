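ts <- function(day, secs) as.POSIXct(paste(day, "00:00:00"), tz = "UTC") + secs

events_df <- function(secs, labels, day = "2012-09-05") {
  data.frame(timestamp = ts(day, secs),
             sensor_id = rep("Bedroom", length(secs)),
             value = rep("ON", length(secs)), activity = labels,
             stringsAsFactors = FALSE)
}

test_that("event logs parse with sub-second timestamps and file order", {
  path <- write_event_lines(c(
    "2012-09-05 15:57:02.665670 Bedroom OFF Dress",
    "2012-09-05 15:57:03.428454 Ignore 61 Other_Activity",
    "2012-09-05 15:57:09.633537 Bathroom ON Personal_Hygiene"))
  ev <- read_casas_events(path, "csh101")
  expect_equal(nrow(ev), 3)
  expect_equal(ev$sensor_id, c("Bedroom", "Ignore", "Bathroom"))
  expect_equal(ev$value, c("OFF", "61", "ON"))
  expect_equal(ev$activity, c("Dress", "Other_Activity", "Personal_Hygiene"))
  expect_equal(as.numeric(ev$timestamp[1]) %% 60, 2.665670, tolerance = 1e-6)
  expect_equal(attr(ev, "user"), "csh101")
})

test_that("empty and malformed logs are handled", {
  empty <- write_event_lines(character(0))
  ev <- read_casas_events(empty, "u")
  expect_equal(nrow(ev), 0)

  mixed <- write_event_lines(c(
    "2012-09-05 15:57:02.1 Bedroom OFF Dress",
    "2012-09-05 15:57:03.2 Bedroom ON Dress",
    "2012-09-05 15:57:04.3",                   # truncated
    "2012-09-05 15:57:05.4 Bathroom ON Bathe"))
  expect_warning(ev <- read_casas_events(mixed, "u"), "1 malformed")
  expect_equal(nrow(ev), 3)
  expect_equal(attr(ev, "n_malformed"), 1L)

  expect_error(read_casas_events(tempfile(), "u"), "cannot read")
})

test_that("consecutive identical labels merge into half-open runs", {
  ev <- events_df(0:4, c("Dress", "Dress", "Other", "Other", "Hygiene"))
  iv <- merge_consecutive_runs(ev, "u")
  expect_equal(iv$activity, c("Dress", "Other", "Hygiene"))
  expect_equal(iv$duration_s, c(2, 2, 0))
  expect_equal(as.numeric(iv$start - iv$start[1]), c(0, 2, 4))

  # interleaving restarts the run each time the label changes
  ev2 <- events_df(0:5, c("Hyg", "Oth", "Hyg", "Oth", "Hyg", "Oth"))
  iv2 <- merge_consecutive_runs(ev2, "u")
  expect_equal(sum(iv2$activity == "Hyg"), 3)

  # single event: one zero-duration interval
  iv3 <- merge_consecutive_runs(events_df(0, "Sleep"), "u")
  expect_equal(iv3$duration_s, 0)

  # last-event end rule
  iv4 <- merge_consecutive_runs(ev, "u", end_rule = "last_event")
  expect_equal(iv4$duration_s, c(1, 1, 0))

  expect_equal(nrow(merge_consecutive_runs(events_df(numeric(0), character(0)), "u")), 0)
})

test_that("merging alternating-label sequences is idempotent", {
  set.seed(42)
  labs <- sample(c("A", "B", "C"), 50, replace = TRUE)
  ev <- events_df(seq_along(labs), labs)
  iv <- merge_consecutive_runs(ev, "u")
  # feed run starts back in as events: same intervals again
  ev2 <- data.frame(timestamp = iv$start, sensor_id = "s", value = "v",
                    activity = iv$activity)
  iv2 <- merge_consecutive_runs(ev2, "u")
  expect_equal(iv2$activity, iv$activity)
  expect_equal(iv2$start, iv$start)
})

test_that("midnight splitting conserves duration and never crosses days", {
  iv <- data.frame(user = "u", activity = "Sleep",
                   start = ts("2020-01-01", 23 * 3600),
                   end = ts("2020-01-02", 7 * 3600),
                   duration_s = 8 * 3600)
  sp <- split_intervals_at_midnight(iv)
  expect_equal(nrow(sp), 2)
  expect_equal(sp$duration_s, c(3600, 7 * 3600))
  expect_equal(sum(sp$duration_s), iv$duration_s)

  inside <- data.frame(user = "u", activity = "Nap",
                       start = ts("2020-01-01", 100),
                       end = ts("2020-01-01", 200), duration_s = 100)
  expect_equal(split_intervals_at_midnight(inside), inside)

  span3 <- data.frame(user = "u", activity = "Away",
                      start = ts("2020-01-01", 10 * 3600),
                      end = ts("2020-01-03", 5 * 3600),
                      duration_s = 2 * 86400 - 5 * 3600)
  sp3 <- split_intervals_at_midnight(span3)
  expect_equal(nrow(sp3), 3)
  expect_equal(sum(sp3$duration_s), span3$duration_s, tolerance = 1e-6)
  expect_true(all(as.Date(sp3$start, tz = "UTC") ==
                    as.Date(sp3$end - 1e-3, tz = "UTC")))
})

test_that("daily dedication is percent of the fixed 86,400 s day", {
  iv <- data.frame(
    user = "u", activity = c("Sleep", "Sleep", "Cook"),
    start = c(ts("2020-01-02", 0), ts("2020-01-03", 1000), ts("2020-01-03", 40000)),
    end = c(ts("2020-01-03", 0), ts("2020-01-03", 1000 + 27216),
            ts("2020-01-03", 41000)),
    duration_s = c(86400, 27216, 1000))
  # pad with boundary days so day 2 and 3 survive the default dropping
  pad <- data.frame(user = "u", activity = "Other",
                    start = c(ts("2020-01-01", 0), ts("2020-01-04", 0)),
                    end = c(ts("2020-01-01", 10), ts("2020-01-04", 10)),
                    duration_s = 10)
  tab <- compute_daily_dedication(rbind(iv, pad))
  m <- dedication_matrix(tab)
  expect_equal(unname(m[1, "Sleep"]), 100)          # full-day coverage
  expect_equal(unname(m[2, "Sleep"]), 31.5)         # 27216 / 86400 * 100
  expect_equal(unname(m[2, "Cook"]), 1000 / 864)
  expect_equal(unname(m[1, "Cook"]), 0)             # absent activity is 0

  # an uncovered day inside the range becomes a row of zeros
  gap <- data.frame(user = "u", activity = "Eat",
                    start = c(ts("2020-01-01", 0), ts("2020-01-05", 0)),
                    end = c(ts("2020-01-01", 100), ts("2020-01-05", 100)),
                    duration_s = 100)
  tab2 <- compute_daily_dedication(gap, drop_boundary_days = FALSE)
  expect_equal(nrow(tab2), 5)
  expect_true(all(dedication_matrix(tab2)[2:4, ] == 0))

  bad <- data.frame(user = "u", activity = "X", start = ts("2020-01-01", 10),
                    end = ts("2020-01-01", 0), duration_s = -10)
  expect_error(compute_daily_dedication(bad), "negative")
})

test_that("dropping an activity removes its column and nothing else", {
  tab <- tiny_table(matrix(c(30, 5, 2, 40, 8, 1), 2, 3, byrow = TRUE),
                    activities = c("Sleep", "Other_Activity", "Cook"))
  before <- rowSums(dedication_matrix(tab))
  dropped <- drop_activity(tab, "Other_Activity")
  expect_equal(activity_names(dropped), c("Sleep", "Cook"))
  expect_equal(dedication_matrix(dropped),
               dedication_matrix(tab)[, c("Sleep", "Cook")])
  expect_equal(before - rowSums(dedication_matrix(dropped)),
               dedication_matrix(tab)[, "Other_Activity"])
  expect_error(drop_activity(tab, "Nope"), "unknown")
})

test_that("activity summaries use population-form spread", {
  tab <- tiny_table(matrix(c(10, 10, 0, 20), 2, 2),
                    activities = c("A", "B"))
  s <- summarize_activities(tab)
  expect_equal(s$mean[s$activity == "A"], 10)
  expect_equal(s$sd[s$activity == "A"], 0)
  expect_equal(s$mean[s$activity == "B"], 10)
  expect_equal(s$sd[s$activity == "B"], 10)  # population denominator
})

test_that("dedication CSV round-trips through write/read", {
  tab <- tiny_table(matrix(runif(12, 0, 30), 4, 3))
  path <- tempfile(fileext = ".csv")
  write_dedication_csv(tab, path, digits = NA)
  back <- read_dedication_csv(path)
  expect_equal(activity_names(back), activity_names(tab))
  expect_equal(dedication_matrix(back), dedication_matrix(tab),
               tolerance = 1e-12)
  expect_equal(back$day, tab$day)
})
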