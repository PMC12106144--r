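# Synthetic smart-home routine generator. Populations of daily dedication
# vectors with known structure: archetype base profiles, per-user random
# effects, weekday/weekend modulation, and independently controllable
# per-activity logit-normal day noise (so zero noise reproduces the latent
# means exactly and dispersions can differ per activity). Days are clipped
# and rescaled so the total over all activities never exceeds 100.

.casas_activity_names <- function() {
  c("Bathe", "Bed_Toilet_Transition", "Caregiver", "Cook", "Cook_Breakfast",
    "Cook_Dinner", "Cook_Lunch", "Dress", "Drink", "Drug_Management",
    "Eat", "Eat_Breakfast", "Eat_Dinner", "Eat_Lunch", "Enter_Home",
    "Entertain_Guests", "Evening_Meds", "Exercise", "Go_To_Sleep", "Groom",
    "Housekeeping", "Laundry", "Leave_Home", "Make_Bed", "Morning_Meds",
    "Nap", "Paramedics", "Personal_Hygiene", "Phone", "Read", "Relax",
    "Shop", "Sleep", "Sleep_Out_Of_Bed", "Step_Out", "Take_Medicine",
    "Toilet", "Wash_Dishes", "Watch_TV", "Work", "Work_At_Table")
}

#' Default population archetypes for the routine simulator
#'
#' Three archetypes over 41 activity labels, emulating the scale of a real
#' single-resident smart-home corpus: a dominant Sleep block (~31% of the
#' day), a heavy-tailed spread of small activities, weekend modulation of
#' social/work activities, and heterogeneous per-activity noise.
#'
#' @return list of `archetype` lists with fields `name`, `base_dedication`
#'   (named percent vector), `weekend_multiplier` (named), `noise_scale`
#'   (named, logit-scale standard deviations).
#' @export
default_archetypes <- function() {
  acts <- .casas_activity_names()
  base <- stats::setNames(rep(0.4, length(acts)), acts)
  base[c("Sleep", "Watch_TV", "Relax", "Eat", "Cook", "Work",
         "Personal_Hygiene", "Toilet", "Read", "Nap",
         "Entertain_Guests", "Housekeeping")] <-
    c(31, 7.5, 5, 2.5, 2, 4, 1.5, 1.2, 1.3, 1.5, 0.8, 1.5)
  wk <- stats::setNames(rep(1, length(acts)), acts)
  wk[c("Work", "Work_At_Table")] <- 0.3
  wk[c("Entertain_Guests", "Relax", "Watch_TV", "Sleep")] <-
    c(2.5, 1.3, 1.2, 1.08)
  ns <- stats::setNames(rep(0.35, length(acts)), acts)
  ns[c("Sleep", "Watch_TV")] <- c(0.20, 0.45)
  ns[c("Entertain_Guests", "Exercise", "Shop")] <- 0.55
  tweak <- function(name, changes, noise = ns) {
    b <- base
    b[names(changes)] <- changes
    list(name = name, base_dedication = b, weekend_multiplier = wk,
         noise_scale = noise)
  }
  list(
    tweak("homebody", c(Sleep = 33, Watch_TV = 10, Work = 1, Relax = 6)),
    tweak("worker", c(Sleep = 29, Work = 9, Watch_TV = 5, Relax = 3.5)),
    tweak("social", c(Sleep = 30, Entertain_Guests = 3, Shop = 1.5,
                      Watch_TV = 6)))
}

.validate_archetype <- function(a) {
  for (mult in list(a$weekend_multiplier, a$weekend_multiplier * 0 + 1)) {
    tot <- sum(a$base_dedication * mult)
    if (tot > 100) {
      stop("infeasible archetype '", a$name, "': modulated total ", round(tot, 1),
           " exceeds 100")
    }
  }
  if (any(a$base_dedication < 0)) stop("negative base dedication")
}

#' Simulate a population of daily routines
#'
#' Each user is assigned an archetype (round-robin) and a multiplicative
#' lognormal random effect per activity; each day's latent mean is the user
#' profile scaled by the weekday/weekend multiplier, and the realized
#' dedication applies logit-normal noise per activity (zero noise returns the
#' latent mean exactly). Days whose total would exceed 100 are rescaled onto
#' the simplex boundary.
#'
#' @param n_users,n_days population size; defaults mirror a 30-home,
#'   ~75-day corpus.
#' @param archetypes list from [default_archetypes()] or compatible.
#' @param seed integer seed; the whole population is reproducible.
#' @param start_day first calendar day (a Monday by default so weekly
#'   structure is aligned).
#' @param user_sd standard deviation of the log-scale user random effect.
#' @return list with `table` (a [dedication_table()]) and `manifest` (per-user
#'   archetype, user base profiles, latent per-day means, noise scales, seed).
#' @export
simulate_population <- function(n_users = 30, n_days = 75,
                                archetypes = default_archetypes(),
                                seed = 1L,
                                start_day = as.Date("2012-01-02"),
                                user_sd = 0.15) {
  stopifnot(n_users >= 1, n_days >= 1)
  lapply(archetypes, .validate_archetype)
  acts <- names(archetypes[[1]]$base_dedication)
  t_n <- length(acts)
  set.seed(seed)
  users <- sprintf("syn%03d", seq_len(n_users))
  arch_idx <- rep_len(seq_along(archetypes), n_users)
  days <- start_day + seq_len(n_days) - 1
  weekend <- format(days, "%u") %in% c("6", "7")
  rows <- vector("list", n_users)
  latent <- vector("list", n_users)
  user_base <- matrix(0, n_users, t_n, dimnames = list(users, acts))
  rescaled <- 0L
  for (ui in seq_len(n_users)) {
    a <- archetypes[[arch_idx[ui]]]
    ub <- a$base_dedication * exp(stats::rnorm(t_n, 0, user_sd))
    # keep the user's worst-case modulated total inside the day budget
    worst <- max(sum(ub), sum(ub * a$weekend_multiplier))
    if (worst > 97) ub <- ub * 97 / worst
    user_base[ui, ] <- ub
    mu_days <- matrix(0, n_days, t_n, dimnames = list(NULL, acts))
    val_days <- mu_days
    for (di in seq_len(n_days)) {
      mu <- ub * (if (weekend[di]) a$weekend_multiplier else 1)
      mu <- pmin(mu, 100)
      eps <- stats::rnorm(t_n, 0, a$noise_scale)
      v <- ifelse(mu <= 0, 0,
                  100 * stats::plogis(stats::qlogis(mu / 100) + eps))
      if (sum(v) > 100) { v <- v * 100 / sum(v); rescaled <- rescaled + 1L }
      mu_days[di, ] <- mu
      val_days[di, ] <- v
    }
    latent[[ui]] <- mu_days
    rows[[ui]] <- data.frame(user = users[ui], day = days, val_days,
                             check.names = FALSE, stringsAsFactors = FALSE)
  }
  table <- dedication_table(do.call(rbind, rows), acts)
  manifest <- list(seed = seed, n_users = n_users, n_days = n_days,
                   users = users,
                   archetype = vapply(archetypes, function(a) a$name,
                                      "")[arch_idx],
                   user_base = user_base, latent_means = latent,
                   noise_scale = do.call(
                     rbind, lapply(archetypes[arch_idx],
                                   function(a) a$noise_scale)),
                   n_days_rescaled = rescaled, start_day = start_day)
  list(table = table, manifest = manifest)
}

#' Inject ground-truth anomalies into a dedication table
#'
#' Applies additive per-activity shifts to the listed (user, day) targets; all
#' other rows are returned bit-identical. With a `donor` activity, the shifted
#' time is stolen from the donor so the day total is conserved (the donor is
#' floored at 0, in which case the remainder is unbalanced).
#'
#' @param table a `dedication_table`.
#' @param injections data.frame with columns `user`, `day`, `activity`,
#'   `shift` (percent points, may be negative) and optionally `donor`
#'   (activity name or NA).
#' @param seed unused by the deterministic shifts; kept for interface
#'   stability with randomized injection helpers.
#' @return list with `table` (perturbed) and `truth` (data.frame of distinct
#'   injected user-days).
#' @export
inject_anomalies <- function(table, injections, seed = NULL) {
  acts <- activity_names(table)
  df <- as.data.frame(table)
  if (nrow(injections) > 0) {
    for (i in seq_len(nrow(injections))) {
      r <- which(df$user == injections$user[i] &
                   df$day == as.Date(injections$day[i]))
      if (length(r) != 1) {
        stop("injection target not in table: ", injections$user[i], " ",
             injections$day[i])
      }
      act <- injections$activity[i]
      if (!act %in% acts) stop("unknown activity in injection: ", act)
      new_val <- df[r, act] + injections$shift[i]
      if (new_val < -1e-9 || new_val > 100 + 1e-9) {
        stop("injection drives ", act, " out of [0, 100]")
      }
      df[r, act] <- min(max(new_val, 0), 100)
      donor <- if ("donor" %in% names(injections)) injections$donor[i] else NA
      if (!is.na(donor)) {
        if (!donor %in% acts) stop("unknown donor activity: ", donor)
        df[r, donor] <- max(df[r, donor] - injections$shift[i], 0)
      }
      tot <- sum(df[r, acts])
      if (tot > 100 + 1e-9) {
        others <- setdiff(acts, c(act, donor))
        excess <- tot - 100
        pool <- sum(df[r, others])
        if (pool < excess) stop("injection leaves no room in the day budget")
        df[r, others] <- df[r, others] * (pool - excess) / pool
      }
    }
  }
  truth <- unique(data.frame(user = as.character(injections$user),
                             day = as.Date(injections$day),
                             stringsAsFactors = FALSE))
  list(table = dedication_table(df, acts), truth = truth)
}

#' Construct gross injections that exceed both detector thresholds
#'
#' Picks `n` distinct (user, day) targets and, for each, forces several
#' activities far above their population upper whiskers (computed on the
#' clean table), shrinking the remaining activities to respect the 100% day
#' budget. The perturbation is large by construction: each marked activity
#' lands at least `margin` points above its whisker, and the total absolute
#' change is big enough to spike the day's prediction error.
#'
#' @param table the clean `dedication_table`.
#' @param n number of anomalous days to create.
#' @param seed seed for target selection.
#' @param activities activities to force upward (must exist in the table).
#' @param margin percent points above the upper whisker.
#' @param eligible optional data.frame (user, day) restricting targets (e.g.,
#'   to days that will actually be screened after windowing).
#' @return data.frame of injections suitable for [inject_anomalies()].
#' @export
gross_injections <- function(table, n, seed = 1L,
                             activities = c("Entertain_Guests",
                                            "Sleep_Out_Of_Bed", "Watch_TV"),
                             margin = 15, eligible = NULL) {
  acts <- activity_names(table)
  stopifnot(all(activities %in% acts))
  limits <- compute_activity_limits(table)
  upper <- stats::setNames(limits$upper, limits$activity)
  target_vals <- upper[activities] + margin
  if (sum(target_vals) > 95) {
    target_vals <- pmax(upper[activities] + 1,
                        target_vals * 95 / sum(target_vals))
  }
  df <- as.data.frame(table)
  pool <- df[, c("user", "day")]
  if (!is.null(eligible)) {
    key <- paste(pool$user, pool$day)
    pool <- pool[key %in% paste(eligible$user, as.Date(eligible$day)), ,
                 drop = FALSE]
  }
  if (nrow(pool) < n) stop("not enough eligible days for ", n, " injections")
  set.seed(seed)
  picks <- pool[sample.int(nrow(pool), n), , drop = FALSE]
  rows <- lapply(seq_len(n), function(i) {
    r <- which(df$user == picks$user[i] & df$day == picks$day[i])
    data.frame(user = picks$user[i], day = picks$day[i],
               activity = activities,
               shift = as.numeric(target_vals - unlist(df[r, activities])),
               donor = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Emit a CASAS-format event stream realizing a dedication table
#'
#' The inverse of the ingest pipeline: per (user, day) each activity with
#' positive dedication becomes one timestamped episode (events carry the
#' activity label), unused time is emitted as `Other_Activity`, and the
#' merged-run dedications recovered by ingest reproduce the table to within
#' 0.01 percentage points per cell.
#'
#' @param table a `dedication_table`.
#' @param dir output directory; one `<user>.txt` log per user.
#' @param seed seed for episode ordering and sensor tokens.
#' @return named character vector of log paths (names are user ids), suitable
#'   for [ingest_casas()].
#' @export
emit_event_stream <- function(table, dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  acts <- activity_names(table)
  sensors <- c("Bedroom", "Kitchen", "Bathroom", "LivingRoom", "Ignore")
  df <- as.data.frame(table)
  paths <- character(0)
  fmt_event <- function(day, sec, activity) {
    sprintf("%s %02d:%02d:%09.6f %s %s %s",
            format(day, "%Y-%m-%d"),
            sec %/% 3600, (sec %% 3600) %/% 60, sec %% 60,
            sample(sensors, 1), sample(c("ON", "OFF"), 1), activity)
  }
  for (u in unique(df$user)) {
    sub <- df[df$user == u, , drop = FALSE]
    lines <- character(0)
    for (r in seq_len(nrow(sub))) {
      day <- sub$day[r]
      ded <- unlist(sub[r, acts])
      present <- acts[ded > 0]
      dur <- ded[ded > 0] * 864  # percent -> seconds of the 86,400 s day
      ord <- sample(seq_along(present))
      present <- present[ord]; dur <- dur[ord]
      slack <- 86400 - sum(dur)
      sec <- 0
      for (j in seq_along(present)) {
        lines <- c(lines, fmt_event(day, sec, present[j]))
        if (dur[j] > 120) {  # mid-episode event exercises run merging
          lines <- c(lines, fmt_event(day, sec + 60, present[j]))
        }
        sec <- sec + dur[j]
      }
      if (slack > 1e-9) {
        lines <- c(lines, fmt_event(day, sec, "Other_Activity"))
      }
      if (r == nrow(sub)) {
        # terminal sentinel: the final run must end at its own last event
        last_label <- if (slack > 1e-9) "Other_Activity"
                      else present[length(present)]
        lines <- c(lines, fmt_event(day, 86399.999, last_label))
      }
    }
    path <- file.path(dir, paste0(u, ".txt"))
    writeLines(lines, path)
    paths[u] <- path
  }
  paths
}

#' Write a simulation scenario to a YAML config
#' @param scenario list with `n_users`, `n_days`, `seed`, optional
#'   `archetypes` and `injections`.
#' @param path output YAML path.
#' @export
write_scenario <- function(scenario, path) {
  enc <- scenario
  if (!is.null(enc$injections)) {
    enc$injections$day <- as.character(enc$injections$day)
    enc$injections <- lapply(seq_len(nrow(enc$injections)),
                             function(i) as.list(enc$injections[i, ]))
  }
  yaml::write_yaml(enc, path)
  invisible(path)
}

#' Read a simulation scenario from YAML
#' @param path YAML written by [write_scenario()].
#' @return scenario list with `injections` restored as a data.frame.
#' @export
read_scenario <- function(path) {
  sc <- yaml::read_yaml(path)
  if (!is.null(sc$injections)) {
    sc$injections <- do.call(rbind, lapply(sc$injections, function(r) {
      data.frame(user = r$user, day = as.Date(r$day), activity = r$activity,
                 shift = r$shift,
                 donor = if (is.null(r$donor)) NA_character_ else r$donor,
                 stringsAsFactors = FALSE)
    }))
  }
  sc
}
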