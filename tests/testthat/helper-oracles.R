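# Independent oracles used across the suite.  These re-derive the model's
# behaviour by literal rule application on a minute grid, written without
# reference to the package's closed-form implementation.

# Literal episode-by-episode application of the new-day rules:
# (a) spans a calendar-day boundary, or (b) starts on/after the day following
# the previous new-day sleep's end day; first episode always new-day.
oracle_classify <- function(sched) {
  n <- nrow(sched)
  kind <- character(n)
  prev_nd_end_day <- NA_integer_
  for (i in seq_len(n)) {
    d_start <- sched$start[i] %/% 1440L
    d_end <- sched$end[i] %/% 1440L
    nd <- (i == 1L) || (d_start < d_end) ||
      (!is.na(prev_nd_end_day) && d_start >= prev_nd_end_day + 1L)
    kind[i] <- if (nd) "newday" else "nap"
    if (nd) prev_nd_end_day <- d_end
  }
  kind
}

# Effective sleep per new-day sleep: own duration plus every nap since the
# previous new-day sleep.
oracle_gammas <- function(sched, kind) {
  nd <- which(kind == "newday")
  vapply(seq_along(nd), function(k) {
    i <- nd[k]
    prev <- if (k == 1L) 0L else nd[k - 1L]
    naps <- which(kind == "nap" & seq_len(nrow(sched)) > prev &
                    seq_len(nrow(sched)) < i)
    sum(sched$end[i] - sched$start[i], sched$end[naps] - sched$start[naps])
  }, 0)
}

# Minute-by-minute walk over [first wake, horizon): per-minute status
# ("asleep", "excluded", "tl") and a TL accumulated one slope-increment per
# elapsed minute since the covering new-day wake (reset there to
# max(threshold - gamma, 0)).  TL keeps rising through nap minutes -- the
# worked example's onset falls inside a nap -- but those minutes report
# "asleep" and the 28-h clock restarts at the end of any episode.
oracle_minute_grid <- function(sched, params = tiredness_params(),
                               horizon = NULL) {
  kind <- oracle_classify(sched)
  gammas <- oracle_gammas(sched, kind)
  nd <- which(kind == "newday")
  wake_times <- sched$end[nd]
  if (is.null(horizon)) horizon <- max(sched$end) + params$max_awake
  t0 <- wake_times[1L]
  mins <- seq.int(t0, horizon - 1L)
  status <- character(length(mins))
  tl <- rep(NA_real_, length(mins))
  cur_tl <- NA_real_
  last_sleep_end <- t0   # first wake ends a sleep
  next_reset <- 1L
  for (j in seq_along(mins)) {
    t <- mins[j]
    while (next_reset <= length(wake_times) && t == wake_times[next_reset]) {
      cur_tl <- max(params$threshold_tl - gammas[next_reset], 0)
      next_reset <- next_reset + 1L
    }
    asleep <- any(t >= sched$start & t < sched$end)
    if (asleep) {
      status[j] <- "asleep"
      ends_now <- sched$end[sched$start <= t & t < sched$end]
      last_sleep_end <- max(last_sleep_end, ends_now)
    } else if (t - last_sleep_end >= params$max_awake) {
      status[j] <- "excluded"
    } else {
      status[j] <- "tl"
      tl[j] <- cur_tl
    }
    cur_tl <- cur_tl + params$slope
  }
  data.frame(minute = mins, status = status, tl = tl)
}

# Random small schedule: episodes drawn over a few days, overlaps merged the
# same way a device-export reader would (interval union).
make_random_schedule <- function(seed, max_episodes = 6L, days = 3L) {
  set.seed(seed)
  k <- sample.int(max_episodes, 1L)
  base <- as.integer(parse_minute("2015-10-05T00:00"))
  start <- sort(base + sample.int(days * 1440L, k))
  dur <- sample(30:540, k, replace = TRUE)
  keep_s <- integer(); keep_e <- integer()
  last_end <- -Inf
  for (i in seq_len(k)) {      # drop overlapping draws to keep episodes clean
    if (start[i] >= last_end) {
      keep_s <- c(keep_s, start[i]); keep_e <- c(keep_e, start[i] + dur[i])
      last_end <- start[i] + dur[i]
    }
  }
  new_schedule("rs", data.frame(start = keep_s, end = keep_e))
}

# A schedule + posts with a constructed awake gap of `gap_hours` between the
# first wake and the second sleep.
make_gap_fixture <- function(gap_hours) {
  wake <- parse_minute("2015-10-05T08:00")
  sched <- new_schedule("g1", data.frame(
    start = c(parse_minute("2015-10-05T01:00"), wake + gap_hours * 60L),
    end = c(wake, wake + gap_hours * 60L + 420L)))
  post_min <- seq(wake, wake + gap_hours * 60L - 1L, by = 30L)
  posts <- data.frame(post_id = sprintf("gp%03d", seq_along(post_min)),
                      subject_id = "g1", timestamp = post_min,
                      text = "tired again tonight", stringsAsFactors = FALSE)
  list(schedule = sched, posts = posts, wake = wake,
       next_sleep = wake + gap_hours * 60L)
}

example_sleep_path <- function()
  system.file("extdata", "example_sleep.csv", package = "sleepdep")
example_posts_path <- function()
  system.file("extdata", "example_posts.csv", package = "sleepdep")
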