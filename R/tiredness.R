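#' Tiredness-model parameters
#'
#' The tiredness level (TL) is a piecewise-linear latent state: after each
#' new-day sleep it restarts at `max(threshold_tl - gamma, 0)` (gamma = the
#' effective sleep minutes credited to that sleep) and rises linearly at
#' `slope` TL units per awake minute.  A subject is sleep deprived while
#' TL >= `threshold_tl`.  With the defaults, a fully rested subject (gamma >=
#' 360 min, i.e. 6 h) reaches the threshold after exactly 960 awake minutes
#' (16 h), and the slope is 360/960 = 3/8.
#'
#' @param threshold_tl TL value at which sleep deprivation begins (default
#'   360, the minute count of the 6-h deprivation definition).
#' @param hours_to_sld_rested awake minutes from a fully rested wake to
#'   deprivation onset (default 960 = 16 h).
#' @param min_sleep minutes of sleep per day below which a subject is sleep
#'   deprived (default 360 = 6 h).
#' @param max_awake maximum plausible awake stretch in minutes (default
#'   1680 = 28 h); staying awake longer is treated as sensor missingness and
#'   the surplus time is excluded.
#' @return a `tiredness_params` list with the above fields plus the implied
#'   `slope` (`threshold_tl / hours_to_sld_rested`).
#' @examples
#' p <- tiredness_params()
#' p$slope            # 3/8 TL per minute
#' initial_tl(240, p) # 120
#' @export
tiredness_params <- function(threshold_tl = 360, hours_to_sld_rested = 960,
                             min_sleep = 360, max_awake = 1680) {
  stopifnot(threshold_tl > 0, hours_to_sld_rested > 0,
            min_sleep > 0, max_awake > 0)
  structure(list(threshold_tl = threshold_tl,
                 slope = threshold_tl / hours_to_sld_rested,
                 min_sleep = min_sleep,
                 hours_to_sld_rested = hours_to_sld_rested,
                 max_awake = max_awake),
            class = "tiredness_params")
}

#' Classify sleep episodes into new-day sleeps and naps
#'
#' An episode is a *new-day sleep* iff (a) it spans a calendar-day boundary
#' (its start date precedes its end date), or (b) it starts on or after the
#' day following the previous new-day sleep's end date.  The first episode of
#' a schedule always opens a new day.  Every other episode is a *nap*; a
#' nap's duration is credited to the NEXT new-day sleep's effective sleep
#' total, so napping never lowers the tiredness level on the day of the nap.
#' Naps after the final new-day sleep have no sleep to credit and are
#' discarded (a warning reports the count).
#'
#' @param schedule a validated, merged `sleep_schedule`.
#' @return data frame of day units: `wake_time`, `newday_start`,
#'   `newday_duration`, `nap_minutes`, `gamma` (all integer minutes);
#'   zero rows for an empty schedule.
#' @export
classify_episodes <- function(schedule) {
  n <- nrow(schedule)
  empty <- data.frame(wake_time = integer(), newday_start = integer(),
                      newday_duration = integer(), nap_minutes = integer(),
                      gamma = integer())
  if (n == 0L) return(empty)
  is_newday <- logical(n)
  last_newday_end_day <- NA_integer_
  for (i in seq_len(n)) {
    spans_midnight <- minute_day(schedule$start[i]) < minute_day(schedule$end[i])
    after_rest_day <- !is.na(last_newday_end_day) &&
      minute_day(schedule$start[i]) >= last_newday_end_day + 1L
    is_newday[i] <- i == 1L || spans_midnight || after_rest_day
    if (is_newday[i]) last_newday_end_day <- minute_day(schedule$end[i])
  }
  idx <- which(is_newday)
  trailing_naps <- sum(!is_newday & seq_len(n) > max(idx))
  if (trailing_naps > 0L)
    warning(trailing_naps, " nap(s) after the final new-day sleep discarded")
  units <- lapply(seq_along(idx), function(k) {
    i <- idx[k]
    prev <- if (k == 1L) 0L else idx[k - 1L]
    naps <- setdiff(seq_len(n)[seq_len(n) > prev & seq_len(n) < i], idx)
    nap_min <- sum(schedule$end[naps] - schedule$start[naps])
    dur <- schedule$end[i] - schedule$start[i]
    data.frame(wake_time = schedule$end[i], newday_start = schedule$start[i],
               newday_duration = dur, nap_minutes = as.integer(nap_min),
               gamma = as.integer(dur + nap_min))
  })
  do.call(rbind, units)
}

#' Effective sleep credited to a day unit
#' @param unit one row of [classify_episodes()] output.
#' @return gamma in minutes: the new-day sleep's duration plus all credited
#'   nap durations.
#' @export
effective_gamma <- function(unit) as.integer(unit$newday_duration + unit$nap_minutes)

#' Tiredness level at wake
#'
#' `max(threshold_tl - gamma, 0)`: a subject who slept at least
#' `threshold_tl` minutes wakes fully rested at TL 0; shorter sleep leaves a
#' proportional tiredness debt.
#' @param gamma effective sleep minutes (>= 1).
#' @param params a [tiredness_params()] object.
#' @return TL units in `[0, threshold_tl]`.
#' @export
initial_tl <- function(gamma, params = tiredness_params()) {
  if (any(gamma < 1)) stop("gamma must be >= 1 minute")
  pmax(params$threshold_tl - gamma, 0)
}

#' Build a subject's piecewise-linear tiredness trajectory
#'
#' One linear segment per day unit: the segment starts when the new-day sleep
#' ends (`wake_time`) at `initial_tl(gamma)` and rises at `params$slope` per
#' minute until the next new-day sleep starts.  The final segment runs to the
#' schedule horizon: the last observed episode's end plus `max_awake`
#' minutes, after which all time is treated as excluded (sensor missingness).
#' `sld_onset` is the instant TL reaches the deprivation threshold (the onset
#' instant itself counts as deprived), or `NA` when the segment ends first.
#'
#' Exclusion windows implement the 28-hour missing-data rule: for any awake
#' gap between consecutive episodes (naps included; even a short nap resets
#' the clock) longer than `max_awake`, the stretch from `gap start +
#' max_awake` to the next episode is excluded.
#'
#' @param schedule a validated `sleep_schedule`.
#' @param params a [tiredness_params()] object.
#' @param horizon optional trajectory end (integer minute); defaults to the
#'   last episode end + `params$max_awake`.
#' @return a `tiredness_trajectory` list: `subject_id`, `segments` (data
#'   frame `wake_time`, `segment_end`, `gamma`, `intercept`, `sld_onset`),
#'   `asleep` (episode intervals), `exclusions`, `horizon`, `params`.
#' @examples
#' f <- system.file("extdata", "example_sleep.csv", package = "sleepdep")
#' traj <- build_trajectory(read_sleep_csv(f)$s1)
#' traj$segments[, c("gamma", "intercept")]
#' format_minute(traj$segments$sld_onset)
#' @export
build_trajectory <- function(schedule, params = tiredness_params(),
                             horizon = NULL) {
  units <- classify_episodes(schedule)
  if (is.null(horizon))
    horizon <- max(schedule$end) + as.integer(params$max_awake)
  if (nrow(units) == 0L)
    return(structure(list(subject_id = if (nrow(schedule)) schedule$subject_id[1L] else NA_character_,
                          segments = data.frame(), asleep = schedule,
                          exclusions = exclusion_windows(schedule, params, horizon),
                          horizon = horizon, params = params),
                     class = "tiredness_trajectory"))
  seg_end <- c(units$newday_start[-1L], horizon)
  intercept <- initial_tl(units$gamma, params)
  onset <- units$wake_time + (params$threshold_tl - intercept) / params$slope
  onset[onset >= seg_end] <- NA_real_
  segments <- data.frame(wake_time = units$wake_time, segment_end = seg_end,
                         gamma = units$gamma, intercept = intercept,
                         sld_onset = onset)
  structure(list(subject_id = schedule$subject_id[1L], segments = segments,
                 asleep = data.frame(start = schedule$start, end = schedule$end),
                 exclusions = exclusion_windows(schedule, params, horizon),
                 horizon = horizon, params = params),
            class = "tiredness_trajectory")
}

#' @export
print.tiredness_trajectory <- function(x, ...) {
  cat("Tiredness trajectory for subject", x$subject_id, "\n")
  s <- x$segments
  if (nrow(s)) {
    cat(sprintf("  %d segment(s), horizon %s\n", nrow(s), format_minute(x$horizon)))
    for (i in seq_len(nrow(s)))
      cat(sprintf("  wake %s  gamma %4d  TL0 %5.1f  onset %s\n",
                  format_minute(s$wake_time[i]), s$gamma[i], s$intercept[i],
                  if (is.na(s$sld_onset[i])) "-" else format_minute(s$sld_onset[i])))
  } else cat("  (no segments)\n")
  if (nrow(x$exclusions)) cat("  ", nrow(x$exclusions), "exclusion window(s)\n")
  invisible(x)
}

#' Evaluate the tiredness level at an instant
#'
#' Intervals are half-open `[start, end)` at minute resolution.  Precedence:
#' a time inside a recorded sleep episode is `"asleep"` (recorded sleepers do
#' not post; such posts indicate clock skew); inside an exclusion window or
#' at/after the horizon it is `"excluded"`; before the first wake it is
#' `"undefined"`; otherwise the closed-form TL
#' `intercept + slope * (t - wake_time)` of the covering segment.
#'
#' @param traj a [build_trajectory()] result.
#' @param t integer minute (vectorised).
#' @return list with character `status` (`"tl"`, `"asleep"`, `"excluded"`,
#'   `"undefined"`) and numeric `tl` (NA unless status is `"tl"`).
#' @export
tiredness_at <- function(traj, t) {
  n <- length(t)
  status <- rep(NA_character_, n)
  tl <- rep(NA_real_, n)
  in_any <- function(iv, t) {
    if (is.null(iv) || nrow(iv) == 0L) return(rep(FALSE, length(t)))
    vapply(t, function(x) any(x >= iv$start & x < iv$end), FALSE)
  }
  asleep <- in_any(traj$asleep, t)
  excl <- in_any(traj$exclusions, t) | t >= traj$horizon
  segs <- traj$segments
  first_wake <- if (nrow(segs)) segs$wake_time[1L] else Inf
  for (i in seq_len(n)) {
    if (asleep[i]) { status[i] <- "asleep"; next }
    if (excl[i]) { status[i] <- "excluded"; next }
    if (t[i] < first_wake) { status[i] <- "undefined"; next }
    k <- which(t[i] >= segs$wake_time & t[i] < segs$segment_end)
    if (length(k) == 0L) { status[i] <- "excluded"; next }  # past-horizon guard
    k <- k[1L]
    status[i] <- "tl"
    tl[i] <- segs$intercept[k] + traj$params$slope * (t[i] - segs$wake_time[k])
  }
  list(status = status, tl = tl)
}

#' Sleep-deprived intervals of a trajectory
#'
#' For every segment whose TL reaches the threshold before the segment ends,
#' the half-open interval `[sld_onset, segment_end)`.  Deprivation includes
#' the onset instant (TL == threshold counts as deprived), so a fully rested
#' subject's onset falls exactly 16 h after wake.
#'
#' @param traj a [build_trajectory()] result.
#' @return data frame with `start`, `end` (minutes).
#' @export
sld_intervals <- function(traj) {
  s <- traj$segments
  if (nrow(s) == 0L) return(data.frame(start = numeric(), end = numeric()))
  keep <- !is.na(s$sld_onset)
  data.frame(start = s$sld_onset[keep], end = s$segment_end[keep])
}

#' 28-hour missing-data exclusion windows
#'
#' For each consecutive pair of episodes of any kind, an awake gap strictly
#' longer than `max_awake` minutes yields the window `(gap start + max_awake,
#' next episode start)`; the same rule applies after the final episode when
#' the horizon lies beyond `last end + max_awake`.  A gap of exactly 28 hours
#' produces nothing.
#'
#' @param schedule a validated `sleep_schedule`.
#' @param params a [tiredness_params()] object.
#' @param horizon optional horizon minute (default: last end + `max_awake`,
#'   which yields no trailing window).
#' @return data frame with `start`, `end` (minutes).
#' @export
exclusion_windows <- function(schedule, params = tiredness_params(),
                              horizon = NULL) {
  n <- nrow(schedule)
  out <- data.frame(start = integer(), end = integer())
  if (n == 0L) return(out)
  if (is.null(horizon)) horizon <- max(schedule$end) + as.integer(params$max_awake)
  starts <- integer(); ends <- integer()
  gap_from <- schedule$end[-n]; gap_to <- schedule$start[-1L]
  over <- which(gap_to - gap_from > params$max_awake)
  if (length(over)) {
    starts <- c(starts, gap_from[over] + as.integer(params$max_awake))
    ends <- c(ends, gap_to[over])
  }
  if (horizon > schedule$end[n] + params$max_awake) {
    starts <- c(starts, schedule$end[n] + as.integer(params$max_awake))
    ends <- c(ends, as.integer(horizon))
  }
  if (length(starts)) data.frame(start = starts, end = ends)[order(starts), ] else out
}

#' Export trajectory segments for audit or plotting
#' @param traj a `tiredness_trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  trajs <- if (inherits(traj, "tiredness_trajectory")) list(traj) else traj
  rows <- lapply(trajs, function(tr) {
    s <- tr$segments
    if (nrow(s) == 0L) return(NULL)
    data.frame(subject_id = tr$subject_id,
               wake_time = format_minute(s$wake_time),
               segment_end = format_minute(s$segment_end),
               gamma = s$gamma, intercept = s$intercept,
               sld_onset = ifelse(is.na(s$sld_onset), "",
                                  format_minute(s$sld_onset)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(subject_id = character(), wake_time = character(),
                      segment_end = character(), gamma = integer(),
                      intercept = numeric(), sld_onset = character())
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
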