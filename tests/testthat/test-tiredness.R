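params <- tiredness_params()

test_that("model constants follow from the parameterisation", {
  expect_equal(params$threshold_tl, 360)
  expect_equal(params$slope, 3 / 8)
  expect_equal(params$max_awake, 1680)
  expect_error(tiredness_params(threshold_tl = -1))
})

test_that("initial TL is max(threshold - gamma, 0)", {
  expect_equal(initial_tl(420, params), 0)
  expect_equal(initial_tl(240, params), 120)
  expect_equal(initial_tl(360, params), 0)
  expect_equal(initial_tl(1, params), 359)
  expect_error(initial_tl(0, params), "gamma")
})

test_that("the worked example reproduces: intercepts, onsets, nap crediting", {
  sched <- read_sleep_csv(example_sleep_path())$s1
  units <- classify_episodes(sched)
  expect_equal(nrow(units), 3L)            # three new-day sleeps
  expect_equal(units$gamma, c(420L, 240L, 330L))  # nap credited forward
  expect_equal(effective_gamma(units[3L, ]), 330L)

  traj <- build_trajectory(sched, params)
  expect_equal(traj$segments$intercept, c(0, 120, 30))
  expect_equal(format_minute(traj$segments$sld_onset[1:2]),
               c("2015-10-05T23:00", "2015-10-06T14:40"))
  # deprivation runs from onset to the next new-day sleep
  iv <- sld_intervals(traj)
  expect_equal(format_minute(iv$start[1L]), "2015-10-05T23:00")
  expect_equal(format_minute(iv$end[1L]), "2015-10-06T00:00")
})

test_that("midnight-spanning episodes are always new-day sleeps", {
  sched <- new_schedule("s", data.frame(
    start = parse_minute("2015-10-05T23:30"),
    end = parse_minute("2015-10-06T00:10")))
  units <- classify_episodes(sched)
  expect_equal(nrow(units), 1L)
  expect_equal(units$gamma, 40L)
  expect_equal(initial_tl(units$gamma, params), 320)
})

test_that("naps after the final new-day sleep are discarded with a warning", {
  sched <- new_schedule("s", data.frame(
    start = parse_minute(c("2015-10-05T00:00", "2015-10-05T14:00")),
    end = parse_minute(c("2015-10-05T07:00", "2015-10-05T15:00"))))
  expect_warning(units <- classify_episodes(sched), "discarded")
  expect_equal(nrow(units), 1L)
  expect_equal(units$gamma, 420L)
  expect_equal(nrow(classify_episodes(sched[0, ])), 0L)
})

test_that("episode classification matches the literal rule-application oracle", {
  for (seed in 1:40) {
    sched <- make_random_schedule(seed)
    kind <- oracle_classify(sched)
    units <- suppressWarnings(classify_episodes(sched))
    expect_equal(units$newday_start, sched$start[kind == "newday"],
                 info = paste("seed", seed))
    expect_equal(units$gamma, as.integer(oracle_gammas(sched, kind)),
                 info = paste("seed", seed))
  }
})

test_that("closed-form TL and statuses match the minute-grid oracle", {
  for (seed in 1:25) {
    sched <- make_random_schedule(seed + 100)
    traj <- suppressWarnings(build_trajectory(sched, params))
    grid <- oracle_minute_grid(sched, params)
    at <- tiredness_at(traj, grid$minute)
    expect_equal(at$status, ifelse(grid$status == "tl", "tl", grid$status),
                 info = paste("seed", seed))
    ok <- grid$status == "tl"
    expect_lt(max(abs(at$tl[ok] - grid$tl[ok])), 1e-9)
  }
})

test_that("deprived minute sets equal the oracle's TL >= threshold set", {
  for (seed in 1:25) {
    sched <- make_random_schedule(seed + 200)
    traj <- suppressWarnings(build_trajectory(sched, params))
    grid <- oracle_minute_grid(sched, params)
    oracle_set <- grid$minute[grid$status == "tl" &
                                grid$tl >= params$threshold_tl]
    iv <- sld_intervals(traj)
    in_iv <- rep(FALSE, nrow(grid))
    for (k in seq_len(nrow(iv)))
      in_iv <- in_iv | (grid$minute >= iv$start[k] & grid$minute < iv$end[k])
    model_set <- grid$minute[in_iv & grid$status == "tl"]
    expect_equal(model_set, oracle_set, info = paste("seed", seed))
  }
})

test_that("a rested subject reaches deprivation exactly 960 minutes after wake", {
  wake <- parse_minute("2015-10-05T07:00")
  sched <- new_schedule("s", data.frame(start = wake - 420L, end = wake))
  traj <- build_trajectory(sched, params,
                           horizon = wake + 1200L)
  expect_equal(traj$segments$sld_onset - traj$segments$wake_time, 960)
  # a gamma=420 segment lasting 10 h never reaches the threshold
  short <- build_trajectory(sched, params, horizon = wake + 600L)
  expect_true(is.na(short$segments$sld_onset))
  expect_equal(nrow(sld_intervals(short)), 0L)
})

test_that("exclusion windows trigger strictly beyond 28 h, at any episode kind", {
  # wake 08:00 day 1, next sleep 14:00 day 2 (30 h later) -> window (12:00 d2, 14:00 d2)
  fx <- make_gap_fixture(30L)
  win <- exclusion_windows(fx$schedule, params)
  expect_equal(nrow(win), 1L)
  expect_equal(format_minute(win$start), "2015-10-06T12:00")
  expect_equal(format_minute(win$end), "2015-10-06T14:00")
  # exactly 28 h: nothing
  expect_equal(nrow(exclusion_windows(make_gap_fixture(28L)$schedule, params)), 0L)
  # 28-h clock resets at a nap: 20 h awake + nap + 20 h awake has no window
  base <- parse_minute("2015-10-05T00:00")
  sched <- new_schedule("s", data.frame(
    start = base + c(0L, 1620L, 2850L),   # night, 30-min rest 20 h later,
    end = base + c(420L, 1650L, 3270L)))  # next sleep 20 h after that
  expect_equal(nrow(exclusion_windows(sched, params)), 0L)
})

test_that("TL is linear, non-decreasing, with intercepts in [0, threshold]", {
  for (seed in 1:20) {
    sched <- make_random_schedule(seed + 300)
    traj <- suppressWarnings(build_trajectory(sched, params))
    s <- traj$segments
    expect_true(all(s$intercept >= 0 & s$intercept <= params$threshold_tl))
    expect_true(all(diff(s$wake_time) > 0))
    expect_true(all(s$segment_end > s$wake_time))
    expect_true(all(is.na(s$sld_onset) |
                      abs(s$intercept + params$slope *
                            (s$sld_onset - s$wake_time) -
                            params$threshold_tl) < 1e-9))
    ok <- s$gamma >= 360 & (s$segment_end - s$wake_time) > 960
    expect_true(all(s$sld_onset[ok] - s$wake_time[ok] == 960))
  }
})

test_that("every post-wake minute has exactly one disposition", {
  for (seed in 1:10) {
    sched <- make_random_schedule(seed + 400)
    traj <- suppressWarnings(build_trajectory(sched, params))
    first_wake <- traj$segments$wake_time[1L]
    mins <- seq.int(first_wake, traj$horizon - 1L)
    at <- tiredness_at(traj, mins)
    expect_false(any(is.na(at$status)))
    expect_true(all(xor(at$status == "tl", is.na(at$tl))))
  }
})
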