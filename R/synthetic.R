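#' Synthetic-world configuration
#'
#' Parameters of the generator that emulates the study's data: per-subject
#' nightly sleep episodes whose durations straddle the 6-h deprivation
#' threshold, occasional afternoon naps, occasional skipped nights producing
#' >28-h awake gaps, and a stream of timestamped posts whose unigram
#' distribution (and optionally sentiment) shifts with the author's true
#' deprivation state.
#'
#' Text is drawn from a Zipf-weighted vocabulary `w001..wNNN`.  Deprived
#' posts draw tokens from `P_dep = (1 - effect_size) * P_suff + effect_size *
#' Q`, where `Q` is `P_suff` restricted to a random subset of the vocabulary
#' of relative size `deprived_vocab_fraction` and renormalized — a reduced
#' active vocabulary operationalizing the finding that sleep-deprived
#' subjects generate fewer distinct words.  `effect_size = 0` makes the text
#' distribution state-independent.  Each post also appends, with probability
#' 1/2, one mood word from the bundled sentiment lexicon; `sentiment_shift`
#' tilts the mood word negative when deprived (0 = no tilt).
#'
#' @param n_subjects,n_days world size.
#' @param mean_sleep,sd_sleep,min_sleep_gen nightly sleep duration: truncated
#'   normal in minutes (defaults 390 / 90 / floor 60), placed across
#'   midnight so every night is a new-day sleep.
#' @param nap_prob,nap_len afternoon-nap probability per day and length.
#' @param gap_prob probability a night is skipped (never two in a row),
#'   forcing a >28-h awake gap and hence an exclusion window.
#' @param posts_per_day Poisson mean of posts per subject-day.
#' @param vocab_size content vocabulary size.
#' @param effect_size mixture weight `[0, 1]` of the deprived text shift.
#' @param deprived_vocab_fraction relative size of the reduced deprived
#'   vocabulary.
#' @param sentiment_shift polarity tilt of deprived posts' mood words
#'   (negative values tilt negative; 0 disables).
#' @param background_factor background corpus sentences per generated post
#'   (embedding training material).
#' @param seed integer seed; worlds are byte-identical given the config.
#' @return a `world_config` list.
#' @export
world_config <- function(n_subjects = 20L, n_days = 14L, mean_sleep = 390,
                         sd_sleep = 90, min_sleep_gen = 60, nap_prob = 0.2,
                         nap_len = 90, gap_prob = 0.05, posts_per_day = 4,
                         vocab_size = 500L, effect_size = 0.5,
                         deprived_vocab_fraction = 0.6,
                         sentiment_shift = -0.2, background_factor = 2,
                         seed = 1L) {
  stopifnot(n_subjects >= 1, n_days >= 1, mean_sleep > 0, sd_sleep >= 0,
            min_sleep_gen >= 1, nap_prob >= 0, nap_prob <= 1,
            gap_prob >= 0, gap_prob <= 1, posts_per_day > 0,
            vocab_size >= 10, effect_size >= 0, effect_size <= 1,
            deprived_vocab_fraction > 0, deprived_vocab_fraction <= 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_days = as.integer(n_days), mean_sleep = mean_sleep,
                 sd_sleep = sd_sleep, min_sleep_gen = min_sleep_gen,
                 nap_prob = nap_prob, nap_len = nap_len, gap_prob = gap_prob,
                 posts_per_day = posts_per_day,
                 vocab_size = as.integer(vocab_size),
                 effect_size = effect_size,
                 deprived_vocab_fraction = deprived_vocab_fraction,
                 sentiment_shift = sentiment_shift,
                 background_factor = background_factor,
                 seed = as.integer(seed)),
            class = "world_config")
}

rtrunc_norm <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x < lower)) {
    bad <- x < lower
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Generate a synthetic world
#'
#' Draws per-subject sleep schedules, derives each subject's ground-truth
#' tiredness trajectory with the package's own tiredness model (the
#' generator and the labeling pipeline share one implementation, so pipeline
#' labels must equal generator truth wherever nothing is dropped), places
#' posts uniformly over awake minutes, and generates state-conditional post
#' text.
#'
#' @param config a [world_config()].
#' @param params a [tiredness_params()] object.
#' @return a `synthetic_world`: `schedules` (named list of
#'   `sleep_schedule`s), `trajectories`, `posts` (data frame), `truth`
#'   (`post_id`, `truth_state` in deprived/sufficient/excluded), `corpus`
#'   (list of token vectors), and the `config`.
#' @export
generate_world <- function(config = world_config(), params = tiredness_params()) {
  lex <- read_lexicon()
  neg_words <- lex$word[lex$polarity < -0.2]
  pos_words <- lex$word[lex$polarity > 0.2]
  vocab <- sprintf("w%03d", seq_len(config$vocab_size))
  p_suff <- 1 / (seq_len(config$vocab_size) + 2)
  p_suff <- p_suff / sum(p_suff)
  day0 <- parse_minute("2015-10-05T00:00") %/% 1440L

  with_seed(config$seed, {
    dep_idx <- sort(sample(config$vocab_size,
                           max(1L, round(config$deprived_vocab_fraction *
                                           config$vocab_size))))
    q <- numeric(config$vocab_size)
    q[dep_idx] <- p_suff[dep_idx] / sum(p_suff[dep_idx])
    p_dep <- (1 - config$effect_size) * p_suff + config$effect_size * q

    p_neg_dep <- min(1, max(0, 0.5 - config$sentiment_shift))  # shift<0 => more negative words
    schedules <- list(); trajectories <- list()
    post_rows <- list(); truth_rows <- list(); corpus <- list()
    pid <- 0L
    mood <- function(deprived) {
      if (stats::runif(1) > 0.5) return(character())
      p_neg <- if (deprived) p_neg_dep else 0.5
      if (stats::runif(1) < p_neg) sample(neg_words, 1L) else sample(pos_words, 1L)
    }
    for (si in seq_len(config$n_subjects)) {
      sid <- sprintf("s%02d", si)
      starts <- integer(); ends <- integer()
      prev_skipped <- TRUE  # first night always kept
      for (d in 0:config$n_days) {
        skip <- !prev_skipped && stats::runif(1) < config$gap_prob
        prev_skipped <- skip
        if (skip) next
        dur <- round(rtrunc_norm(1L, config$mean_sleep, config$sd_sleep,
                                 config$min_sleep_gen))
        pre <- round(stats::runif(1, 15, max(16, min(120, dur - 15))))
        s <- (day0 + d + 1L) * 1440L - as.integer(pre)
        starts <- c(starts, s); ends <- c(ends, s + as.integer(dur))
      }
      for (d in seq_len(config$n_days)) {
        if (stats::runif(1) >= config$nap_prob) next
        ns <- (day0 + d) * 1440L + as.integer(round(stats::runif(1, 13 * 60, 16 * 60)))
        ne <- ns + as.integer(round(config$nap_len))
        if (any(ns < ends & ne > starts)) next  # overlaps a night: drop
        starts <- c(starts, ns); ends <- c(ends, ne)
      }
      ord <- order(starts)
      sched <- new_schedule(sid, merge_episodes(starts[ord], ends[ord]))
      traj <- build_trajectory(sched, params)
      schedules[[sid]] <- sched
      trajectories[[sid]] <- traj

      first_wake <- traj$segments$wake_time[1L]
      mins <- setdiff(seq(first_wake, traj$horizon - 1L),
                      unlist(mapply(seq, sched$start, sched$end - 1L,
                                    SIMPLIFY = FALSE)))
      n_posts <- stats::rpois(1L, config$posts_per_day * config$n_days)
      if (n_posts == 0L || length(mins) == 0L) next
      t_post <- sort(sample(mins, n_posts, replace = TRUE))
      at <- tiredness_at(traj, t_post)
      state <- ifelse(at$status == "excluded", "excluded",
                      ifelse(at$tl >= params$threshold_tl,
                             "deprived", "sufficient"))
      for (k in seq_len(n_posts)) {
        pid <- pid + 1L
        len <- stats::rpois(1L, 8) + 1L
        pr <- if (state[k] == "deprived") p_dep else p_suff
        toks <- c(sample(vocab, len, replace = TRUE, prob = pr),
                  mood(state[k] == "deprived"))
        post_rows[[pid]] <- data.frame(
          post_id = sprintf("p%06d", pid), subject_id = sid,
          timestamp = t_post[k], text = paste(toks, collapse = " "),
          stringsAsFactors = FALSE)
        truth_rows[[pid]] <- data.frame(post_id = sprintf("p%06d", pid),
                                        truth_state = state[k],
                                        stringsAsFactors = FALSE)
        corpus[[length(corpus) + 1L]] <- toks
      }
    }
    n_back <- as.integer(round(config$background_factor * length(post_rows)))
    for (b in seq_len(n_back)) {
      len <- stats::rpois(1L, 8) + 1L
      corpus[[length(corpus) + 1L]] <-
        c(sample(vocab, len, replace = TRUE, prob = p_suff), mood(FALSE))
    }
    posts <- if (length(post_rows)) do.call(rbind, post_rows) else
      data.frame(post_id = character(), subject_id = character(),
                 timestamp = integer(), text = character())
    truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(post_id = character(), truth_state = character())
    structure(list(schedules = schedules, trajectories = trajectories,
                   posts = posts, truth = truth, corpus = corpus,
                   config = config, params = params),
              class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  st <- table(factor(x$truth$truth_state,
                     c("deprived", "sufficient", "excluded")))
  cat(sprintf("synthetic world: %d subjects, %d posts (%d deprived / %d sufficient / %d excluded), %d corpus sentences\n",
              length(x$schedules), nrow(x$posts), st[["deprived"]],
              st[["sufficient"]], st[["excluded"]], length(x$corpus)))
  invisible(x)
}

#' Write a synthetic world as a dataset directory
#'
#' Writes `sleep.csv`, `posts.csv`, `truth.csv` and `corpus.txt` (one
#' sentence of space-separated tokens per line) in the package's file
#' formats, so a world round-trips through [read_sleep_csv()] and
#' [read_posts()].
#'
#' @param world a [generate_world()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
world_to_files <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sleep <- do.call(rbind, lapply(world$schedules, function(s)
    data.frame(subject_id = s$subject_id, start = format_minute(s$start),
               end = format_minute(s$end), stringsAsFactors = FALSE)))
  if (is.null(sleep))
    sleep <- data.frame(subject_id = character(), start = character(),
                        end = character())
  utils::write.csv(sleep, file.path(dir, "sleep.csv"), row.names = FALSE,
                   quote = TRUE)
  posts <- world$posts
  posts$timestamp <- format_minute(posts$timestamp)
  utils::write.csv(posts, file.path(dir, "posts.csv"), row.names = FALSE,
                   quote = TRUE)
  utils::write.csv(world$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = TRUE)
  writeLines(vapply(world$corpus, paste, "", collapse = " "),
             file.path(dir, "corpus.txt"))
  invisible(dir)
}
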