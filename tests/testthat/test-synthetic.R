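test_that("worlds are reproducible from the seed and seed-sensitive", {
  cfg <- world_config(n_subjects = 3, n_days = 5, seed = 17)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(serialize(w1, NULL), serialize(w2, NULL))
  w3 <- generate_world(world_config(n_subjects = 3, n_days = 5, seed = 18))
  expect_false(identical(w1$posts, w3$posts))
})

test_that("skipped nights force exclusion windows; gap_prob 0 forces none", {
  w <- generate_world(world_config(n_subjects = 4, n_days = 3, gap_prob = 1,
                                   nap_prob = 0, seed = 2))
  for (tr in w$trajectories) expect_gt(nrow(tr$exclusions), 0L)
  w0 <- generate_world(world_config(n_subjects = 4, n_days = 6, gap_prob = 0,
                                    seed = 2))
  expect_false(any(w0$truth$truth_state == "excluded"))
})

test_that("truth is aligned with posts and derived from the tiredness model", {
  w <- generate_world(world_config(n_subjects = 5, n_days = 7, gap_prob = 0.2,
                                   seed = 23))
  expect_equal(nrow(w$truth), nrow(w$posts))
  expect_equal(w$truth$post_id, w$posts$post_id)
  labeled <- label_posts(w$posts, w$trajectories, quiet = TRUE)
  kept <- labeled$drop_reason == "none"
  expect_true(any(kept))
  expect_equal(labeled$label[kept] == "sleep_deprived",
               w$truth$truth_state[kept] == "deprived")
  expect_equal(labeled$drop_reason == "excluded",
               w$truth$truth_state == "excluded")
})

test_that("a dataset directory round-trips through the package readers", {
  w <- generate_world(world_config(n_subjects = 3, n_days = 4, seed = 5))
  dir <- withr::local_tempdir()
  world_to_files(w, dir)
  expect_true(all(file.exists(file.path(dir, c("sleep.csv", "posts.csv",
                                               "truth.csv", "corpus.txt")))))
  sched <- read_sleep_csv(file.path(dir, "sleep.csv"))
  expect_equal(names(sched), names(w$schedules))
  for (s in names(sched))
    expect_equal(sched[[s]]$start, w$schedules[[s]]$start)
  posts <- read_posts(file.path(dir, "posts.csv"))
  expect_equal(posts[order(posts$post_id), ]$text,
               w$posts[order(w$posts$post_id), ]$text)
  expect_equal(nrow(utils::read.csv(file.path(dir, "truth.csv"))),
               nrow(w$posts))
})

test_that("deprived post fraction decreases with mean nightly sleep", {
  frac <- vapply(c(300, 390, 480), function(ms) {
    w <- generate_world(world_config(n_subjects = 8, n_days = 10,
                                     mean_sleep = ms, gap_prob = 0, seed = 7))
    mean(w$truth$truth_state == "deprived")
  }, 0)
  expect_true(all(diff(frac) < 0))
})

test_that("at zero effect size the text distribution is state-independent", {
  # two-sample chi-square on unigram counts (top tokens + rest bucket),
  # 20 replicate worlds: at alpha = 0.01 at least 18 should be non-significant
  pvals <- vapply(1:20, function(r) {
    w <- generate_world(world_config(n_subjects = 5, n_days = 8,
                                     effect_size = 0,
                                     deprived_vocab_fraction = 1,
                                     sentiment_shift = 0, seed = 1000 + r))
    toks <- strsplit(w$posts$text, " ", fixed = TRUE)
    state <- w$truth$truth_state
    dep <- table(unlist(toks[state == "deprived"]))
    suf <- table(unlist(toks[state == "sufficient"]))
    all_tok <- union(names(dep), names(suf))
    m <- cbind(dep = as.numeric(dep[all_tok]), suf = as.numeric(suf[all_tok]))
    m[is.na(m)] <- 0
    top <- order(rowSums(m), decreasing = TRUE)[seq_len(min(25, nrow(m)))]
    m2 <- rbind(m[top, ], colSums(m[-top, , drop = FALSE]))
    suppressWarnings(stats::chisq.test(m2, simulate.p.value = TRUE,
                                       B = 500)$p.value)
  }, 0)
  expect_gte(sum(pvals > 0.01), 18L)
})
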