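# Small synthetic tensors for classifier tests: labels depend (or not) on
# the presence of a "marker" direction in the token features.
make_sep_tensor <- function(n = 400, kappa = 6, xi = 9, sep = TRUE, seed = 1) {
  set.seed(seed)
  values <- array(stats::rnorm(n * kappa * xi, sd = 0.5), c(n, kappa, xi))
  labels <- rep(0:1, length.out = n)
  for (i in seq_len(n)) {
    len <- sample(2:kappa, 1)
    if (len < kappa) values[i, (len + 1):kappa, ] <- 0
    if (sep && labels[i] == 1L)
      values[i, sample(len, 1), 1] <- 3    # marker feature at a random position
  }
  structure(list(values = values, labels = labels,
                 post_ids = sprintf("p%d", seq_len(n)),
                 kappa = kappa, dim = xi - 3L),
            class = "feature_tensor")
}

test_that("splits are 81/9/10, stratified, disjoint, exhaustive, seeded", {
  tens <- make_sep_tensor(n = 1000, sep = FALSE)
  cfg <- train_config(seed = 7)
  parts <- split_dataset(tens, cfg)
  expect_equal(length(parts$train$labels), 810, tolerance = 0, ignore_attr = TRUE)
  expect_equal(length(parts$val$labels), 90)
  expect_equal(length(parts$test$labels), 100)
  idx <- unlist(parts$indices, use.names = FALSE)
  expect_equal(sort(idx), 1:1000)                     # disjoint + exhaustive
  whole <- mean(tens$labels)
  for (p in c("train", "val", "test"))
    expect_lt(abs(mean(parts[[p]]$labels) - whole), 0.02)
  parts2 <- split_dataset(tens, cfg)
  expect_identical(parts$indices, parts2$indices)     # same seed, same split
  cfg$seed <- 8L
  expect_false(identical(split_dataset(tens, cfg)$indices, parts$indices))
  small <- sleepdep:::tensor_slice(tens, 1:15)
  expect_error(split_dataset(small, cfg), "10 rows per class")
})

test_that("AUC matches exhaustive positive-negative pair counting", {
  # toy 4-item example: pairs (0.9>0.8), (0.9>0.1), (0.4<0.8), (0.4>0.1) -> 3/4
  expect_equal(auc_score(c(0.9, 0.8, 0.4, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_score(c(0.5, 0.5, 0.5, 0.5), c(1, 1, 0, 0)), 0.5)  # midranks
  expect_error(auc_score(c(0.1, 0.2), c(1, 1)), "both classes")

  pair_count_auc <- function(s, y) {           # brute-force oracle
    pos <- s[y == 1]; neg <- s[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(31)
  for (rep in 1:20) {
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(40), 1)                   # rounded scores force ties
    expect_equal(auc_score(s, y), pair_count_auc(s, y))
  }
})

test_that("AUC is invariant under strictly monotone score transforms and agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(11)
  y <- rbinom(60, 1, 0.5); y[1:2] <- c(0, 1)
  s <- rnorm(60)
  a <- auc_score(s, y)
  expect_equal(auc_score(exp(s), y), a)
  expect_equal(auc_score(2 * s - 7, y), a)
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                 direction = "<"))))
})

test_that("analytic BPTT gradients match numerical differentiation", {
  set.seed(21)
  B <- 3L; Tn <- 4L; xi <- 5L; H <- 4L
  X <- array(rnorm(B * Tn * xi), c(B, Tn, xi))
  X[1, 4, ] <- 0; X[2, 3:4, ] <- 0                  # padded tails
  mask <- apply(X != 0, c(1, 2), any) * 1
  y <- c(1, 0, 1)
  par <- sleepdep:::gru_init(xi, H, seed = 2)
  keep <- matrix(1, B, H)
  loss_of <- function(p) {
    fw <- sleepdep:::gru_forward(p, X, mask, keep)
    -mean(y * log(fw$p + 1e-12) + (1 - y) * log(1 - fw$p + 1e-12))
  }
  fw <- sleepdep:::gru_forward(par, X, mask, keep)
  g <- sleepdep:::gru_backward(par, X, mask, y, fw, keep)
  eps <- 1e-6
  for (nm in names(par)) {
    ana <- g[[nm]]
    pick <- if (length(par[[nm]]) > 6) sample(length(par[[nm]]), 6) else
      seq_along(par[[nm]])
    for (k in pick) {
      pp <- par; pp[[nm]][k] <- pp[[nm]][k] + eps
      pm <- par; pm[[nm]][k] <- pm[[nm]][k] - eps
      num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      expect_equal(ana[k], num, tolerance = 1e-5,
                   info = paste("param", nm, "entry", k))
    }
  }
})

test_that("padding rows do not influence the forward pass", {
  par <- sleepdep:::gru_init(5L, 4L, seed = 3)
  set.seed(4)
  X <- array(rnorm(2 * 3 * 5), c(2, 3, 5))
  X[, 3, ] <- 0
  mask <- apply(X != 0, c(1, 2), any) * 1
  p1 <- sleepdep:::gru_forward(par, X, mask)$p
  X2 <- X; X2[, 3, ] <- 99                          # garbage behind the mask
  p2 <- sleepdep:::gru_forward(par, X2, mask)$p
  expect_equal(p1, p2)
})

test_that("the GRU separates separable data and stays near chance on noise", {
  tens <- make_sep_tensor(n = 400, sep = TRUE, seed = 2)
  cfg <- train_config(hidden_units = 16, epochs = 12, batch_size = 32,
                      learning_rate = 5e-3, seed = 1)
  parts <- split_dataset(tens, cfg)
  model <- train_model(parts$train, parts$val, cfg, quiet = TRUE)
  train_auc <- auc_score(predict(model, parts$train), parts$train$labels)
  expect_gte(train_auc, 0.95)

  noise <- make_sep_tensor(n = 400, sep = FALSE, seed = 3)
  partsn <- split_dataset(noise, cfg)
  modeln <- train_model(partsn$train, partsn$val, cfg, quiet = TRUE)
  expect_gte(modeln$best_val_auc, 0.4)
  expect_lte(modeln$best_val_auc, 0.65)   # no-signal bound up to sampling noise
})

test_that("training is reproducible for a fixed seed and flags divergence", {
  tens <- make_sep_tensor(n = 120, sep = TRUE, seed = 5)
  cfg <- train_config(hidden_units = 8, epochs = 3, batch_size = 32, seed = 9)
  parts <- split_dataset(tens, cfg)
  m1 <- train_model(parts$train, parts$val, cfg, quiet = TRUE)
  m2 <- train_model(parts$train, parts$val, cfg, quiet = TRUE)
  expect_identical(m1$par, m2$par)
  expect_identical(predict(m1, parts$test), predict(m2, parts$test))
})

test_that("repeated evaluation aggregates per-seed AUCs", {
  tens <- make_sep_tensor(n = 300, sep = TRUE, seed = 6)
  cfg <- train_config(hidden_units = 8, epochs = 4, batch_size = 32)
  res <- repeated_evaluation(tens, cfg, seeds = 1:3)
  expect_length(res$per_seed_aucs, 3L)
  expect_equal(res$mean_auc, mean(res$per_seed_aucs))
  expect_equal(res$sd_auc, sd(res$per_seed_aucs))
  expect_equal(res$n_train + res$n_val + res$n_test, 300L)
})
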