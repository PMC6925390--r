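#' Stratified train/validation/test split
#'
#' The dataset is first split 90/10 into train+validation and test, then the
#' 90 is split 90/10 again into train and validation, giving 81/9/10 of the
#' whole.  Splitting is random but stratified by label (each part's label
#' proportions track the whole) and fully determined by `config$seed`.
#'
#' @param tensor a [build_tensor()] result with at least 10 rows per class.
#' @param config a [train_config()].
#' @return list of `feature_tensor`s `train`, `val`, `test` plus an
#'   `indices` list of the row indices used.
#' @export
split_dataset <- function(tensor, config = train_config()) {
  y <- tensor$labels
  if (min(table(factor(y, c(0L, 1L)))) < 10L)
    stop("need at least 10 rows per class to split")
  test <- integer(); val <- integer(); train <- integer()
  with_seed(config$seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      n <- length(idx)
      n_test <- round(config$test_fraction * n)
      test <- c(test, idx[seq_len(n_test)])
      rest <- idx[-seq_len(n_test)]
      n_val <- round(config$val_fraction_of_trainval * length(rest))
      val <- c(val, rest[seq_len(n_val)])
      train <- c(train, rest[-seq_len(n_val)])
    }
  })
  list(train = tensor_slice(tensor, sort(train)),
       val = tensor_slice(tensor, sort(val)),
       test = tensor_slice(tensor, sort(test)),
       indices = list(train = sort(train), val = sort(val), test = sort(test)))
}

#' Repeated seeded train/evaluate runs
#'
#' For each seed: split the tensor (stratified), train the GRU, and compute
#' the test AUC.  Reports per-seed AUCs with their mean and sample standard
#' deviation, the aggregate the study protocol quotes.
#'
#' @param tensor a [build_tensor()] result.
#' @param config a [train_config()]; its `seed` field is replaced by each
#'   element of `seeds` in turn.
#' @param seeds integer vector (>= 2 for a defined SD; a single seed is
#'   allowed and yields `NA` SD).
#' @param quiet passed to [train_model()].
#' @return an `eval_result`: `per_seed_aucs`, `mean_auc`, `sd_auc`,
#'   `n_train`, `n_val`, `n_test`, `seeds`, `config`.
#' @export
repeated_evaluation <- function(tensor, config = train_config(),
                                seeds = 1:5, quiet = TRUE) {
  stopifnot(length(seeds) >= 1L)
  aucs <- numeric(0)
  sizes <- NULL
  for (s in seeds) {
    cfg <- config
    cfg$seed <- as.integer(s)
    parts <- split_dataset(tensor, cfg)
    model <- train_model(parts$train, parts$val, cfg, quiet = quiet)
    ev <- evaluate_auc(model, parts$test)
    aucs <- c(aucs, ev$auc)
    sizes <- list(n_train = length(parts$train$labels),
                  n_val = length(parts$val$labels),
                  n_test = length(parts$test$labels))
  }
  structure(c(list(per_seed_aucs = aucs, mean_auc = mean(aucs),
                   sd_auc = if (length(aucs) > 1L) stats::sd(aucs) else NA_real_,
                   seeds = as.integer(seeds), config = config), sizes),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("AUC over %d seed(s): mean %.3f (SD %s)\n  per seed: %s\n",
              length(x$per_seed_aucs), x$mean_auc,
              ifelse(is.na(x$sd_auc), "NA", sprintf("%.3f", x$sd_auc)),
              paste(sprintf("%.3f", x$per_seed_aucs), collapse = ", ")))
  invisible(x)
}
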