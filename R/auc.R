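#' ROC-AUC by the rank (Mann-Whitney) statistic
#'
#' `AUC = (R1 - n1 (n1 + 1) / 2) / (n1 n0)` where `R1` is the rank sum of the
#' positive-class scores with ties resolved by midranks.  Equivalent to the
#' probability that a random positive outranks a random negative, counting
#' ties as 1/2, and invariant under any strictly monotone transform of the
#' scores.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels 0/1 (or logical) class labels.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_score(c(0.9, 0.8, 0.4, 0.1), c(1, 0, 1, 0))  # 0.75
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC needs both classes present in the evaluation set")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a trained model on a held-out set
#' @param model a [train_model()] result.
#' @param test a `feature_tensor` disjoint from training data.
#' @return list with `auc`, `n_test`, and the prediction `scores`.
#' @export
evaluate_auc <- function(model, test) {
  scores <- predict(model, test)
  list(auc = auc_score(scores, test$labels), n_test = length(test$labels),
       scores = scores)
}
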