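#' Build the classifier's feature tensor
#'
#' Converts labeled posts into the 3-dimensional input array of shape
#' (delta, kappa, xi): delta posts, kappa token positions (the maximum
#' surviving-token count over the dataset), and per-token feature length
#' xi = dim + 3.  Each post is preprocessed, out-of-vocabulary tokens are
#' dropped (mirroring the removal of rare words before vectorization), and
#' every surviving token contributes its word vector concatenated with three
#' post-level features: sentiment polarity, subjectivity, and the hour of
#' posting as a raw integer 0--23.  Posts shorter than kappa are zero-padded,
#' so a position is padding iff its whole xi-vector is zero.  A post whose
#' tokens are all out-of-vocabulary stays as an all-zero row (a warning
#' reports the count).
#'
#' @param rows labeled posts ([label_posts()] rows with `drop_reason ==
#'   "none"`); must contain `post_id`, `timestamp`, `text`, `label`.
#' @param emb a [train_embeddings()] result.
#' @param lexicon a [read_lexicon()] data frame.
#' @param kappa optional fixed token-axis length; default: computed from
#'   `rows` as the maximum surviving-token count (at least 1).
#' @return a `feature_tensor`: list with `values` (delta x kappa x xi array),
#'   `labels` (integer 0/1, 1 = sleep deprived), `post_ids`, `kappa`, `dim`.
#' @export
build_tensor <- function(rows, emb, lexicon = read_lexicon(), kappa = NULL) {
  stopifnot(all(rows$drop_reason == "none"), !is.null(rows$label))
  dim_ <- ncol(emb$vectors)
  toks <- lapply(rows$text, function(s) {
    tk <- preprocess(s)
    tk[tk %in% emb$vocab]
  })
  if (is.null(kappa)) kappa <- max(1L, max(lengths(toks)))
  delta <- nrow(rows)
  xi <- dim_ + 3L
  values <- array(0, dim = c(delta, kappa, xi))
  n_empty <- 0L
  hours <- minute_hour(rows$timestamp)
  for (i in seq_len(delta)) {
    tk <- toks[[i]]
    if (length(tk) == 0L) { n_empty <- n_empty + 1L; next }
    tk <- tk[seq_len(min(length(tk), kappa))]
    sent <- sentiment_scores(rows$text[i], lexicon)
    for (j in seq_along(tk)) {
      values[i, j, seq_len(dim_)] <- emb$vectors[tk[j], ]
      values[i, j, dim_ + 1L] <- sent[["polarity"]]
      values[i, j, dim_ + 2L] <- sent[["subjectivity"]]
      values[i, j, dim_ + 3L] <- hours[i]
    }
  }
  if (n_empty > 0L)
    warning(n_empty, " post(s) with no in-vocabulary token kept as all-zero rows")
  structure(list(values = values,
                 labels = as.integer(rows$label == "sleep_deprived"),
                 post_ids = rows$post_id, kappa = as.integer(kappa),
                 dim = as.integer(dim_)),
            class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("feature tensor: %d posts x %d tokens x %d features (%d deprived / %d sufficient)\n",
              d[1], d[2], d[3], sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

# Subset a feature tensor by row index, preserving structure.
tensor_slice <- function(tensor, idx) {
  structure(list(values = tensor$values[idx, , , drop = FALSE],
                 labels = tensor$labels[idx],
                 post_ids = tensor$post_ids[idx],
                 kappa = tensor$kappa, dim = tensor$dim),
            class = "feature_tensor")
}
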