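#' @useDynLib sleepdep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Embedding hyperparameters
#'
#' Defaults mirror a conventional small-corpus CBOW setup: 100-dimensional
#' vectors, a symmetric context window of 5 and a minimum token frequency of
#' 5 (rarer tokens are dropped from the vocabulary before training).
#'
#' @param dim word-vector length.
#' @param window symmetric context window size in tokens.
#' @param min_count minimum corpus frequency for a token to be embedded.
#' @param epochs training passes over the corpus.
#' @param negative negative samples per centre word.
#' @param alpha,min_alpha initial and floor learning rate (linear decay).
#' @param seed RNG seed for initialisation and negative sampling.
#' @return an `embedding_config` list.
#' @export
embedding_config <- function(dim = 100L, window = 5L, min_count = 5L,
                             epochs = 5L, negative = 5L, alpha = 0.05,
                             min_alpha = 1e-4, seed = 1L) {
  stopifnot(dim >= 1, window >= 1, min_count >= 1, epochs >= 1)
  structure(list(dim = as.integer(dim), window = as.integer(window),
                 min_count = as.integer(min_count),
                 epochs = as.integer(epochs), negative = as.integer(negative),
                 alpha = alpha, min_alpha = min_alpha,
                 seed = as.integer(seed)),
            class = "embedding_config")
}

#' Train CBOW word vectors
#'
#' Trains continuous bag-of-words word2vec embeddings with negative sampling
#' on a tokenized corpus.  Training is single-threaded and seeded, so the
#' result is deterministic for a given corpus and config.
#'
#' @param corpus a list of character token vectors (e.g. [preprocess()]
#'   output), or a character vector of raw texts which will be preprocessed.
#' @param config an [embedding_config()].
#' @return a `word_embedding`: list with `vectors` (vocab x dim matrix with
#'   token rownames), `vocab`, and `config`.
#' @export
train_embeddings <- function(corpus, config = embedding_config()) {
  if (is.character(corpus)) corpus <- preprocess(corpus)
  if (length(corpus) == 1L && !is.list(corpus)) corpus <- list(corpus)
  corpus <- lapply(corpus, as.character)
  if (length(corpus) == 0L || sum(lengths(corpus)) == 0L)
    stop("empty corpus: nothing to train embeddings on")
  counts <- table(unlist(corpus, use.names = FALSE))
  vocab <- names(counts)[counts >= config$min_count]
  if (length(vocab) == 0L)
    stop("no token reaches min_count = ", config$min_count)
  vocab <- sort(vocab)
  ids <- stats::setNames(seq_along(vocab) - 1L, vocab)
  sentences <- lapply(corpus, function(toks) {
    m <- ids[toks]
    as.integer(m[!is.na(m)])
  })
  sentences <- sentences[lengths(sentences) > 1L]
  if (length(sentences) == 0L)
    stop("no sentence with >= 2 in-vocabulary tokens")
  vec <- .cbow_train(sentences, as.integer(counts[vocab]), config$dim,
                     config$window, config$negative, config$epochs,
                     config$alpha, config$min_alpha, config$seed)
  rownames(vec) <- vocab
  structure(list(vectors = vec, vocab = vocab, config = config),
            class = "word_embedding")
}

#' @export
print.word_embedding <- function(x, ...) {
  cat("CBOW word embedding:", length(x$vocab), "tokens x", ncol(x$vectors),
      "dimensions\n")
  invisible(x)
}

#' Save / load embeddings in word2vec text format
#'
#' The standard interchange format: a header line `"<vocab_size> <dim>"`
#' followed by one `"token v1 ... vdim"` row per vocabulary entry.
#' @param emb a `word_embedding`.
#' @param path file path.
#' @return `save_embedding`: `path` invisibly; `load_embedding`: a
#'   `word_embedding` (with a default config attached).
#' @export
save_embedding <- function(emb, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(emb$vectors), ncol(emb$vectors)), con)
  rows <- apply(emb$vectors, 1L, function(v)
    paste(format(v, digits = 9L, scientific = TRUE, trim = TRUE),
          collapse = " "))
  writeLines(paste(rownames(emb$vectors), rows), con)
  invisible(path)
}

#' @rdname save_embedding
#' @export
load_embedding <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- as.integer(strsplit(lines[1L], " ")[[1L]])
  parts <- strsplit(lines[-1L], " ", fixed = TRUE)
  vocab <- vapply(parts, `[[`, "", 1L)
  vec <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(hdr[2L])))
  rownames(vec) <- vocab
  stopifnot(nrow(vec) == hdr[1L])
  structure(list(vectors = vec, vocab = vocab,
                 config = embedding_config(dim = hdr[2L])),
            class = "word_embedding")
}
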