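# Tokenization, stopword filtering and lexicon sentiment for post text.

.sleepdep_env <- new.env(parent = emptyenv())

#' Bundled stopword list
#'
#' Fixed English + Spanish stopword lists snapshotted in the package so
#' preprocessing is reproducible across environments.
#' @return character vector of lowercase stopwords.
#' @export
stopword_list <- function() {
  if (is.null(.sleepdep_env$stopwords)) {
    files <- system.file("extdata", c("stopwords_en.txt", "stopwords_es.txt"),
                         package = "sleepdep")
    .sleepdep_env$stopwords <- unique(unlist(lapply(files, function(f)
      trimws(readLines(f, encoding = "UTF-8", warn = FALSE)))))
  }
  .sleepdep_env$stopwords
}

#' Tokenize and clean post text
#'
#' Lower-cases, then tokenizes on whitespace and punctuation while keeping
#' URLs, hashtags (`#x`) and mentions (`@x`) as single tokens.  Tokens on the
#' bundled English/Spanish stopword lists are removed, as are tokens with no
#' ASCII letter or digit (the operational reading of "non-English
#' characters": pure emoji/symbol tokens drop, accented Latin words such as
#' "cafe" with an accent are retained).
#'
#' @param text character vector of UTF-8 strings.
#' @return for a single string, a character vector of tokens; for a vector,
#'   a list of such vectors.  Empty results are allowed.
#' @examples
#' preprocess("I am the tired one")   # "tired" "one"
#' @export
preprocess <- function(text) {
  one <- function(s) {
    s <- tolower(s)
    raw <- strsplit(trimws(s), "\\s+")[[1L]]
    raw <- raw[nzchar(raw)]
    toks <- unlist(lapply(raw, function(w) {
      if (grepl("^(https?://|www\\.)", w)) return(w)
      if (grepl("^[#@]", w)) {
        # keep marker + word body, strip trailing punctuation
        return(sub("[^\\p{L}\\p{N}_]+$", "", w, perl = TRUE))
      }
      strsplit(w, "[^\\p{L}\\p{N}']+", perl = TRUE)[[1L]]
    }))
    toks <- gsub("^'+|'+$", "", toks)
    toks <- toks[nzchar(toks)]
    toks <- toks[!(toks %in% stopword_list())]
    toks[grepl("[A-Za-z0-9]", toks)]
  }
  if (length(text) == 1L) one(text) else lapply(text, one)
}

#' Load a sentiment lexicon
#'
#' A lexicon is a CSV `word,polarity,subjectivity` with polarity in
#' `[-1, 1]` and subjectivity in `[0, 1]`.  The default is the small general
#' lexicon bundled with the package; any file with the same schema can be
#' substituted.
#' @param path lexicon CSV path (default: bundled lexicon).
#' @return data frame `word`, `polarity`, `subjectivity`.
#' @export
read_lexicon <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "sentiment_lexicon.csv", package = "sleepdep")
  lex <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("word", "polarity", "subjectivity") %in% names(lex)),
            all(lex$polarity >= -1 & lex$polarity <= 1),
            all(lex$subjectivity >= 0 & lex$subjectivity <= 1))
  lex
}

#' Lexicon sentiment of a post
#'
#' Polarity is the mean lexicon polarity over matched tokens (0 when no
#' token matches; positive in `(0, 1]`, negative in `[-1, 0)`, 0 neutral);
#' subjectivity is the mean lexicon subjectivity over matched tokens (0 when
#' none match, 1 fully subjective).  Both are order-invariant multiset means
#' and are clipped to their documented ranges.
#'
#' @param text a single UTF-8 string.
#' @param lexicon a [read_lexicon()] data frame.
#' @return numeric `c(polarity, subjectivity)`.
#' @export
sentiment_scores <- function(text, lexicon = read_lexicon()) {
  toks <- preprocess(text)
  hit <- match(toks, lexicon$word)
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0L) return(c(polarity = 0, subjectivity = 0))
  c(polarity = min(1, max(-1, mean(lexicon$polarity[hit]))),
    subjectivity = min(1, max(0, mean(lexicon$subjectivity[hit]))))
}
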