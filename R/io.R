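#' Read per-subject sleep schedules from CSV
#'
#' The file must have header columns `subject_id,start,end` with ISO-8601
#' timestamps at minute (or second, truncated) precision.  Episodes are
#' grouped by subject, sorted by start, and validated (`start < end`, duration
#' at least one minute).  Overlapping or touching episodes within a subject
#' are merged into a single episode spanning their union, since device exports
#' can fragment one sleep into several rows; merging preserves total covered
#' minutes.
#'
#' @param path path to the sleep CSV.
#' @return named list (one element per subject) of `sleep_schedule` data
#'   frames with columns `subject_id`, `start`, `end` (integer minutes).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("subject_id,start,end",
#'              "s1,2015-10-05T00:00,2015-10-05T07:00"), f)
#' sched <- read_sleep_csv(f)
#' episode_duration(sched$s1)   # 420 minutes
#' @export
read_sleep_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("subject_id", "start", "end")
  if (!all(need %in% names(df)))
    stop("sleep CSV must have columns subject_id,start,end; got: ",
         paste(names(df), collapse = ","))
  if (nrow(df) == 0L) return(stats::setNames(list(), character()))
  start <- parse_minute(df$start)
  end <- parse_minute(df$end)
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed timestamp in sleep CSV at data row ", bad[1L],
         " (", df$start[bad[1L]], " / ", df$end[bad[1L]], ")")
  bad <- which(end <= start)
  if (length(bad))
    stop("sleep episode end <= start at data row ", bad[1L],
         " (", df$subject_id[bad[1L]], ": ", df$start[bad[1L]],
         " .. ", df$end[bad[1L]], ")")
  ep <- data.frame(subject_id = df$subject_id, start = start, end = end,
                   stringsAsFactors = FALSE)
  sched <- lapply(split(ep, ep$subject_id), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    new_schedule(d$subject_id[1L], merge_episodes(d$start, d$end))
  })
  sched[order(names(sched))]
}

#' Construct a validated sleep schedule
#'
#' @param subject_id subject identifier.
#' @param episodes data frame with integer-minute `start`, `end` columns,
#'   sorted and non-overlapping.
#' @return a `sleep_schedule` data frame.
#' @export
new_schedule <- function(subject_id, episodes) {
  out <- data.frame(subject_id = rep(subject_id, nrow(episodes)),
                    start = as.integer(episodes$start),
                    end = as.integer(episodes$end),
                    stringsAsFactors = FALSE)
  if (nrow(out) > 1L && any(out$start[-1L] < out$end[-nrow(out)]))
    stop("schedule episodes overlap after merging; internal error")
  if (any(out$end <= out$start)) stop("episode with end <= start")
  class(out) <- c("sleep_schedule", "data.frame")
  out
}

# Interval union over [start, end) pairs; input sorted by start.
merge_episodes <- function(start, end) {
  if (length(start) == 0L) return(data.frame(start = integer(), end = integer()))
  ms <- start[1L]; me <- end[1L]
  outs <- integer(); oute <- integer()
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= me) {          # overlap or touching: extend
      me <- max(me, end[i])
    } else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(outs, ms), end = c(oute, me))
}

#' Total minutes covered by a schedule's episodes
#' @param schedule a `sleep_schedule`.
#' @return integer minutes.
#' @export
episode_duration <- function(schedule) sum(schedule$end - schedule$start)

#' Read timestamped posts from CSV or JSON-lines
#'
#' Accepts a CSV with header `post_id,subject_id,timestamp,text`, or a
#' JSON-lines file (one JSON object per line with the same keys; detected by a
#' `.jsonl`/`.ndjson` extension or a leading `{`).  Rows whose text is empty
#' after whitespace stripping are skipped with a warning that reports the
#' count.  Duplicate `post_id`s are an error.  The result is sorted by
#' `(subject_id, timestamp)`.
#'
#' @param path path to the posts file.
#' @return data frame with columns `post_id`, `subject_id`, `timestamp`
#'   (integer minutes), `text`.
#' @export
read_posts <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  jsonl <- grepl("\\.(jsonl|ndjson)$", path) ||
    (length(first) && grepl("^\\s*\\{", first))
  if (jsonl) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, jsonlite::fromJSON)
    df <- data.frame(
      post_id = vapply(rows, function(r) as.character(r$post_id), ""),
      subject_id = vapply(rows, function(r) as.character(r$subject_id), ""),
      timestamp = vapply(rows, function(r) as.character(r$timestamp), ""),
      text = vapply(rows, function(r) as.character(r$text), ""),
      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, colClasses = "character")
    need <- c("post_id", "subject_id", "timestamp", "text")
    if (!all(need %in% names(df)))
      stop("posts file must have fields post_id,subject_id,timestamp,text")
  }
  if (nrow(df) == 0L)
    return(data.frame(post_id = character(), subject_id = character(),
                      timestamp = integer(), text = character(),
                      stringsAsFactors = FALSE))
  empty <- !nzchar(trimws(df$text))
  if (any(empty)) {
    warning(sum(empty), " post(s) with empty text skipped")
    df <- df[!empty, , drop = FALSE]
  }
  dup <- duplicated(df$post_id)
  if (any(dup))
    stop("duplicate post_id: ", paste(unique(df$post_id[dup]), collapse = ", "))
  ts <- parse_minute(df$timestamp)
  bad <- which(is.na(ts))
  if (length(bad))
    stop("malformed timestamp in posts file at data row ", bad[1L],
         " (", df$timestamp[bad[1L]], ")")
  out <- data.frame(post_id = df$post_id, subject_id = df$subject_id,
                    timestamp = ts, text = df$text, stringsAsFactors = FALSE)
  out[order(out$subject_id, out$timestamp), , drop = FALSE]
}

#' Write / read labeled posts
#'
#' The labeled-post table is the pipeline's central artifact: one row per
#' input post with the tiredness level (`tl`) at posting time, the binary
#' `label` (`sleep_deprived` / `sleep_sufficient`), and a `drop_reason`
#' (`none`, `asleep`, `excluded`, `undefined`, `no_schedule`).  A label is
#' present iff `drop_reason == "none"`; dropped rows carry empty `tl` and
#' `label` fields on disk.  `read_labeled_posts(write_labeled_posts(x)) == x`.
#'
#' @param rows labeled-post data frame (see [label_posts()]).
#' @param path output / input CSV path.
#' @return `write_labeled_posts` returns `path` invisibly;
#'   `read_labeled_posts` returns the data frame.
#' @export
write_labeled_posts <- function(rows, path) {
  dropped <- rows$drop_reason != "none"
  out <- data.frame(
    post_id = rows$post_id,
    subject_id = rows$subject_id,
    timestamp = format_minute(rows$timestamp),
    tl = ifelse(dropped, "", vapply(rows$tl, function(v)
      if (is.na(v)) "" else format(v, digits = 15L, scientific = FALSE), "")),
    label = ifelse(dropped, "", rows$label),
    drop_reason = rows$drop_reason,
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_labeled_posts
#' @export
read_labeled_posts <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  data.frame(
    post_id = df$post_id,
    subject_id = df$subject_id,
    timestamp = parse_minute(df$timestamp),
    tl = ifelse(nzchar(df$tl), suppressWarnings(as.numeric(df$tl)), NA_real_),
    label = ifelse(nzchar(df$label), df$label, NA_character_),
    drop_reason = df$drop_reason,
    stringsAsFactors = FALSE)
}
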