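#' Label posts with the tiredness model
#'
#' Joins each post to its author's tiredness trajectory and emits the binary
#' training label: `sleep_deprived` when the TL at posting time is at or
#' above the deprivation threshold, `sleep_sufficient` otherwise.  Posts that
#' cannot be labeled are kept with a `drop_reason` instead of a label:
#' `asleep` (timestamp inside a recorded sleep episode), `excluded` (28-hour
#' missing-data rule), `undefined` (before the subject's first wake),
#' `no_schedule` (no sleep data for the subject).  Every input post appears
#' exactly once in the output, in input order.
#'
#' @param posts data frame from [read_posts()].
#' @param trajs named list of [build_trajectory()] results, keyed by subject.
#' @param params a [tiredness_params()] object.
#' @param quiet suppress the summary message.
#' @return data frame `post_id`, `subject_id`, `timestamp`, `text`, `tl`,
#'   `label`, `drop_reason`.
#' @export
label_posts <- function(posts, trajs, params = tiredness_params(),
                        quiet = FALSE) {
  n <- nrow(posts)
  tl <- rep(NA_real_, n)
  label <- rep(NA_character_, n)
  drop <- rep("none", n)
  for (s in unique(posts$subject_id)) {
    idx <- which(posts$subject_id == s)
    tr <- trajs[[s]]
    if (is.null(tr)) { drop[idx] <- "no_schedule"; next }
    at <- tiredness_at(tr, posts$timestamp[idx])
    is_tl <- at$status == "tl"
    drop[idx[!is_tl]] <- at$status[!is_tl]
    tl[idx[is_tl]] <- at$tl[is_tl]
    label[idx[is_tl]] <- ifelse(at$tl[is_tl] >= params$threshold_tl,
                                "sleep_deprived", "sleep_sufficient")
  }
  out <- data.frame(post_id = posts$post_id, subject_id = posts$subject_id,
                    timestamp = posts$timestamp, text = posts$text,
                    tl = tl, label = label, drop_reason = drop,
                    stringsAsFactors = FALSE)
  if (!quiet) {
    lab <- table(factor(out$label, c("sleep_deprived", "sleep_sufficient")))
    dr <- table(out$drop_reason)
    message("labeled ", sum(out$drop_reason == "none"), "/", n, " posts (",
            lab[["sleep_deprived"]], " deprived, ",
            lab[["sleep_sufficient"]], " sufficient); drops: ",
            paste(names(dr), dr, sep = "=", collapse = ", "))
  }
  out
}
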