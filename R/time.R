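#' Minute-resolution timestamps
#'
#' All timestamps in this package are naive local clock times held as integer
#' minutes since 1970-01-01 00:00.  No time-zone or DST arithmetic is applied:
#' a calendar day is exactly 1440 minutes and the day index of a minute is
#' `minute %/% 1440`.  This matches a model defined purely in clock hours and
#' minutes.
#'
#' `parse_minute()` accepts ISO-8601 strings at minute or second precision
#' (`"2015-10-05T07:00"`, with `"T"` or a space as separator; seconds are
#' truncated).  `format_minute()` is its inverse at minute precision.
#'
#' @param x character vector of timestamps (`parse_minute`) or integer minutes
#'   (`format_minute`, `minute_day`, `minute_hour`).
#' @return `parse_minute`: integer minutes (NA where unparseable);
#'   `format_minute`: character `"YYYY-MM-DDTHH:MM"`; `minute_day`: integer
#'   day index since epoch; `minute_hour`: integer hour of day 0--23.
#' @examples
#' m <- parse_minute("2015-10-05T07:00")
#' format_minute(m)
#' minute_hour(m)
#' @export
parse_minute <- function(x) {
  x <- sub("T", " ", trimws(as.character(x)), fixed = TRUE)
  t <- strptime(x, "%Y-%m-%d %H:%M", tz = "UTC")
  out <- as.numeric(as.POSIXct(t))
  as.integer(floor(out / 60))
}

#' @rdname parse_minute
#' @export
format_minute <- function(x) {
  format(as.POSIXct(as.numeric(x) * 60, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M")
}

#' @rdname parse_minute
#' @export
minute_day <- function(x) as.integer(x %/% 1440L)

#' @rdname parse_minute
#' @export
minute_hour <- function(x) as.integer((x %% 1440L) %/% 60L)

#' Run code with a private RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package internals never perturb user-level
#' reproducibility.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
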