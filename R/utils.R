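#' @keywords internal
"_PACKAGE"

## Timestamps are naive local clock times stored as POSIXct in UTC so that no
## timezone or DST arithmetic is ever applied; all analysis works on clock
## hours within the calendar day.
.TZ <- "UTC"
.TS_FORMAT <- "%Y-%m-%d %H:%M"

ANALYTES <- c("TC", "HDL", "TG")

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded generators do not perturb the session.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Fractional clock hour within the calendar day (0 <= h < 24).
clock_hour <- function(timestamp) {
  lt <- as.POSIXlt(timestamp, tz = .TZ)
  lt$hour + lt$min / 60 + lt$sec / 3600
}

## Calendar date of a sample. A sample falling exactly on midnight is
## assigned to the ending day (a "24:00" sample belongs to the day before).
sample_date <- function(timestamp) {
  d <- as.Date(timestamp, tz = .TZ)
  midnight <- clock_hour(timestamp) == 0
  d[midnight] <- d[midnight] - 1L
  d
}

## Minute of day relative to `date` midnight; a 24:00 sample yields 1440.
minute_of_day <- function(timestamp, date) {
  as.integer(round(as.numeric(difftime(
    timestamp, as.POSIXct(paste(date, "00:00"), tz = .TZ), units = "mins"))))
}

#' Define a within-day clock-time window
#'
#' Windows are half-open `[start, end)` on the clock-hour axis, so a sample
#' at exactly `end` is excluded and shared boundaries never double count.
#'
#' @param start,end clock hours (numeric, e.g. `6` or `6.5`) with
#'   `0 <= start < end <= 24`.
#' @param label optional window label.
#' @return An object of class `time_window`.
#' @examples
#' time_window(6, 8, "fasted morning")
#' @export
time_window <- function(start, end, label = NULL) {
  stopifnot(is.numeric(start), is.numeric(end), length(start) == 1L,
            length(end) == 1L)
  if (!(start >= 0 && start < end && end <= 24))
    stop("time_window requires 0 <= start < end <= 24 within one day")
  structure(list(start = start, end = end,
                 label = label %||% sprintf("%05.2f-%05.2f", start, end)),
            class = "time_window")
}

#' @export
print.time_window <- function(x, ...) {
  cat(sprintf("<time_window [%s, %s) '%s'>\n",
              format(x$start), format(x$end), x$label))
  invisible(x)
}

in_window <- function(hour, window) {
  hour >= window$start & hour < window$end
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Stable hash of an R object (manifest provenance); md5 of its serialization.
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
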