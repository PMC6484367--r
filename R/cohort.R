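## Data model for sparse self-tracked lipid timeseries.
##
## A cohort is a long-format data.frame, one row per timestamped measurement
## of one analyte for one participant, with optional context columns
## (fasting state, ordinal hunger 0-3, menstrual cycle day, an id linking
## time-paired duplicate QC tests, and a same-time clinical reference value).

COHORT_COLUMNS <- c("participant", "timestamp", "analyte", "value", "fasted",
                    "hunger", "cycle_day", "pair_id", "reference_value")

#' Column-mapping dialect for lipid sample CSV files
#'
#' Describes how columns of a delimited file map onto the canonical sample
#' fields, and the timestamp format used. The defaults match the package's
#' own CSV layout.
#'
#' @param participant,timestamp,analyte,value names of the four required
#'   columns in the source file.
#' @param fasted,hunger,cycle_day,pair_id,reference_value names of the
#'   optional columns; set to `NULL` if absent.
#' @param timestamp_format a [strptime()] format for the timestamp column.
#' @return A named list of class `cohort_dialect`.
#' @export
cohort_dialect <- function(participant = "participant",
                           timestamp = "timestamp",
                           analyte = "analyte",
                           value = "value",
                           fasted = "fasted",
                           hunger = "hunger",
                           cycle_day = "cycle_day",
                           pair_id = "pair_id",
                           reference_value = "reference_value",
                           timestamp_format = .TS_FORMAT) {
  structure(list(participant = participant, timestamp = timestamp,
                 analyte = analyte, value = value, fasted = fasted,
                 hunger = hunger, cycle_day = cycle_day, pair_id = pair_id,
                 reference_value = reference_value,
                 timestamp_format = timestamp_format),
            class = "cohort_dialect")
}

#' Build a validated lipid cohort from a data frame
#'
#' Checks every row against the sample invariants (supported analyte,
#' physiologically possible concentration 0 < value < 2000 mg/dL, hunger in
#' 0-3, cycle day >= 1, parseable timestamp), drops violating rows, and
#' records them with reasons in the `rejects` attribute. Rows are sorted by
#' participant and timestamp and exact duplicate (participant, timestamp,
#' analyte) records are rejected.
#'
#' @param df a data.frame with columns `participant`, `timestamp` (POSIXct
#'   or "YYYY-MM-DD HH:MM" character), `analyte` ("TC", "HDL" or "TG"),
#'   `value` (mg/dL), and optionally `fasted`, `hunger`, `cycle_day`,
#'   `pair_id`, `reference_value`.
#' @param provenance short description of where the data came from.
#' @param timestamp_format [strptime()] format used when `timestamp` is
#'   character.
#' @return A `lipid_cohort` data.frame with attributes `rejects` (data.frame
#'   of row, reason) and `provenance`.
#' @export
as_lipid_cohort <- function(df, provenance = "in-memory",
                            timestamp_format = .TS_FORMAT) {
  stopifnot(is.data.frame(df))
  required <- c("participant", "timestamp", "analyte", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))

  n <- nrow(df)
  out <- data.frame(
    participant = as.character(df$participant),
    timestamp = if (inherits(df$timestamp, "POSIXct"))
      as.POSIXct(df$timestamp, tz = .TZ)
    else as.POSIXct(strptime(as.character(df$timestamp),
                             format = timestamp_format, tz = .TZ)),
    analyte = as.character(df$analyte),
    value = suppressWarnings(as.numeric(df$value)),
    fasted = if ("fasted" %in% names(df)) as.logical(df$fasted)
             else rep(NA, n),
    hunger = if ("hunger" %in% names(df))
      suppressWarnings(as.integer(df$hunger)) else rep(NA_integer_, n),
    cycle_day = if ("cycle_day" %in% names(df))
      suppressWarnings(as.integer(df$cycle_day)) else rep(NA_integer_, n),
    pair_id = if ("pair_id" %in% names(df)) {
      p <- as.character(df$pair_id); p[!is.na(p) & p == ""] <- NA; p
    } else rep(NA_character_, n),
    reference_value = if ("reference_value" %in% names(df))
      suppressWarnings(as.numeric(df$reference_value)) else rep(NA_real_, n),
    stringsAsFactors = FALSE
  )

  reason <- rep(NA_character_, n)
  flag <- function(bad, why) reason[is.na(reason) & bad] <<- why
  flag(is.na(out$timestamp), "unparseable timestamp")
  flag(!(out$analyte %in% ANALYTES), "unsupported analyte")
  flag(is.na(out$value), "missing value")
  flag(!is.na(out$value) & (out$value <= 0 | out$value >= 2000),
       "value outside (0, 2000) mg/dL")
  flag(!is.na(out$hunger) & !(out$hunger %in% 0:3), "hunger outside 0-3")
  flag(!is.na(out$cycle_day) & out$cycle_day < 1L, "cycle_day < 1")
  dup <- duplicated(out[c("participant", "timestamp", "analyte")])
  flag(dup, "duplicate (participant, timestamp, analyte)")

  bad <- !is.na(reason)
  rejects <- data.frame(row = which(bad), reason = reason[bad],
                        stringsAsFactors = FALSE)
  if (nrow(rejects))
    for (i in seq_len(nrow(rejects)))
      message(sprintf("rejected row %d: %s", rejects$row[i],
                      rejects$reason[i]))
  out <- out[!bad, , drop = FALSE]
  out <- out[order(out$participant, out$timestamp, out$analyte), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("lipid_cohort", "data.frame"),
            rejects = rejects, provenance = provenance)
}

#' Read lipid samples from a delimited text file
#'
#' @param path path to a CSV file with a header row.
#' @param dialect a [cohort_dialect()] mapping file columns to sample fields.
#' @return A validated `lipid_cohort`; invalid rows are dropped and logged
#'   in the `rejects` attribute.
#' @seealso [write_samples()] for the inverse, a lossless round trip.
#' @export
read_samples <- function(path, dialect = cohort_dialect()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("participant", "timestamp", "analyte", "value")
  for (field in required) {
    if (!(dialect[[field]] %in% names(raw)))
      stop(sprintf("column '%s' (mapped to %s) not found in %s",
                   dialect[[field]], field, path))
  }
  df <- data.frame(participant = raw[[dialect$participant]],
                   timestamp = raw[[dialect$timestamp]],
                   analyte = raw[[dialect$analyte]],
                   value = raw[[dialect$value]],
                   stringsAsFactors = FALSE)
  for (field in c("fasted", "hunger", "cycle_day", "pair_id",
                  "reference_value")) {
    src <- dialect[[field]]
    if (!is.null(src) && src %in% names(raw)) df[[field]] <- raw[[src]]
  }
  if ("fasted" %in% names(df)) {
    f <- toupper(trimws(df$fasted))
    df$fasted <- ifelse(f %in% c("TRUE", "T", "1", "YES"), TRUE,
                        ifelse(f %in% c("FALSE", "F", "0", "NO"), FALSE, NA))
  }
  as_lipid_cohort(df, provenance = path,
                  timestamp_format = dialect$timestamp_format)
}

#' Write a lipid cohort to CSV
#'
#' Writes all canonical columns so that `read_samples(write_samples(x))`
#' reproduces `x` exactly. An empty cohort yields a header-only file.
#'
#' @param cohort a `lipid_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(cohort, path) {
  stopifnot(inherits(cohort, "lipid_cohort"))
  out <- as.data.frame(cohort)
  out$timestamp <- format(out$timestamp, .TS_FORMAT, tz = .TZ)
  utils::write.csv(out[COHORT_COLUMNS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.lipid_cohort <- function(x, ...) {
  cat(sprintf("<lipid_cohort: %d samples, %d participants, analytes: %s>\n",
              nrow(x), length(unique(x$participant)),
              paste(sort(unique(x$analyte)), collapse = ", ")))
  rej <- attr(x, "rejects")
  if (!is.null(rej) && nrow(rej))
    cat(sprintf("  (%d rows rejected on import)\n", nrow(rej)))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat(sprintf("  ... %d more rows\n", nrow(x) - 5L))
  invisible(x)
}

## Subsetting keeps the class but not the rejects log (it refers to source
## rows, not the subset).
#' @export
`[.lipid_cohort` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out))
    out <- structure(out, class = c("lipid_cohort", "data.frame"),
                     provenance = attr(x, "provenance"))
  out
}

#' Keep one fasted sample per morning
#'
#' Retains samples flagged as fasted (self-reported >= 12 h water-only fast)
#' whose clock time falls in the given morning window, then keeps only the
#' earliest qualifying sample per analyte per calendar day, giving one
#' fasted value per morning per analyte. The window must end by 12:00
#' because a fasted sample is only defined before noon. Idempotent.
#'
#' @param cohort a `lipid_cohort` (one participant or many).
#' @param window a [time_window()] ending at or before 12:00; default
#'   06:00-08:00.
#' @return The filtered `lipid_cohort`.
#' @export
filter_fasted_morning <- function(cohort, window = time_window(6, 8)) {
  stopifnot(inherits(cohort, "lipid_cohort"),
            inherits(window, "time_window"))
  if (window$end > 12)
    stop("fasted-morning window must end at or before 12:00")
  keep <- !is.na(cohort$fasted) & cohort$fasted &
    in_window(clock_hour(cohort$timestamp), window)
  x <- cohort[keep, , drop = FALSE]
  if (!nrow(x)) return(x)
  x <- x[order(x$participant, x$timestamp), , drop = FALSE]
  key <- paste(x$participant, x$analyte, sample_date(x$timestamp))
  x <- x[!duplicated(key), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Split a participant's samples into qualifying within-day slices
#'
#' Partitions samples by calendar day (midnight-to-midnight local time; a
#' sample at exactly 24:00 belongs to the ending day) and keeps days with at
#' least `min_samples` samples of the analyte under study. Days below the
#' threshold are dropped and listed in the `dropped` attribute.
#'
#' @param cohort a `lipid_cohort`, typically one participant.
#' @param min_samples minimum samples per day (>= 2); serial within-day
#'   sampling uses 4, rhythm fitting uses 6.
#' @param analyte optional analyte to restrict to before slicing; when
#'   `NULL` all rows count toward the threshold.
#' @return A list of per-day `lipid_cohort` slices, named by
#'   `participant/date`, with attribute `dropped` (data.frame participant,
#'   date, n).
#' @export
within_day_slices <- function(cohort, min_samples = 4L, analyte = NULL) {
  stopifnot(inherits(cohort, "lipid_cohort"))
  if (min_samples < 2L) stop("min_samples must be >= 2")
  x <- cohort
  if (!is.null(analyte)) {
    stopifnot(analyte %in% ANALYTES)
    x <- x[x$analyte == analyte, , drop = FALSE]
  }
  if (!nrow(x))
    return(structure(list(), dropped = data.frame(
      participant = character(), date = as.Date(character()),
      n = integer())))
  key <- paste(x$participant, sample_date(x$timestamp), sep = "/")
  slices <- split(seq_len(nrow(x)), key)
  n_by <- vapply(slices, length, integer(1))
  keep <- n_by >= min_samples
  dropped <- data.frame(
    participant = sub("/.*$", "", names(slices)[!keep]),
    date = as.Date(sub("^.*/", "", names(slices)[!keep])),
    n = unname(n_by[!keep]), stringsAsFactors = FALSE)
  out <- lapply(slices[keep], function(i) {
    s <- x[i, , drop = FALSE]
    rownames(s) <- NULL
    s
  })
  structure(out, dropped = dropped)
}
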