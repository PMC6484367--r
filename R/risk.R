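## Clinical risk-category classification and category-crossing statistics.
##
## The default scheme follows the standard US cholesterol-education bands:
## TC <200 / 200-239 / >=240; HDL-c <40 / 40-59 / >=60 (for HDL lower is
## worse); TG <150 / 150-199 / 200-499 / >=500 mg/dL. A value equal to a
## boundary belongs to the higher category ("<200" vs "200-240" phrasing).

#' Risk-category scheme for the lipid panel
#'
#' Ordered category boundaries per analyte. The boundary convention is
#' lower-inclusive: `value < b1` is category 1, `b1 <= value < b2` category
#' 2, and so on. For HDL-c the category order runs from worse to better
#' (low HDL-c is the risk state); `direction` records this.
#'
#' @param TC,HDL,TG numeric vectors of strictly increasing boundaries,
#'   mg/dL.
#' @param labels named list of category label vectors, one more label than
#'   boundaries per analyte.
#' @return An object of class `risk_scheme`.
#' @examples
#' sch <- risk_scheme()
#' classify(sch, "TC", c(195, 200, 245))
#' @export
risk_scheme <- function(TC = c(200, 240),
                        HDL = c(40, 60),
                        TG = c(150, 200, 500),
                        labels = list(
                          TC = c("desirable", "borderline-high", "high"),
                          HDL = c("low", "intermediate", "high"),
                          TG = c("normal", "borderline-high", "high",
                                 "very-high"))) {
  bounds <- list(TC = TC, HDL = HDL, TG = TG)
  for (a in names(bounds)) {
    b <- bounds[[a]]
    if (length(b) < 1 || any(diff(b) <= 0) || any(b <= 0))
      stop("boundaries for ", a, " must be positive and strictly increasing")
    if (length(labels[[a]]) != length(b) + 1L)
      stop("need ", length(b) + 1L, " labels for ", a)
  }
  structure(list(boundaries = bounds, labels = labels,
                 direction = c(TC = "higher-worse", HDL = "lower-worse",
                               TG = "higher-worse")),
            class = "risk_scheme")
}

#' @export
print.risk_scheme <- function(x, ...) {
  cat("<risk_scheme>\n")
  for (a in names(x$boundaries))
    cat(sprintf("  %-3s: %s  (boundaries %s mg/dL, %s)\n", a,
                paste(x$labels[[a]], collapse = " | "),
                paste(x$boundaries[[a]], collapse = ", "),
                x$direction[[a]]))
  invisible(x)
}

#' Classify a concentration into its risk category
#'
#' Total function over positive values: every value maps to exactly one
#' category, with boundary values assigned to the higher category.
#'
#' @param scheme a [risk_scheme()].
#' @param analyte `"TC"`, `"HDL"` or `"TG"`.
#' @param value concentrations in mg/dL (vectorized, > 0).
#' @return Character vector of category labels.
#' @export
classify <- function(scheme, analyte, value) {
  stopifnot(inherits(scheme, "risk_scheme"))
  if (!analyte %in% names(scheme$boundaries))
    stop("unknown analyte: ", analyte)
  stopifnot(all(value > 0))
  idx <- findInterval(value, scheme$boundaries[[analyte]]) + 1L
  scheme$labels[[analyte]][idx]
}

#' Per-participant risk-category crossing report
#'
#' For each participant and analyte, pools the qualifying samples under the
#' chosen grouping — all samples from within-day slices that reach
#' `min_samples` measurements, or the one-per-morning fasted values inside
#' the morning window — and reports the range (max - min, mg/dL), the set
#' of risk categories visited, and whether the participant crossed a
#' category boundary (visited two or more). Participants with fewer than
#' two qualifying samples are excluded from denominators and listed in
#' `excluded`.
#'
#' @param cohort a `lipid_cohort`.
#' @param scheme a [risk_scheme()].
#' @param grouping `"within_day"` or `"across_mornings"`.
#' @param window morning [time_window()] for `across_mornings` (default
#'   06:00-08:00).
#' @param min_samples within-day slice threshold (default 2).
#' @return An object of class `crossing_report`: `participants`
#'   (per-participant-analyte data.frame), `cohort` (per-analyte n,
#'   n_crossed, pct_crossed plus an `"any"` union row), `excluded`, and the
#'   grouping used.
#' @export
crossing_report <- function(cohort, scheme = risk_scheme(),
                            grouping = c("within_day", "across_mornings"),
                            window = time_window(6, 8),
                            min_samples = 2L) {
  stopifnot(inherits(cohort, "lipid_cohort"))
  grouping <- match.arg(grouping)

  per <- list(); excl <- list()
  for (a in ANALYTES) {
    if (grouping == "within_day") {
      slices <- within_day_slices(cohort, min_samples = min_samples,
                                  analyte = a)
      x <- if (length(slices)) do.call(rbind, lapply(slices, as.data.frame))
           else NULL
    } else {
      f <- filter_fasted_morning(cohort, window)
      x <- as.data.frame(f[f$analyte == a, , drop = FALSE])
    }
    if (is.null(x) || !nrow(x)) next
    for (p in unique(x$participant)) {
      v <- x$value[x$participant == p]
      if (length(v) < 2L) {
        excl[[length(excl) + 1L]] <- data.frame(
          participant = p, analyte = a, n = length(v),
          stringsAsFactors = FALSE)
        next
      }
      cats <- unique(classify(scheme, a, v))
      per[[length(per) + 1L]] <- data.frame(
        participant = p, analyte = a, n_samples = length(v),
        min = min(v), max = max(v), range = max(v) - min(v),
        n_categories = length(cats),
        categories = paste(sort(cats), collapse = ";"),
        crossed = length(cats) >= 2L, stringsAsFactors = FALSE)
    }
  }
  participants <- if (length(per)) do.call(rbind, per) else
    data.frame(participant = character(), analyte = character(),
               n_samples = integer(), min = numeric(), max = numeric(),
               range = numeric(), n_categories = integer(),
               categories = character(), crossed = logical(),
               stringsAsFactors = FALSE)
  rownames(participants) <- NULL

  cohort_rows <- lapply(ANALYTES, function(a) {
    sub <- participants[participants$analyte == a, , drop = FALSE]
    data.frame(analyte = a, n = nrow(sub), n_crossed = sum(sub$crossed),
               pct_crossed = if (nrow(sub)) 100 * mean(sub$crossed) else NA_real_,
               stringsAsFactors = FALSE)
  })
  ## union: a participant counts as crossed if any analyte crossed
  if (nrow(participants)) {
    by_p <- tapply(participants$crossed, participants$participant, any)
    cohort_rows[[length(cohort_rows) + 1L]] <- data.frame(
      analyte = "any", n = length(by_p), n_crossed = sum(by_p),
      pct_crossed = 100 * mean(by_p), stringsAsFactors = FALSE)
  } else {
    cohort_rows[[length(cohort_rows) + 1L]] <- data.frame(
      analyte = "any", n = 0L, n_crossed = 0L, pct_crossed = NA_real_,
      stringsAsFactors = FALSE)
  }

  structure(list(participants = participants,
                 cohort = do.call(rbind, cohort_rows),
                 excluded = if (length(excl)) do.call(rbind, excl) else
                   data.frame(participant = character(),
                              analyte = character(), n = integer()),
                 grouping = grouping, scheme = scheme),
            class = "crossing_report")
}

#' @export
print.crossing_report <- function(x, ...) {
  cat(sprintf("<crossing_report: grouping = %s>\n", x$grouping))
  print(x$cohort, row.names = FALSE)
  if (nrow(x$excluded))
    cat(sprintf("  %d participant-analyte series excluded (<2 samples)\n",
                nrow(x$excluded)))
  invisible(x)
}

#' Cohort variability summary of per-participant ranges
#'
#' The within-group variability statistic: per analyte, the median and
#' standard deviation over participants of the per-participant range
#' (max - min, mg/dL). The dispersion is the SD of the ranges; this choice
#' is recorded in the output.
#'
#' @param report a [crossing_report()].
#' @return data.frame with analyte, n, median_range, sd_range and a
#'   `dispersion` attribute `"sd of per-participant ranges"`.
#' @export
variability_summary <- function(report) {
  stopifnot(inherits(report, "crossing_report"))
  p <- report$participants
  if (!nrow(p)) stop("empty crossing report")
  rows <- lapply(intersect(ANALYTES, unique(p$analyte)), function(a) {
    r <- p$range[p$analyte == a]
    data.frame(analyte = a, n = length(r),
               median_range = stats::median(r),
               sd_range = if (length(r) > 1) stats::sd(r) else 0,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            dispersion = "sd of per-participant ranges")
}
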