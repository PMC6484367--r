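## Within-day profile normalization, aggregation and peak/trough testing.
##
## Each qualifying day of one participant becomes a percent-of-maximum
## profile on a minute-of-day grid: values are divided by that day's
## maximum (x100) and linearly interpolated between the first and last
## observed minute (never extrapolated). Interpolated minutes exist for
## aggregation and visualization only; rank-based window tests use observed
## samples alone.

#' Convert one within-day slice to a percent-of-maximum profile
#'
#' @param slice a single-day `lipid_cohort` slice for one participant (see
#'   [within_day_slices()]).
#' @param analyte analyte to profile.
#' @param min_samples minimum observed samples required; days with fewer
#'   are excluded from rhythm analysis (returns `NULL` with a message),
#'   default 6.
#' @return An object of class `daily_profile` (participant, analyte, date,
#'   integer `minute` grid between first and last observation, `pct`
#'   percent-of-max values, logical `observed` mask), or `NULL` when the
#'   day does not qualify.
#' @export
to_percent_of_max <- function(slice, analyte, min_samples = 6L) {
  stopifnot(inherits(slice, "lipid_cohort"), analyte %in% ANALYTES)
  x <- as.data.frame(slice[slice$analyte == analyte, , drop = FALSE])
  if (!nrow(x)) return(NULL)
  date <- sample_date(x$timestamp[1])
  if (nrow(x) < min_samples) {
    message(sprintf(
      "excluded %s %s %s: %d < %d samples", x$participant[1], analyte,
      format(date), nrow(x), min_samples))
    return(NULL)
  }
  minute <- minute_of_day(x$timestamp, date)
  o <- order(minute)
  minute <- minute[o]
  pct <- 100 * x$value[o] / max(x$value)
  grid <- seq(minute[1], minute[length(minute)])
  interp <- stats::approx(minute, pct, xout = grid, method = "linear")$y
  observed <- grid %in% minute
  interp[observed] <- pct[match(grid[observed], minute)]
  structure(list(participant = x$participant[1], analyte = analyte,
                 date = date, minute = grid, pct = interp,
                 observed = observed),
            class = "daily_profile")
}

#' @export
print.daily_profile <- function(x, ...) {
  cat(sprintf(
    "<daily_profile %s %s %s: %d observed samples, grid %02d:%02d-%02d:%02d>\n",
    x$participant, x$analyte, format(x$date), sum(x$observed),
    x$minute[1] %/% 60, x$minute[1] %% 60,
    x$minute[length(x$minute)] %/% 60, x$minute[length(x$minute)] %% 60))
  invisible(x)
}

#' All qualifying daily profiles of a cohort
#'
#' Applies [within_day_slices()] then [to_percent_of_max()] across the
#' cohort; days with fewer than `min_samples` observations of the analyte
#' are excluded.
#'
#' @inheritParams to_percent_of_max
#' @param cohort a `lipid_cohort`.
#' @return list of `daily_profile` objects.
#' @export
daily_profiles <- function(cohort, analyte, min_samples = 6L) {
  slices <- within_day_slices(cohort, min_samples = min_samples,
                              analyte = analyte)
  out <- lapply(slices, to_percent_of_max, analyte = analyte,
                min_samples = min_samples)
  out[!vapply(out, is.null, logical(1))]
}

#' Aggregate daily profiles by minute of day
#'
#' Pools the (interpolated) percent-of-max profiles and takes the median
#' (default, matching a median-of-individuals display) or mean across
#' profiles at each minute where at least one profile is defined.
#'
#' @param profiles list of `daily_profile` objects.
#' @param stat `"median"` or `"mean"`.
#' @return An `aggregate_profile`: data.frame with `minute`, `value`, `n`
#'   (profiles contributing) and `n_observed` (profiles with a real sample
#'   at that minute).
#' @export
aggregate_profiles <- function(profiles, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  stopifnot(length(profiles) >= 1)
  minutes <- sort(unique(unlist(lapply(profiles, `[[`, "minute"))))
  vals <- matrix(NA_real_, length(minutes), length(profiles))
  obs <- matrix(FALSE, length(minutes), length(profiles))
  for (j in seq_along(profiles)) {
    p <- profiles[[j]]
    i <- match(p$minute, minutes)
    vals[i, j] <- p$pct
    obs[i, j] <- p$observed
  }
  f <- if (stat == "median") function(v) stats::median(v, na.rm = TRUE)
       else function(v) mean(v, na.rm = TRUE)
  out <- data.frame(minute = minutes,
                    value = apply(vals, 1, f),
                    n = rowSums(!is.na(vals)),
                    n_observed = rowSums(obs))
  out <- out[out$n >= 1, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, stat = stat,
            class = c("aggregate_profile", "data.frame"))
}

#' Centered moving average of an aggregate profile
#'
#' Smooths the per-minute aggregate with a centered window of the given
#' width; at the edges the window truncates to the profile's defined
#' extent (no wraparound across midnight).
#'
#' @param profile an [aggregate_profiles()] result.
#' @param hours window width in hours (default 2).
#' @return An `aggregate_profile` with smoothed `value`.
#' @export
moving_average <- function(profile, hours = 2) {
  stopifnot(inherits(profile, "aggregate_profile"), hours > 0)
  half <- hours * 60 / 2
  m <- profile$minute
  v <- profile$value
  cs <- c(0, cumsum(v))
  lo <- findInterval(m - half, m, left.open = TRUE) + 1L  # first idx >= m-half
  hi <- findInterval(m + half, m)                          # last idx <= m+half
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  out <- profile
  out$value <- sm
  out
}

#' Rank-based peak-versus-trough window test
#'
#' Pools the observed (not interpolated) percent-of-max values falling in a
#' morning trough window and an afternoon peak window across profiles and
#' compares the two distributions with a Kruskal-Wallis test. Because the
#' pooled values are typically non-Normal, a Kolmogorov-Smirnov check of
#' the pooled standardized values against a Normal is run first and its p
#' value recorded; the nonparametric test is used regardless.
#'
#' @param profiles list of `daily_profile` objects.
#' @param trough,peak [time_window()]s; defaults 05:00-07:00 and
#'   15:00-17:00 (for triglycerides the conventional windows are
#'   09:00-11:00 and 16:00-18:00).
#' @return An object of class `window_test` with the H `statistic`,
#'   `p.value`, group sizes, the normality pretest p, and a `degenerate`
#'   flag (all pooled values tied gives H = 0, p = 1).
#' @export
peak_trough_test <- function(profiles, trough = time_window(5, 7),
                             peak = time_window(15, 17)) {
  stopifnot(inherits(trough, "time_window"), inherits(peak, "time_window"))
  pool <- function(w) unlist(lapply(profiles, function(p) {
    h <- p$minute / 60
    p$pct[p$observed & in_window(h, w)]
  }))
  x_t <- pool(trough)
  x_p <- pool(peak)
  if (length(x_t) < 2) stop("trough window [", trough$label,
                            "] has fewer than 2 observed values")
  if (length(x_p) < 2) stop("peak window [", peak$label,
                            "] has fewer than 2 observed values")
  all_vals <- c(x_t, x_p)
  degenerate <- stats::sd(all_vals) == 0
  if (degenerate) {
    H <- 0; pval <- 1; norm_p <- NA_real_
  } else {
    kw <- suppressWarnings(stats::kruskal.test(
      list(trough = x_t, peak = x_p)))
    H <- unname(kw$statistic); pval <- kw$p.value
    z <- (all_vals - mean(all_vals)) / stats::sd(all_vals)
    norm_p <- suppressWarnings(stats::ks.test(z, "pnorm")$p.value)
  }
  structure(list(statistic = H, p.value = pval,
                 n = c(trough = length(x_t), peak = length(x_p)),
                 normality.p = norm_p, trough = trough, peak = peak,
                 degenerate = degenerate),
            class = "window_test")
}

#' @export
print.window_test <- function(x, ...) {
  cat(sprintf(
    "Kruskal-Wallis peak vs trough: H = %.3f, p = %.3g (n = %d vs %d)\n",
    x$statistic, x$p.value, x$n[["trough"]], x$n[["peak"]]))
  cat(sprintf("  windows: trough [%s), peak [%s)\n", x$trough$label,
              x$peak$label))
  if (!is.na(x$normality.p))
    cat(sprintf("  KS normality pretest p = %.3g\n", x$normality.p))
  if (x$degenerate) cat("  degenerate: all pooled values tied\n")
  invisible(x)
}

default_windows <- function(analyte) {
  if (analyte == "TG")
    list(trough = time_window(9, 11), peak = time_window(16, 18))
  else
    list(trough = time_window(5, 7), peak = time_window(15, 17))
}

#' Full daily-rhythm analysis for one analyte
#'
#' Composes the analysis chain: qualifying within-day slices are converted
#' to percent-of-maximum profiles, aggregated by minute of day (median by
#' default), smoothed with a 2 h moving average, and fit to a bounded
#' sum-of-sines model (half-day 10-12 h plus daily 23-25 h components by
#' default). Each individual profile's observed points are additionally fit
#' to a single 23-25 h component, and the peak-versus-trough window test is
#' run on the observed values.
#'
#' @param cohort a `lipid_cohort`.
#' @param analyte analyte to analyse.
#' @param min_samples minimum observed samples per day (default 6).
#' @param stat aggregation statistic, `"median"` (default) or `"mean"`.
#' @param ma_hours moving-average window in hours (default 2).
#' @param bounds_aggregate period bounds for the aggregate fit.
#' @param bounds_individual period bounds for per-individual fits.
#' @param trough,peak [time_window()]s for the window test; defaults
#'   depend on the analyte (see [peak_trough_test()]).
#' @return An object of class `rhythm_report`: `analyte`, `n_profiles`,
#'   `aggregate` (smoothed profile), `fit` (aggregate [sinefit()]),
#'   `window_test`, `individual_fits` (list of `sinefit`),
#'   `individual_summary` (data.frame with period, amplitude, acrophase,
#'   adjusted R^2 per profile), `excluded`, and `status` (`"ok"` or
#'   `"empty"` when no day qualifies).
#' @export
rhythm_pipeline <- function(cohort, analyte, min_samples = 6L,
                            stat = "median", ma_hours = 2,
                            bounds_aggregate = list(c(10, 12), c(23, 25)),
                            bounds_individual = list(c(23, 25)),
                            trough = NULL, peak = NULL) {
  stopifnot(inherits(cohort, "lipid_cohort"), analyte %in% ANALYTES)
  w <- default_windows(analyte)
  trough <- trough %||% w$trough
  peak <- peak %||% w$peak

  slices <- within_day_slices(cohort, min_samples = min_samples,
                              analyte = analyte)
  profiles <- daily_profiles(cohort, analyte, min_samples = min_samples)
  if (!length(profiles))
    return(structure(list(analyte = analyte, n_profiles = 0L,
                          status = "empty",
                          excluded = attr(slices, "dropped")),
                     class = "rhythm_report"))

  agg <- aggregate_profiles(profiles, stat = stat)
  sm <- moving_average(agg, hours = ma_hours)
  fit <- sinefit(sm$minute / 60, sm$value, period_bounds = bounds_aggregate)

  ind <- lapply(profiles, function(p) {
    tp <- p$minute[p$observed] / 60
    yp <- p$pct[p$observed]
    if (length(tp) <= 3 * length(bounds_individual) + 1) return(NULL)
    sinefit(tp, yp, period_bounds = bounds_individual)
  })
  keep <- !vapply(ind, is.null, logical(1))
  ind <- ind[keep]
  ind_summary <- if (length(ind)) do.call(rbind, lapply(seq_along(ind),
    function(i) {
      f <- ind[[i]]
      p <- profiles[keep][[i]]
      data.frame(participant = p$participant, date = p$date,
                 period = dominant_period(f),
                 amplitude = max(f$amplitudes),
                 acrophase = if (f$degenerate) NA_real_ else acrophase(f),
                 r.squared = f$r.squared, adj.r.squared = f$adj.r.squared,
                 degenerate = f$degenerate, stringsAsFactors = FALSE)
    })) else NULL

  wt <- tryCatch(peak_trough_test(profiles, trough = trough, peak = peak),
                 error = function(e) e)

  structure(list(analyte = analyte, n_profiles = length(profiles),
                 aggregate = sm, fit = fit, window_test = wt,
                 individual_fits = ind, individual_summary = ind_summary,
                 excluded = attr(slices, "dropped"), status = "ok"),
            class = "rhythm_report")
}

#' @export
print.rhythm_report <- function(x, ...) {
  cat(sprintf("<rhythm_report %s: %d daily profiles>\n", x$analyte,
              x$n_profiles))
  if (x$status == "empty") {
    cat("  no qualifying within-day slices\n")
    return(invisible(x))
  }
  print(x$fit)
  if (inherits(x$window_test, "window_test")) print(x$window_test)
  else cat("  window test unavailable:",
           conditionMessage(x$window_test), "\n")
  invisible(x)
}
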