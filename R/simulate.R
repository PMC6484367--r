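## Seedable generator of free-living lipid timeseries with the
## multi-timescale structure the analysis assumes: a multiplicative daily
## cosine (TC and TG; HDL arrhythmic), a ~4 h multiplicative ultradian
## component on TG antiphase to perceived hunger, an additive menstrual
## envelope on morning fasted TC, additive exponentially decaying
## postprandial TG bumps, and multiplicative Normal measurement noise at the
## device's coefficient of variation.

#' Describe one sinusoidal rhythm component
#'
#' @param period period in hours (> 0).
#' @param rel_amplitude relative amplitude as a fraction of baseline,
#'   `0 <= rel_amplitude < 1`; the latent multiplicative factor is
#'   `1 + rel_amplitude * cos(2*pi*(t - acrophase)/period)`.
#' @param acrophase clock hour of the component's peak.
#' @return An object of class `rhythm_component`.
#' @examples
#' # daily cholesterol rhythm peaking at 16:00 with a 40% of-maximum swing
#' rhythm_component(24, 0.25, 16)
#' @export
rhythm_component <- function(period, rel_amplitude, acrophase = 0) {
  stopifnot(period > 0, rel_amplitude >= 0, rel_amplitude < 1)
  structure(list(period = period, rel_amplitude = rel_amplitude,
                 acrophase = acrophase), class = "rhythm_component")
}

#' Describe a menstrual-cycle envelope on fasted total cholesterol
#'
#' A triangular rise-fall contribution added to the latent TC signal:
#' zero at the cycle start, rising linearly to `range_mgdl` at `peak_day`
#' (near ovulation), then falling linearly back to zero at the cycle end
#' (across the luteal phase).
#'
#' @param cycle_length cycle length in days.
#' @param peak_day day of the peak, `1 <= peak_day <= cycle_length`.
#' @param range_mgdl peak-to-trough span in mg/dL.
#' @return An object of class `menstrual_envelope`.
#' @export
menstrual_envelope <- function(cycle_length = 28L, peak_day = 14L,
                               range_mgdl = 50) {
  stopifnot(peak_day >= 1, peak_day <= cycle_length, range_mgdl >= 0)
  structure(list(cycle_length = as.integer(cycle_length),
                 peak_day = as.integer(peak_day), range_mgdl = range_mgdl),
            class = "menstrual_envelope")
}

menstrual_contribution <- function(env, day) {
  if (is.null(env)) return(rep(0, length(day)))
  d <- ((day - 1) %% env$cycle_length) + 1
  up <- d <= env$peak_day
  frac <- ifelse(up, (d - 1) / max(env$peak_day - 1, 1),
                 (env$cycle_length - d) / max(env$cycle_length - env$peak_day, 1))
  env$range_mgdl * frac
}

#' Sampling schemes for the synthetic cohort
#'
#' `sampling_within_day()` samples every analyte at regular intervals within
#' each day (e.g. every 6 h at 06:00/12:00/18:00/24:00, or hourly);
#' `sampling_mornings()` takes one fasted sample per analyte per morning at
#' a uniformly drawn time inside the window, across consecutive days;
#' `sampling_hourly_waking()` is the single-subject ultradian protocol —
#' hourly samples across the waking day with a perceived-hunger rating
#' (ordinal 0-3) recorded alongside each triglyceride sample.
#'
#' @param interval_h sampling interval in hours.
#' @param start,end first and last clock hour sampled each day (inclusive;
#'   `end = 24` places the last sample at midnight, assigned to the ending
#'   day).
#' @param n_days number of consecutive days sampled.
#' @param window a [time_window()] ending by 12:00 for morning sampling.
#' @return A classed list describing the scheme.
#' @name sampling_schemes
NULL

#' @rdname sampling_schemes
#' @export
sampling_within_day <- function(interval_h = 1, start = 6, end = 22,
                                n_days = 1L) {
  if (end <= start) stop("degenerate scheme: end must be after start")
  stopifnot(interval_h > 0, n_days >= 1)
  structure(list(kind = "within_day_serial", interval_h = interval_h,
                 start = start, end = end, n_days = as.integer(n_days)),
            class = "sampling_scheme")
}

#' @rdname sampling_schemes
#' @export
sampling_mornings <- function(window = time_window(6, 8), n_days = 20L) {
  stopifnot(inherits(window, "time_window"), n_days >= 1)
  if (window$end > 12) stop("morning window must end at or before 12:00")
  structure(list(kind = "across_mornings", window = window,
                 n_days = as.integer(n_days)), class = "sampling_scheme")
}

#' @rdname sampling_schemes
#' @export
sampling_hourly_waking <- function(start = 5, end = 24, n_days = 1L) {
  if (end <= start) stop("degenerate scheme: end must be after start")
  structure(list(kind = "hourly_waking", start = start, end = end,
                 n_days = as.integer(n_days)), class = "sampling_scheme")
}

#' Parameterize a synthetic lipid cohort
#'
#' Defaults emulate the study conditions the analysis is built for:
#' daily rhythms in TC and TG peaking at 16:00 sized so the within-day
#' percent-of-maximum fluctuation is about 40% (TC, relative amplitude
#' 0.25 since `2A/(1+A) = 0.4`) and 34% (TG, A = 0.2048); an arrhythmic HDL
#' channel; a 4 h ultradian TG component whose hunger signal is antiphase
#' (`hunger_phase_offset = pi`); multiplicative measurement noise at 4.15%
#' CV; and hourly within-day sampling 06:00-22:00.
#'
#' @param n_participants cohort size.
#' @param baselines named list per analyte of `c(mean, sd)` population
#'   baseline in mg/dL; per-participant baselines are Normal draws clipped
#'   to be positive.
#' @param daily named list per analyte of [rhythm_component()] or `NULL`
#'   for an arrhythmic channel.
#' @param ultradian_tg [rhythm_component()] for the TG ultradian pulse, or
#'   `NULL`.
#' @param menstrual_tc [menstrual_envelope()] applied to TC, or `NULL`.
#' @param measurement_cv measurement coefficient of variation, percent.
#' @param meal_times clock hours of meals (postprandial TG bumps).
#' @param postprandial_tg `c(gain, tau)`: additive TG rise in mg/dL at each
#'   meal, decaying exponentially with time constant `tau` hours.
#' @param scheme a sampling scheme (see [sampling_within_day()]).
#' @param acrophase_sd between-participant SD of the daily acrophase, hours.
#' @param hunger_phase_offset phase offset (radians) of the hunger cosine
#'   relative to the TG ultradian component; `pi` = antiphase.
#' @param seed integer seed making the generated cohort fully deterministic.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 13L,
                       baselines = list(TC = c(mean = 185, sd = 30),
                                        HDL = c(mean = 55, sd = 12),
                                        TG = c(mean = 150, sd = 60)),
                       daily = list(TC = rhythm_component(24, 0.25, 16),
                                    HDL = NULL,
                                    TG = rhythm_component(24, 0.34 / 1.66, 16)),
                       ultradian_tg = rhythm_component(4, 0.15, 2),
                       menstrual_tc = NULL,
                       measurement_cv = 4.15,
                       meal_times = c(8, 13, 19),
                       postprandial_tg = c(gain = 30, tau = 2),
                       scheme = sampling_within_day(),
                       acrophase_sd = 1,
                       hunger_phase_offset = pi,
                       seed = 1L) {
  stopifnot(n_participants >= 1, measurement_cv >= 0,
            inherits(scheme, "sampling_scheme"),
            all(ANALYTES %in% names(baselines)))
  structure(list(n_participants = as.integer(n_participants),
                 baselines = baselines, daily = daily,
                 ultradian_tg = ultradian_tg, menstrual_tc = menstrual_tc,
                 measurement_cv = measurement_cv, meal_times = meal_times,
                 postprandial_tg = postprandial_tg, scheme = scheme,
                 acrophase_sd = acrophase_sd,
                 hunger_phase_offset = hunger_phase_offset,
                 seed = as.integer(seed)),
            class = "sim_config")
}

cosine_factor <- function(component, t_h) {
  if (is.null(component)) return(rep(1, length(t_h)))
  1 + component$rel_amplitude *
    cos(2 * pi * (t_h - component$acrophase) / component$period)
}

postprandial_bump <- function(t, meal_times, gain, tau, n_days) {
  if (!length(meal_times) || gain <= 0) return(rep(0, length(t)))
  out <- rep(0, length(t))
  for (day in seq_len(n_days) - 1L) for (m in meal_times) {
    m_abs <- 24 * day + m
    dt <- t - m_abs
    on <- dt >= 0
    out[on] <- out[on] + gain * exp(-dt[on] / tau)
  }
  out
}

#' Noiseless latent lipid value for one simulated participant
#'
#' The latent signal is
#' `B * (1 + A_d cos(2pi (t_h - phi_d)/P_d)) * (1 + A_u cos(2pi (t_h - phi_u)/P_u))
#'  + M(day) + PP(t)`
#' where `B` is the participant baseline, the first factor is the daily
#' component, the second the ultradian component (TG only), `M` the
#' menstrual envelope (TC only) and `PP` the postprandial bump sum (TG
#' only). Disabled components contribute factor 1 or addend 0.
#'
#' @param config a [sim_config()].
#' @param draw one participant's realized parameters, a row of
#'   `generate_cohort()$truth$participants` (or a list with elements
#'   `baseline_TC` etc.).
#' @param analyte `"TC"`, `"HDL"` or `"TG"`.
#' @param t time in hours since midnight of simulation day 1 (vectorized).
#' @return Latent concentration in mg/dL.
#' @export
latent_value <- function(config, draw, analyte, t) {
  stopifnot(analyte %in% ANALYTES)
  t_h <- t %% 24
  day <- floor(t / 24) + 1
  base <- draw[[paste0("baseline_", analyte)]]
  daily <- config$daily[[analyte]]
  if (!is.null(daily)) {
    daily <- rhythm_component(daily$period, daily$rel_amplitude,
                              draw[[paste0("acrophase_", analyte)]])
  }
  v <- base * cosine_factor(daily, t_h)
  if (analyte == "TG") {
    v <- v * cosine_factor(config$ultradian_tg, t_h)
    pp <- config$postprandial_tg
    v <- v + postprandial_bump(t, config$meal_times, pp[["gain"]],
                               pp[["tau"]], max(ceiling(max(t) / 24), 1))
  }
  if (analyte == "TC")
    v <- v + menstrual_contribution(config$menstrual_tc, day)
  v
}

#' Apply multiplicative measurement noise at a given CV
#'
#' Returns `latent * (1 + e)` with `e ~ Normal(0, cv/100)`, redrawing any
#' replicate that would be non-positive so the output is always > 0.
#'
#' @param latent latent concentrations, mg/dL (> 0).
#' @param cv coefficient of variation in percent; `0` returns `latent`
#'   unchanged.
#' @return Noisy measurements, same length as `latent`.
#' @export
apply_measurement_noise <- function(latent, cv) {
  stopifnot(all(latent > 0), cv >= 0)
  if (cv == 0) return(latent)
  out <- latent * (1 + stats::rnorm(length(latent), 0, cv / 100))
  while (any(bad <- out <= 0))
    out[bad] <- latent[bad] * (1 + stats::rnorm(sum(bad), 0, cv / 100))
  out
}

## Continuous hunger signal and its ordinal four-point discretization
## (0 = not hungry ... 3 = very hungry) by quartiles of the cosine range.
hunger_signal <- function(config, t_h) {
  u <- config$ultradian_tg
  if (is.null(u)) return(rep(0, length(t_h)))
  cos(2 * pi * (t_h - u$acrophase) / u$period + config$hunger_phase_offset)
}

hunger_ordinal <- function(h) {
  as.integer(cut(h, breaks = c(-1.0001, -0.5, 0, 0.5, 1.0001))) - 1L
}

scheme_times <- function(scheme) {
  ## per-day sampling clock hours (mornings draw times at generation)
  switch(scheme$kind,
         within_day_serial = seq(scheme$start, scheme$end,
                                 by = scheme$interval_h),
         hourly_waking = seq(scheme$start, scheme$end, by = 1),
         across_mornings = NULL)
}

SIM_ORIGIN <- "2024-01-01"

#' Generate a synthetic lipid cohort with known ground truth
#'
#' Draws per-participant baselines and daily acrophases, evaluates the
#' latent multi-timescale signal at the scheme's sampling times, applies
#' measurement noise, and returns both the observable cohort and the ground
#' truth needed for parameter-recovery checks. Fully deterministic for a
#' fixed config (including its seed).
#'
#' @param config a [sim_config()].
#' @return A list with `cohort` (a `lipid_cohort`; morning-scheme samples
#'   carry `fasted = TRUE`, hourly-waking TG samples carry the hunger
#'   ordinal, menstrual simulations carry `cycle_day`) and `truth` (class
#'   `lipo_truth`: `participants` data.frame of realized parameters,
#'   `samples` data.frame with the latent value under each measurement, and
#'   the `config`). Latent minute-resolution trajectories are available via
#'   [latent_trajectory()].
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    ids <- sprintf("P%02d", seq_len(config$n_participants))
    draws <- data.frame(participant = ids, stringsAsFactors = FALSE)
    for (a in ANALYTES) {
      b <- config$baselines[[a]]
      draws[[paste0("baseline_", a)]] <-
        pmax(stats::rnorm(length(ids), b[["mean"]], b[["sd"]]), 1)
      d <- config$daily[[a]]
      draws[[paste0("acrophase_", a)]] <- if (is.null(d)) NA_real_ else
        stats::rnorm(length(ids), d$acrophase, config$acrophase_sd)
    }

    sch <- config$scheme
    origin <- as.POSIXct(paste(SIM_ORIGIN, "00:00"), tz = .TZ)
    rows <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      draw <- as.list(draws[i, ])
      if (sch$kind == "across_mornings") {
        t_abs <- 24 * (seq_len(sch$n_days) - 1) +
          stats::runif(sch$n_days, sch$window$start, sch$window$end)
        t_abs <- round(t_abs * 60) / 60   # minute resolution
        fasted <- TRUE
      } else {
        per_day <- scheme_times(sch)
        t_abs <- as.vector(outer(per_day, 24 * (seq_len(sch$n_days) - 1), "+"))
        fasted <- FALSE
      }
      t_abs <- sort(t_abs)
      per <- vector("list", length(ANALYTES))
      for (j in seq_along(ANALYTES)) {
        a <- ANALYTES[j]
        latent <- latent_value(config, draw, a, t_abs)
        obs <- apply_measurement_noise(latent, config$measurement_cv)
        per[[j]] <- data.frame(
          participant = ids[i],
          timestamp = origin + round(t_abs * 3600),
          analyte = a, value = pmax(round(obs, 1), 0.1), fasted = fasted,
          hunger = if (a == "TG" && sch$kind == "hourly_waking")
            hunger_ordinal(hunger_signal(config, t_abs %% 24))
          else NA_integer_,
          cycle_day = if (a == "TC" && !is.null(config$menstrual_tc))
            as.integer(((floor(t_abs / 24)) %% config$menstrual_tc$cycle_length) + 1L)
          else NA_integer_,
          pair_id = NA_character_, reference_value = NA_real_,
          latent = latent, stringsAsFactors = FALSE)
      }
      rows[[i]] <- do.call(rbind, per)
    }
    all <- do.call(rbind, rows)
    cohort <- as_lipid_cohort(all[setdiff(names(all), "latent")],
                              provenance = sprintf("simulated (seed %d)",
                                                   config$seed))
    truth <- structure(list(participants = draws,
                            samples = all[c("participant", "timestamp",
                                            "analyte", "latent")],
                            config = config),
                       class = "lipo_truth")
    list(cohort = cohort, truth = truth)
  })
}

#' Latent minute-resolution trajectory for one simulated participant
#'
#' @param truth the `truth` element returned by [generate_cohort()].
#' @param participant participant id (e.g. `"P01"`).
#' @param analyte analyte name.
#' @param days which simulation days to cover (default day 1).
#' @return data.frame with `t` (hours since day-1 midnight) and `latent`
#'   (mg/dL), on a 1-minute grid.
#' @export
latent_trajectory <- function(truth, participant, analyte, days = 1L) {
  stopifnot(inherits(truth, "lipo_truth"))
  draws <- truth$participants
  draw <- as.list(draws[draws$participant == participant, ])
  if (!length(draw$participant)) stop("unknown participant: ", participant)
  t <- unlist(lapply(days, function(d) seq((d - 1) * 24, d * 24, by = 1 / 60)))
  data.frame(t = t,
             latent = latent_value(truth$config, draw, analyte, t))
}

#' Simulate time-paired duplicate tests and clinical validation pairs
#'
#' Emulates the device-QC protocol: pairs of self-tests taken within
#' minutes of each other (two independent noisy measurements of one latent
#' value) and self-test versus venous clinical draw pairs (one noisy
#' measurement against the latent value, standing in for the reference
#' assay).
#'
#' @param config a [sim_config()]; its baselines and `measurement_cv` are
#'   used.
#' @param n_pairs number of duplicate self-test pairs.
#' @param n_clinical number of self-vs-clinical pairs.
#' @param analyte analyte measured.
#' @param seed integer seed.
#' @return list of data.frames `pairs` (participant, analyte, a, b) and
#'   `clinical` (participant, analyte, self, reference).
#' @export
simulate_pairs <- function(config, n_pairs = 50L, n_clinical = 6L,
                           analyte = "TC", seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), analyte %in% ANALYTES)
  b <- config$baselines[[analyte]]
  with_seed(seed, {
    latent <- pmax(stats::rnorm(n_pairs + n_clinical, b[["mean"]], b[["sd"]]), 1)
    lp <- latent[seq_len(n_pairs)]
    lc <- latent[n_pairs + seq_len(n_clinical)]
    pairs <- data.frame(
      participant = sprintf("P%02d", (seq_len(n_pairs) - 1L) %% 25L + 1L),
      analyte = analyte,
      a = apply_measurement_noise(lp, config$measurement_cv),
      b = apply_measurement_noise(lp, config$measurement_cv),
      stringsAsFactors = FALSE)
    clinical <- if (n_clinical > 0) data.frame(
      participant = sprintf("C%02d", seq_len(n_clinical)),
      analyte = analyte,
      self = apply_measurement_noise(lc, config$measurement_cv),
      reference = lc, stringsAsFactors = FALSE)
    else NULL
    list(pairs = pairs, clinical = clinical)
  })
}
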