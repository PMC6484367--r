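# Fixtures built in code: tiny cohorts with known structure.

ts <- function(...) paste("2024-03-01", c(...))

# one participant, hourly TC values on one day, supplied as (hour, value)
hour_cohort <- function(hours, values, analyte = "TC",
                        participant = "P01", fasted = FALSE,
                        date = "2024-03-01") {
  tstr <- sprintf("%s %02d:%02d", date, floor(hours),
                  round((hours %% 1) * 60))
  tstr[hours == 24] <- format(as.Date(date) + 1, "%Y-%m-%d 00:00")
  as_lipid_cohort(data.frame(
    participant = participant, timestamp = tstr,
    analyte = analyte, value = values, fasted = fasted,
    stringsAsFactors = FALSE))
}

# noiseless simulation config: all rhythm components off unless given
quiet_config <- function(...) {
  args <- list(...)
  defaults <- list(
    n_participants = 1L,
    daily = list(TC = NULL, HDL = NULL, TG = NULL),
    ultradian_tg = NULL, menstrual_tc = NULL,
    measurement_cv = 0, meal_times = numeric(),
    postprandial_tg = c(gain = 0, tau = 2),
    acrophase_sd = 0, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}
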