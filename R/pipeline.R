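## End-to-end pipeline: simulate (or load) -> crossing statistics -> rhythm
## analysis -> device QC, with machine-readable artifacts and a
## reproducibility manifest.

rhythm_report_json <- function(report) {
  if (report$status != "ok")
    return(list(analyte = report$analyte, status = report$status))
  f <- report$fit
  wt <- report$window_test
  list(analyte = report$analyte, status = report$status,
       n_profiles = report$n_profiles,
       fit = list(periods = f$periods, amplitudes = f$amplitudes,
                  phases = f$phases, offset = f$offset, sse = f$sse,
                  rmse = f$rmse, r.squared = f$r.squared,
                  adj.r.squared = f$adj.r.squared, n = f$n, p = f$p,
                  dominant_period = dominant_period(f),
                  acrophase = if (f$degenerate) NA else acrophase(f),
                  degenerate = f$degenerate),
       window_test = if (inherits(wt, "window_test"))
         list(H = wt$statistic, p.value = wt$p.value,
              n_trough = unname(wt$n[["trough"]]),
              n_peak = unname(wt$n[["peak"]]),
              normality.p = wt$normality.p, degenerate = wt$degenerate)
       else list(error = conditionMessage(wt)))
}

qc_report_json <- function(qc) {
  list(n_pairs = nrow(qc$pairs), cohort_cv = qc$cohort_cv,
       mean_te = qc$mean_te, category_agreement = qc$category_agreement,
       flags = qc$flags)
}

#' Run the full analysis pipeline into an artifact directory
#'
#' Simulates a within-day cohort and an across-mornings cohort from
#' `config` (or analyses a cohort read from `cohort_path`), computes
#' within-day and across-morning risk-category crossing reports, runs the
#' daily-rhythm analysis for the requested analytes, computes the device-QC
#' report from simulated duplicate and clinical pairs, and writes all
#' artifacts plus a reproducibility manifest (seed, config hash, row
#' counts, file digests) to `out_dir`. Deterministic for a fixed config.
#'
#' @param out_dir artifact directory (created if needed).
#' @param config a [sim_config()]; its scheme is used for the within-day
#'   cohort, and a 20-day morning scheme derived from it for the fasted
#'   cohort.
#' @param cohort_path optional CSV of real samples analysed instead of a
#'   simulation.
#' @param scheme a [risk_scheme()].
#' @param thresholds a [qc_thresholds()].
#' @param rhythm_analytes analytes run through [rhythm_pipeline()].
#' @return Invisibly, a list with the computed reports and artifact paths.
#' @export
run_all <- function(out_dir, config = sim_config(), cohort_path = NULL,
                    scheme = risk_scheme(), thresholds = qc_thresholds(),
                    rhythm_analytes = c("TC", "TG")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  if (is.null(cohort_path)) {
    sim <- generate_cohort(config)
    within_cohort <- sim$cohort
    morning_cfg <- config
    morning_cfg$scheme <- sampling_mornings(n_days = 20L)
    morning_cfg$seed <- config$seed + 1L
    morning_cohort <- generate_cohort(morning_cfg)$cohort
    paths$cohort <- file.path(out_dir, "cohort.csv")
    write_samples(within_cohort, paths$cohort)
    paths$cohort_mornings <- file.path(out_dir, "cohort_mornings.csv")
    write_samples(morning_cohort, paths$cohort_mornings)
  } else {
    within_cohort <- morning_cohort <- read_samples(cohort_path)
  }

  crossing_within <- crossing_report(within_cohort, scheme,
                                     grouping = "within_day")
  crossing_mornings <- crossing_report(morning_cohort, scheme,
                                       grouping = "across_mornings")
  paths$crossing_csv <- file.path(out_dir, "crossing_participants.csv")
  tag <- function(label, d)
    if (nrow(d)) cbind(grouping = label, d) else
      cbind(grouping = character(), d)
  utils::write.csv(rbind(
    tag("within_day", crossing_within$participants),
    tag("across_mornings", crossing_mornings$participants)),
    paths$crossing_csv, row.names = FALSE)
  paths$crossing_json <- file.path(out_dir, "crossing_summary.json")
  jsonlite::write_json(list(
    within_day = crossing_within$cohort,
    across_mornings = crossing_mornings$cohort,
    variability_within = tryCatch(
      variability_summary(crossing_within), error = function(e) NULL),
    variability_mornings = tryCatch(
      variability_summary(crossing_mornings), error = function(e) NULL)),
    paths$crossing_json, auto_unbox = TRUE, digits = NA, dataframe = "rows")

  rhythms <- lapply(rhythm_analytes, function(a)
    rhythm_pipeline(within_cohort, a))
  names(rhythms) <- rhythm_analytes
  paths$rhythm_json <- file.path(out_dir, "rhythm_report.json")
  jsonlite::write_json(lapply(rhythms, rhythm_report_json),
                       paths$rhythm_json, auto_unbox = TRUE, digits = NA)
  for (a in rhythm_analytes) {
    r <- rhythms[[a]]
    if (!is.null(r$individual_summary)) {
      p <- file.path(out_dir, sprintf("individual_fits_%s.csv", a))
      utils::write.csv(r$individual_summary, p, row.names = FALSE)
      paths[[paste0("individual_fits_", a)]] <- p
    }
  }

  qc <- NULL
  if (is.null(cohort_path)) {
    sim_qc <- simulate_pairs(config, n_pairs = 50L, n_clinical = 6L,
                             seed = config$seed + 2L)
    qc <- qc_report(sim_qc$pairs, sim_qc$clinical, scheme, thresholds)
  } else {
    found <- extract_pairs(within_cohort)
    if (!is.null(found$pairs))
      qc <- qc_report(found$pairs, found$clinical, scheme, thresholds)
  }
  if (!is.null(qc)) {
    paths$qc_json <- file.path(out_dir, "qc_report.json")
    jsonlite::write_json(qc_report_json(qc), paths$qc_json,
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    tool = "liporhythm",
    version = as.character(utils::packageVersion("liporhythm")),
    seed = config$seed,
    config_hash = object_hash(config),
    generated_at = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    n_within_samples = nrow(within_cohort),
    n_morning_samples = nrow(morning_cohort),
    n_participants = length(unique(within_cohort$participant)),
    excluded_within = nrow(crossing_within$excluded),
    excluded_mornings = nrow(crossing_mornings$excluded),
    artifacts = lapply(paths, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p)))))
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)

  invisible(list(crossing_within = crossing_within,
                 crossing_mornings = crossing_mornings,
                 rhythms = rhythms, qc = qc, paths = paths,
                 manifest = manifest))
}
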