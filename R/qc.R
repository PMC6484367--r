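## Point-of-care device quality statistics: imprecision (reliability) as
## the percent coefficient of variation between time-paired duplicate
## tests, and inaccuracy (validity) as percent disagreement between a
## self-collected test and a same-time clinical reference draw.

#' Quality-control thresholds for a point-of-care lipid analyzer
#'
#' @param te_standard clinical total-error standard, percent (default 8.9).
#' @param manufacturer_cv manufacturer's reported duplicate CV, percent
#'   (default 4.45).
#' @param category_agreement_band manufacturer's reported risk-category
#'   agreement range, percent (default 84-86).
#' @param manufacturer_te manufacturer's reported average total error,
#'   percent (default 13).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(te_standard = 8.9, manufacturer_cv = 4.45,
                          category_agreement_band = c(84, 86),
                          manufacturer_te = 13) {
  stopifnot(te_standard >= 0, manufacturer_cv >= 0, manufacturer_te >= 0,
            all(category_agreement_band >= 0))
  structure(list(te_standard = te_standard,
                 manufacturer_cv = manufacturer_cv,
                 category_agreement_band = category_agreement_band,
                 manufacturer_te = manufacturer_te),
            class = "qc_thresholds")
}

#' Percent coefficient of variation of a time-paired duplicate test
#'
#' `100 * SD(a, b) / mean(a, b)` with the two-point sample SD (n - 1
#' denominator), i.e. `100 * |a - b| / sqrt(2) / mean(a, b)`. Symmetric in
#' its arguments and scale-invariant.
#'
#' @param a,b the two measurements of the pair, mg/dL (> 0, vectorized).
#' @return Percent CV per pair.
#' @examples
#' paired_cv(190, 210)  # 7.0711
#' @export
paired_cv <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (any(a <= 0 | b <= 0)) stop("paired_cv requires positive values")
  100 * (abs(a - b) / sqrt(2)) / ((a + b) / 2)
}

#' Percent total error of a self-test against a clinical reference
#'
#' `100 * |self - reference| / reference`: percent disagreement with the
#' reference in the denominator, so the statistic is intentionally not
#' symmetric. Outliers are reported as-is, never clipped.
#'
#' @param self self-collected measurement, mg/dL (> 0, vectorized).
#' @param reference clinical reference value, mg/dL (> 0).
#' @return Percent total error per pair.
#' @examples
#' total_error(220, 200)  # 10
#' @export
total_error <- function(self, reference) {
  stopifnot(length(self) == length(reference))
  if (any(self <= 0 | reference <= 0))
    stop("total_error requires positive values")
  100 * abs(self - reference) / reference
}

#' Extract duplicate-test pairs and clinical pairs from a cohort
#'
#' Duplicate pairs are identified by a shared `pair_id` (exactly two
#' samples of one analyte); clinical pairs are samples carrying a
#' `reference_value`.
#'
#' @param cohort a `lipid_cohort`.
#' @return list of data.frames `pairs` (participant, analyte, a, b) and
#'   `clinical` (participant, analyte, self, reference).
#' @export
extract_pairs <- function(cohort) {
  stopifnot(inherits(cohort, "lipid_cohort"))
  x <- as.data.frame(cohort)
  paired <- x[!is.na(x$pair_id), , drop = FALSE]
  pairs <- NULL
  if (nrow(paired)) {
    sp <- split(paired, paste(paired$pair_id, paired$analyte))
    sp <- Filter(function(d) nrow(d) == 2L, sp)
    if (length(sp))
      pairs <- do.call(rbind, lapply(sp, function(d) data.frame(
        participant = d$participant[1], analyte = d$analyte[1],
        a = d$value[1], b = d$value[2], stringsAsFactors = FALSE)))
  }
  clin <- x[!is.na(x$reference_value), , drop = FALSE]
  clinical <- if (nrow(clin)) data.frame(
    participant = clin$participant, analyte = clin$analyte,
    self = clin$value, reference = clin$reference_value,
    stringsAsFactors = FALSE) else NULL
  list(pairs = pairs, clinical = clinical)
}

#' Device reliability and validity report
#'
#' Aggregates per-pair duplicate CVs (per participant and cohort-wide) and,
#' when clinical pairs are supplied, per-pair total error with per-analyte
#' mean and SD, plus the fraction of clinical pairs in which the self-test
#' lands in the same risk category as the reference. Pass flags compare
#' the cohort statistics to the thresholds.
#'
#' @param pairs data.frame of duplicate tests with columns `participant`,
#'   `analyte`, `a`, `b` (see [extract_pairs()] / [simulate_pairs()]).
#' @param clinical_pairs optional data.frame with `participant`, `analyte`,
#'   `self`, `reference`.
#' @param scheme [risk_scheme()] for category agreement.
#' @param thresholds [qc_thresholds()].
#' @param cv_tolerance multiplier on `manufacturer_cv` for the reliability
#'   pass flag (default 1).
#' @return An object of class `qc_report`.
#' @export
qc_report <- function(pairs, clinical_pairs = NULL, scheme = risk_scheme(),
                      thresholds = qc_thresholds(), cv_tolerance = 1) {
  stopifnot(is.data.frame(pairs), nrow(pairs) >= 1,
            all(c("participant", "analyte", "a", "b") %in% names(pairs)))
  pairs$cv <- paired_cv(pairs$a, pairs$b)
  per_participant <- stats::aggregate(cv ~ participant, pairs, mean)
  cohort_cv <- mean(per_participant$cv)

  te_by_analyte <- NULL; te_mean <- NA_real_; agreement <- NA_real_
  if (!is.null(clinical_pairs) && nrow(clinical_pairs)) {
    clinical_pairs$te <- total_error(clinical_pairs$self,
                                     clinical_pairs$reference)
    te_by_analyte <- do.call(rbind, lapply(
      split(clinical_pairs, clinical_pairs$analyte), function(d)
        data.frame(analyte = d$analyte[1], n = nrow(d),
                   mean_te = mean(d$te),
                   sd_te = if (nrow(d) > 1) stats::sd(d$te) else 0,
                   stringsAsFactors = FALSE)))
    rownames(te_by_analyte) <- NULL
    te_mean <- mean(clinical_pairs$te)
    same <- mapply(function(an, s, r)
      classify(scheme, an, s) == classify(scheme, an, r),
      clinical_pairs$analyte, clinical_pairs$self, clinical_pairs$reference)
    agreement <- mean(same)
  }

  flags <- list(
    cv_within_manufacturer =
      cohort_cv <= thresholds$manufacturer_cv * cv_tolerance,
    te_meets_standard = !is.na(te_mean) && te_mean <= thresholds$te_standard,
    te_within_manufacturer = !is.na(te_mean) &&
      te_mean <= thresholds$manufacturer_te,
    agreement_at_manufacturer = !is.na(agreement) &&
      100 * agreement >= thresholds$category_agreement_band[1])

  structure(list(pairs = pairs, per_participant_cv = per_participant,
                 cohort_cv = cohort_cv,
                 clinical_pairs = clinical_pairs,
                 te_by_analyte = te_by_analyte, mean_te = te_mean,
                 category_agreement = agreement,
                 thresholds = thresholds, flags = flags),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report: %d duplicate pairs, cohort mean CV %.2f%% (manufacturer %.2f%%)>\n",
    nrow(x$pairs), x$cohort_cv, x$thresholds$manufacturer_cv))
  if (!is.na(x$mean_te))
    cat(sprintf("  mean total error %.1f%% (standard %.1f%%); category agreement %.0f%%\n",
                x$mean_te, x$thresholds$te_standard,
                100 * x$category_agreement))
  for (nm in names(x$flags))
    cat(sprintf("  %-26s %s\n", nm, ifelse(x$flags[[nm]], "PASS", "FAIL")))
  invisible(x)
}
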