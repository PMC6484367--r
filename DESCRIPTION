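Package: liporhythm
Title: Daily Rhythm Detection and Risk-Category Crossing Analysis for
    Self-Tracked Blood Lipids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing sparse, self-collected timeseries of total
    cholesterol, HDL-cholesterol and triglycerides measured in free-living
    people with a point-of-care analyzer. Provides validated CSV import of
    long-format lipid samples, clinical risk-category classification and
    within-day / across-fasted-morning category-crossing statistics, a
    bounded sum-of-sines model fitted by variable-projection nonlinear
    least squares for detecting daily (23-25 h) and half-day (10-12 h)
    rhythms in percent-of-maximum profiles, nonparametric peak-versus-trough
    window tests, device precision and accuracy statistics (paired
    coefficient of variation, total error, category agreement), and a
    seedable synthetic-cohort generator with daily, ultradian, menstrual
    and postprandial structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
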