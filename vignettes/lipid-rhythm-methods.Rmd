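---
title: "Methods: daily lipid rhythms, risk-category crossing, and device QC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: daily lipid rhythms, risk-category crossing, and device QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liporhythm)
```

## The problem

Point-of-care fingerstick analyzers let people measure total cholesterol
(TC), HDL-cholesterol and triglycerides (TG) many times a day in ordinary
life. Three questions drive the analyses in this package: do a person's
lipids traverse clinical risk-category boundaries on short timescales
(within one day; across fasted mornings); is the within-day variability
structured as a daily rhythm; and is the measuring device precise enough
for these questions to be answerable at all. Every analysis here works on
naive local clock time — the phenomena of interest are phrased in time of
day, so no timezone or DST arithmetic is ever applied.

## Data model and filters

A sample is one timestamped measurement of one analyte in mg/dL with
optional context (fasted flag, ordinal hunger 0–3, menstrual cycle day, a
pair id linking duplicate QC tests, a same-time clinical reference value).
Import validates row-wise — positive values below 2000 mg/dL, supported
analytes only, parseable timestamps, no duplicate (participant, time,
analyte) records — rejecting and logging violations rather than failing.

Two filters define the analysis populations:

- **Fasted mornings**: samples flagged fasted (self-reported ≥ 12 h
  water-only) whose clock time falls in a morning window, by default
  06:00–08:00; at most the *earliest* qualifying sample per analyte per
  calendar day is kept. The earliest-sample rule is a convention we fixed
  for reproducibility; when a morning holds a single fasted sample (the
  common case) it is vacuous. Windows are half-open `[start, end)` so a
  value at the shared boundary of two windows is counted exactly once, and
  a fasted window must end by 12:00 because the fasted state is only
  defined before noon.
- **Within-day slices**: samples partitioned midnight-to-midnight, with a
  sample at exactly 24:00 assigned to the *ending* day (serial protocols
  end at 24:00). A day qualifies with at least `min_samples` measurements
  of the analyte under study — 2 for crossing statistics, 4 for serial
  sampling, 6 for rhythm fitting (too few points cannot constrain a
  3K + 1-parameter fit).

## Risk categories and crossing

The default scheme uses the standard US cholesterol-education bands
(TC <200 / 200–239 / ≥240; HDL-c <40 / 40–59 / ≥60; TG <150 / 150–199 /
200–499 / ≥500 mg/dL), fully overridable. A value equal to a boundary
belongs to the higher category, consistent with "<200" phrasing of the
desirable band. "Crossing" is operationalized as a participant's grouped
samples visiting two or more categories of one analyte; the cohort
statistic is the percentage of participants (with ≥ 2 qualifying samples)
who cross. For multi-day participants the within-day grouping pools all
qualifying days; with one sampled day per participant (the default
simulated protocol) this coincides with single-day crossing. Dispersion of
per-participant ranges is reported as their SD alongside the median; SD
was chosen over IQR/MAD and is recorded in the output so the convention is
explicit.

## The rhythm chain

1. **Percent of within-a-day maximum.** Each qualifying day is divided by
   its own maximum (×100), making profiles scale-free: multiplying a
   person's raw values by any constant changes nothing downstream (tested
   as an invariant).
2. **Linear interpolation** onto a 1-minute grid, only between the first
   and last observed minute — never extrapolated. Interpolated minutes
   exist for aggregation and display; they are excluded from hypothesis
   tests because they are not independent observations.
3. **Aggregation** across profiles by minute of day. The default statistic
   is the median (robust to a single person's extreme day); the mean is
   available.
4. **Two-hour centered moving average**, truncated at the profile's extent
   (no wraparound across midnight, since profiles rarely span it).
5. **Bounded sum-of-sines fit** `y(t) = d + Σ aₖ sin(bₖ t + cₖ)` with
   period 2π/bₖ box-constrained per component: the aggregate profile gets
   a half-day (10–12 h) plus daily (23–25 h) pair, individual profiles a
   single daily component. The offset `d` is essential — percent-of-max
   data live near 60–100, and without an offset no sine sum can reach
   R² ≈ 0.99 there; the adjusted R² penalty counts p = 3K + 1 parameters
   accordingly.
6. **Peak/trough test.** Observed percent-of-max values pooled in a
   morning trough window and an afternoon peak window are compared by a
   Kruskal–Wallis test (defaults 05:00–07:00 vs 15:00–17:00 for TC,
   09:00–11:00 vs 16:00–18:00 for TG — one trough/peak pair per analyte).
   Percent-of-max values are bounded and typically skewed, so a
   Kolmogorov–Smirnov check of standardized pooled values against the
   Normal is run first and its p recorded; the nonparametric test is used
   regardless of its outcome. α = 0.05 two-sided throughout. If every
   pooled value ties, H = 0 and p = 1 are reported with a degenerate flag
   rather than an error.

### Numerical strategy of the fit

For fixed periods the model is linear in `(d, aₖ sin cₖ, aₖ cos cₖ)`, so
`sinefit()` uses variable projection: an exact least-squares solve gives
the profiled SSE as a function of the period vector alone, and that smooth
1–2-dimensional function is minimized by box-bounded quasi-Newton
(`nlminb`) from a deterministic grid of 5 evenly spaced starting periods
per bound (factorial across components). This makes the fit deterministic
— no random restarts — and immune to the amplitude/phase local minima that
plague full nonlinear parameterizations. Amplitudes are recovered as
`√(α² + β²)` ≥ 0, phases via `atan2`. Degenerate constant input returns a
flagged zero-amplitude fit with undefined R²; fewer than 3K + 2 points is
an identifiability error. Parameter uncertainty, when wanted, comes from
the asymptotic Jacobian covariance (`vcov`, `confint`); these are
first-order approximations and the package makes no bootstrap claims.

The acrophase estimate is the clock time of the fitted curve's maximum on
a one-minute grid over the observed span, which stays meaningful when two
components interact.

### A known estimator limitation

With sampling restricted to 06:00–22:00 (two-thirds of a cycle), the
truncated-edge moving average slightly distorts the profile ends, and the
half-day component absorbs part of that distortion; the daily-component
*period* then tends to drift to a bound (23 or 25 h) even on noiseless
input, while the *acrophase* stays accurate to ~15–30 min. The property
tests therefore hold the period's median absolute error to ≤ 1 h (and the
acrophase's to ≤ 1 h, typically ~0.25 h). Sampling a full 24 h, or fitting
the unsmoothed aggregate, recovers the period to well under 0.1 h.

## The synthetic cohort

The generator exists so every downstream stage can be validated against
known ground truth. Its latent signal per participant and analyte is

    B · (1 + A_d cos(2π(t_h − φ_d)/P_d)) · (1 + A_u cos(2π(t_h − φ_u)/P_u))
      + M(day) + PP(t)

multiplicative daily and ultradian cosines on a Normal-drawn,
positive-clipped baseline `B`, plus an additive triangular menstrual
envelope `M` (TC only) and exponentially decaying postprandial bumps `PP`
(TG only). Multiplicative (relative-amplitude) rhythm components were
chosen because the analysis itself is scale-free: a relative amplitude
`A` yields a percent-of-max fluctuation of exactly `2A/(1 + A)`, so the
defaults `A = 0.25` (TC) and `A = 0.205` (TG) produce the 40 % and 34 %
of-maximum daily swings the analysis expects, both peaking at 16:00 with
1 h SD between-person acrophase dispersion (between-person phase spread is
reported in the circadian literature but not precisely known for lipids;
1 h is our configurable choice). HDL-c gets no daily component — it is the
built-in negative control. The TG ultradian component defaults to a 4 h
period; perceived hunger is an ordinal 0–3 discretization (quartiles of
the cosine range) of a cosine offset by π from it, i.e. antiphase.
Measurement noise is multiplicative Normal at 4.15 % CV, redrawn if a
value would be non-positive. Postprandial bumps default to +30 mg/dL
decaying with a 2 h time constant at meals 08:00/13:00/19:00 — a minimal,
conservative model, not a pharmacokinetic one.

Default problem sizes mirror the study conditions the analysis targets: 13
participants sampled hourly 06:00–22:00 for within-day analyses, 20
mornings for the fasted analyses, 20 simulated cohorts for
recovery/negative-control rates, 50 duplicate pairs for QC (5000 where a
Monte-Carlo expectation is being pinned down).

What the generator does *not* emulate: sleep/wake structure, seasonal
variation, diet composition effects, device drift between strip lots,
missing-not-at-random self-sampling, or any between-analyte correlation
beyond the shared schedule. Passing tests therefore demonstrate that the
pipeline recovers structure *of the kind assumed*, at realistic noise —
not that real free-living data are this clean.

## Device QC statistics

Imprecision is the percent CV of a time-paired duplicate,
`100·SD(a,b)/mean(a,b)` with the two-point sample SD (n − 1); it is
symmetric and scale-invariant. Note the two-point CV is biased low: at a
true device CV σ its expectation is σ·√(2/π) ≈ 0.80σ, so a cohort mean
paired CV near 3.3 % is exactly what a 4.15 % device produces — the QC
tests calibrate this expectation by Monte Carlo rather than pretending the
estimator is unbiased. Inaccuracy is plain percent disagreement with the
clinical reference, `100·|self − ref|/ref` — deliberately asymmetric
(reference in the denominator) and deliberately not the CLSI
bias + 1.96·CV construction, which answers a different question. Outliers
are reported, never clipped. Category agreement is the fraction of
clinical pairs classified identically; a 1 % disagreement straddling a
boundary counts as a miss, which is a property of categorical agreement,
not a bug. Pairs are linked by an explicit `pair_id`, never inferred from
timestamp proximity, so QC inputs are auditable.

## Reproducibility

`generate_cohort()` is byte-deterministic in its config (seed included)
and restores the session RNG state. `run_all()` writes every report with a
manifest (seed, config hash, artifact digests); regenerating with the same
config reproduces every artifact except the manifest's wall-clock
timestamp. `scripts/acceptance.R` recomputes the headline quantities from
scratch under a single `--seed`.

## Limitations

Beyond the period-estimator bias discussed above: individual fits on ≤ 17
points with 4 free parameters have wide sampling variability in adjusted
R²; the Kruskal–Wallis test treats pooled values as independent although
values from one participant share a normalizing maximum (its null
rejection rate was verified by simulation to sit near nominal, ~5 % at
α = 0.05, under the default conditions); and the menstrual envelope is a
deterministic triangle — real cycles vary in length and peak day, so
envelope *detection* on real data should expect more smear than the
generator produces.
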