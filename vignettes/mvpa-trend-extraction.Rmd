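---
title: "Extracting long-term MVPA trends from wearable heart-rate data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting long-term MVPA trends from wearable heart-rate data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Wearable fitness trackers record heart rate (HR) minute by minute for months
or years, which makes them attractive for studying how people's
moderate-vigorous physical activity (MVPA) changes over a long observation
window — for example, across the two academic years of a college cohort.
Raw tracker data, however, cannot be analysed like survey scores. Devices
are taken off or lose skin contact, so wear time varies by day and by
person; optical HR sensors drop out precisely during exertion (sweat and
band movement), carving gaps into the very episodes one wants to measure;
and a fixed population-level HR cutoff misclassifies activity because
resting and maximal heart rates differ between people and drift within a
person over time.

`mvpatrend` implements a complete, inspectable pipeline from raw
minute-level HR records to one label per subject — `positive`, `negative`,
or `none` — describing the long-term monotonic trend in that subject's
daily MVPA minutes.

```{r, eval = FALSE}
library(mvpatrend)

cfg <- synth_config(n_subjects = 10, seed = 1,
                    drift = c(rep(1.5, 3), rep(-1.5, 3), rep(0, 4)))
cohort <- generate_cohort(cfg)
ages <- setNames(cohort$truth$subjects$age, cohort$truth$subjects$subject_id)
result <- run_pipeline(cohort$days, cfg$calendar, ages = ages)
result$trends
```

## Pipeline stages and their parameters

### Wear-time compliance

Wear is defined as "an HR value was recorded this minute" — no further
off-wrist heuristic is applied. A day is *compliant* when at least a
fraction `daily_fraction` of its 1440 minutes is worn. The default 0.80
corresponds to `round(0.8 * 1440) = 1152` minutes (19.2 h; 19 h in whole
hours). The threshold is applied to the wear count *before* any imputation,
so imputation can never manufacture compliance. `wear_threshold_sweep()`
reproduces the curve used to choose such a threshold: the number of
eligible subject-days at every candidate fraction from 100% down to 0% in
steps of 10.

Subjects enter the analysis cohort only if the compliant-day count of their
*least compliant* semester is strictly above `min_days_per_semester`
(default 49, about half a semester). "Strictly above" follows from reading
the rule as *above the threshold*; the inclusive comparator is available
(`comparator = ">="`). Days inside excluded calendar ranges (scheduled
breaks) never count toward semester totals, because break-time wear is not
representative; whether to count them is genuinely open, and excluding them
is the stricter choice. Per-subject enrollment windows, when supplied,
prevent semesters that predate a subject's enrollment from counting as
zeros.

### Gap imputation

Within-day gaps are filled by linear interpolation between the flanking
present minutes, but only for interior gaps no longer than
`max_gap_minutes` (default 150 min, the longest gap length commonly seen in
tracker records); leading and trailing gaps have no flank on one side and
stay missing. Present values are never altered, the operation is
idempotent, and imputed values are kept real-valued — the downstream zone
test is a threshold comparison, and rounding to integer bpm would bias
minutes sitting exactly at the zone boundary. Imputation is restricted to
compliant days (at most 20% missing at the default threshold), so long
stretches are never fabricated.

The choice of linear interpolation is backed by a benchmarking harness
(`benchmark_imputation()`): complete 24-hour records are degraded by
deleting random non-overlapping blocks of 25, 50 and 150 minutes until
roughly 20% of the day is missing, each candidate imputer restores them,
and RMSE is pooled over all deleted minutes. Pooling (rather than averaging
per-day RMSEs) weights every deleted minute equally; the alternative is a
one-line change and in our experience does not reorder methods. The harness
accepts any imputer through a `function(day, cfg)` contract, so
state-space/Kalman smoothers can be compared without changing the harness.

### Personalized target heart zones

The MVPA threshold is the Karvonen zone minimum,

$$\mathrm{zone}_{\min} = (\mathrm{HR}_{\max} - \mathrm{RHR}) \cdot y + \mathrm{RHR},$$

with intensity constant $y = 0.5$ by default. The zone is recomputed for
every subject-day so that resting-HR changes over a long study move the
threshold with them. Maximal HR defaults to the age-predicted $220 -
\mathrm{age}$ (an explicit per-subject value overrides it); resting HR
comes from an input table when available, otherwise from the mean of the
day's 30 lowest present minute values. A minute is in the zone when its
(possibly imputed) HR is at or **above** the minimum — the zone has no
upper cutoff, since any higher intensity still is MVPA.

### Bout detection

MVPA only "counts" in bouts of at least `min_bout = 10` consecutive
in-zone minutes. Because a single minute's dropout or a momentary dip below
the threshold should not split an ongoing bout, in-zone runs separated by
at most `merge_gap = 1` out-of-zone minute are combined **before** the
10-minute filter; chains (run–dip–run–dip–run) collapse in one pass. Two
conventions were genuinely open and both are implemented:

* *merge-then-filter* (default) versus *filter-then-merge*
  (`merge_first = FALSE`), which merges only runs already of qualifying
  length;
* the bridged minute counts toward daily target minutes (elapsed-time
  accounting, default) or not (`count_bridged = FALSE`).

The defaults follow the motivation for merging — the HR was effectively in
the zone throughout — and the simplest consistent accounting. Daily
*target minutes* are the sum of bout durations.

### Monthly panel and trend extraction

Daily target minutes are downsampled to calendar months: the sum over a
subject's compliant days in the month, divided by the number of those
compliant days. This normalizes months shortened by breaks and unequal
wear. Months with zero compliant days become missing; leading/trailing
missing months shorten the subject's series, interior ones are linearly
interpolated before decomposition (decomposition needs a regular series; a
flag records which values were interpolated).

The series is decomposed additively — observed = trend + seasonal +
remainder — with seasonal period equal to the number of observed months per
repeating cycle (9 for a nine-month academic year). The decomposition is
classical: the trend is a centered moving average of window `period`
(simple mean for odd periods, so the first and last 4 positions are
undefined at period 9; the standard half-weighted 2×m window for even
periods), the seasonal component is the per-phase mean of the detrended
series re-centered to zero, and the remainder is the rest. The
implementation is the package's own so that the edge behaviour is fully
specified; `stats::decompose()` is used as an independent cross-check in
the test suite. With 18 observed months and period 9 this leaves 10 defined
trend points.

The defined trend points are tested with the Mann-Kendall statistic
$S = \sum_{i<j} \operatorname{sign}(x_j - x_i)$, tie-corrected variance
$\operatorname{Var}(S) = \left[n(n-1)(2n+5) - \sum_t t(t-1)(2t+5)\right]/18$,
the ±1 continuity correction for $Z$, and a two-sided normal p-value. The
two-sided test matches the question — upward *or* downward trend — with
direction read off the sign of $S$. The normal approximation is crude below
$n = 10$ and the package warns there; an exact-distribution option would be
a natural extension. A subject is labeled `positive` when $p < \alpha$ and
$S > 0$, `negative` when $p < \alpha$ and $S < 0$, otherwise `none`
($\alpha = 0.05$ by default).

`check_compliance_balance()` closes the loop with Kruskal-Wallis H-tests
comparing compliant-days-per-month distributions across label groups
(pooled and per month): if labels merely reflected *when* subjects wore the
device, these would reject.

### A caution on the calibration of the labels

The trend component handed to Mann-Kendall is a moving average, and its
increments at period 9 over 18 months turn out to be independent across
the 10 defined points — the defined trend of a *trendless* noisy series is
a short random walk. The Mann-Kendall null variance assumes exchangeable
observations and is therefore too small there: simulation in this
package's acceptance suite (60-subject cohorts, zero drift) puts the
false-label rate near 50% rather than the nominal 5%. The labels are
thus best read as a *screening* of the procedure's sensitivity to sustained
drift — for which the power is excellent — not as calibrated hypothesis
tests; a study wanting calibrated error rates should test the normalized
monthly series directly or adjust the reference distribution for the
smoothing. The package reports whatever the procedure produces and leaves
this interpretation to the analyst.

## The synthetic cohort

No public minute-level dataset accompanies this problem, so the package
ships a generator (`generate_cohort()`) whose defaults *are* the study
conditions the pipeline targets: 18 observed months in two nine-month
academic years (four semesters), period-9 seasonality, and 60 subjects per
cohort. Each subject has

* a circadian baseline — a sinusoid with trough (= resting HR) near 04:00
  and amplitude 12 bpm, plus Gaussian noise (sd 3 bpm);
* scheduled bouts with gamma-distributed durations (mean ≈ 21 min, clamped
  to 10–90) whose expected daily volume is
  `base (30 min/day) + drift × month + seasonal[phase]`, clamped at zero;
  plateaus sit 18 bpm above the subject's true zone minimum with 3-minute
  sub-zone ramps on each side, so with noise off the detected bouts equal
  the scheduled ones exactly;
* dropout gaps (Poisson rate 3/day; lengths geometric over 2–150 min, most
  mass at 2–25) whose start positions are 4× as likely during bouts,
  mimicking the exertion-dropout artifact; regular gaps never push a day
  below the compliance threshold;
* heavily-missing days (probability 0.12) that are guaranteed
  noncompliant, giving roughly 25–27 compliant days per month;
* a ground-truth label fixed by the sign of the injected drift.

A single global seed derives per-subject substreams by stable hashing, so
any subject's data are identical whatever the cohort size or ordering.
What the generator does **not** emulate: sleep architecture and
heart-rate variability, device-specific quantization, gradual sensor bias,
seasonal breaks *within* observed months, or resting-HR drift within a
subject. Passing the recovery tests therefore shows the pipeline correctly
extracts the signal it defines — sustained drift in bout volume under
realistic missingness — not that every property of real tracker data is
handled.

## Numerical choices and degenerate inputs

* Minute slots are 0-based `[0, 1440)`; a reading at `hh:mm` maps to slot
  `60·hh + mm`, seconds truncated. Days are forced to 1440 slots (daylight
  saving is not modeled; readings past slot 1439 cannot occur with clock
  timestamps).
* Ingest rejects, naming the line: unparseable timestamps, HR outside
  [25, 250] bpm, duplicate (subject, minute) rows. Absent minutes become
  explicit missing markers; a day with zero present minutes still exists so
  compliance denominators stay correct.
* Excluded calendar ranges and semesters are half-open `[start, end)` date
  intervals — an unambiguous boundary convention.
* The threshold sweep compares wear fractions with a `1e-9` tolerance so a
  day at exactly 70% wear counts at the 0.7 threshold despite binary
  representation of the step sequence.
* `delete_blocks()` forbids overlapping blocks, allows touching ones, and
  stops at the first deletion reaching the target fraction (the last block
  may overshoot: 12 × 25-min blocks = 300 deleted minutes ≈ 20.8%).
* A day with fewer than two present minutes passes through imputation
  unchanged; a subject whose trend has fewer than 3 defined points (or too
  few months to decompose) is labeled `none` with a warning rather than
  dropped silently.
* All-tied Mann-Kendall input has `Var(S) = 0` and is reported as
  `Z = 0, p = 1`.

## Problem sizes used by the tests and the acceptance script

The package's own verification uses sizes chosen to exercise every code
path while keeping a full run comfortable on one CPU: the bout-detection
oracle comparison uses 10,000 random masks of length ≤ 200; the
Mann-Kendall oracle runs the exhaustive grid of all 3,267 sequences of
length 3–7 over {0, 1, 2}; imputation properties use 1,000 random days;
and label recovery uses three seeded replicates of the default 60-subject
cohort (120 drifted subjects at ±1.5 min/day/month, 60 zero-drift
subjects). Larger replicate counts change none of the conclusions, only
the precision of the estimated rates.

## Known limitations

* The age-predicted maximal HR (220 − age) is a population proxy; measured
  maxima would sharpen zones, and the Karvonen threshold itself is a proxy
  for individual MVPA intensity.
* Only linear interpolation ships as an imputer; the benchmark harness is
  the extension point for model-based imputers.
* The Mann-Kendall labels are anticonservative on smoothed trends (see the
  caution above).
* Loess-based decomposition for non-seasonal series is a configuration
  hook, not implemented.
* The pipeline assumes local clock time; time zone changes and daylight
  saving are outside the model.
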