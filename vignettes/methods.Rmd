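---
title: "Methods: raw wrist accelerometry to daily physical-activity analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: raw wrist accelerometry to daily physical-activity analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methodology: the signal
model, every processing rule and its default, what the synthetic-data
generators emulate, and the decisions we made where the underlying protocol
left the design open. It states no empirical result that the test suite
does not itself compute.

# Signal model and processing conventions

## ENMO and epochs

The raw signal is triaxial acceleration in gravitational units at a fixed
sampling rate (protocol default 50 Hz, wrist-worn). Activity is quantified
as the Euclidean Norm Minus One,

$$\mathrm{ENMO}(x,y,z) = \max\!\big(\sqrt{x^2+y^2+z^2} - 1,\; 0\big),$$

i.e. the vector magnitude corrected for gravity with negative values
rounded to zero, averaged over 5-s epochs.

**Truncation order.** The wording "corrected for gravity with negative
values rounded to zero ... averaged over 5-s epochs" is ambiguous about
whether truncation happens per sample or per epoch mean. We truncate **per
sample before averaging** (the behaviour of the widely used raw-processing
software this pipeline mirrors): per-epoch truncation lets calibration
noise below 1 g cancel genuine activity above it, biasing epochs low. The
alternative is available as `truncate_per = "epoch"` and is covered by a
test showing exactly this cancellation.

**Alignment.** Epochs are half-open intervals $[t, t+5\,\mathrm{s})$
aligned to the recording start; trailing samples that do not fill a whole
epoch are dropped rather than padded (a partial mean over a few samples
would be noisy and biased). Days are civil half-open intervals
$[00{:}00, 24{:}00)$; all timestamps are local civil time with no timezone
arithmetic (single-site protocol).

## Non-wear detection

A 60-min window sliding in 15-min steps is classified non-wear when on at
least 2 of 3 axes the per-axis standard deviation is below 0.013 g **or**
the per-axis value range is below 0.050 g (strict inequalities, so boundary
behaviour is fixed and testable). An epoch is non-wear when any non-wear
window covers it; a final window aligned to the recording end guarantees
tail coverage. The protocol source names only "SD and value range per axis,
60-min windows"; the step, both thresholds and the axis count follow the
heuristic that source cites and are exposed as configuration keys
(`nonwear.window`, `nonwear.step`, `nonwear.sd_thresh`,
`nonwear.range_thresh`, `nonwear.min_axes`), not treated as protocol facts.
The 15-min step bounds the detection granularity: a planted 120-min block
is recovered within one step (±15 min), which the acceptance suite checks
over deliberately grid-misaligned placements.

## Calibration

`simple_calibrate()` is a deliberately simplified stand-in for full
auto-calibration using local gravity: static 10-s windows (all-axis SD
< 0.013 g) supply mean orientation vectors; if at least 10 exist spanning
at least two orientations (> 10° apart), per-axis offset and gain are fitted
by iterated least squares pulling static vectors onto the unit sphere (200
iterations; the iteration is linear-rate, and 200 passes recover a 0.05 g
offset to within 0.005 g on the test fixture). Without enough static
diversity it returns the recording unchanged with `applied = FALSE`.
Temperature compensation and idle-sleep handling are out of scope.

## Intensity classification, bouts, validity

ENMO cut-offs 0.03 / 0.1 / 0.4 g anchor light (≥ 2 METs), moderate
(≥ 3 METs) and vigorous (≥ 6 METs) activity. Boundaries are inclusive
upward — an epoch at exactly a cut-off enters the higher class — mirroring
the "≥ x METs" phrasing; sedentary is strictly below 0.03 g. Bouted MVPA
sums maximal runs of consecutive wear epochs at or above the moderate
cut-off lasting ≥ 10 min; "consecutive" is read strictly, so the default
interruption tolerance is 0 epochs (a tolerance parameter exists for
sensitivity analyses and merges runs separated by at most that many
non-MVPA epochs, counting only MVPA epochs within a qualifying bout).

A day is valid at ≥ 600 wear minutes (boundary inclusive: 7,200 five-second
epochs exactly qualify). Analysable days are measurement days 1–13 (day 1 =
first midnight; day 14 lacks a closing midnight in the processing
convention we follow and is excluded, with the exclusion logged). Week 1 is
days 1–7 and week 2 is days 8–13 — six candidate days. The subject-level
rule (≥ 4 valid weekdays and ≥ 1 valid weekend day *in each week*) is
applied to week 2 as written even though it has only six days; for a
Monday start this makes the single week-2 weekend day (the second Saturday)
decisive. Whether the original protocol evaluated week 2 on six or seven
days is not stated; our choice is explicit and configurable
(`n_analysis_days`, `min_valid_weekdays`, `min_valid_weekend`).

# Relative-intensity audit

The oxygen cost of an absolute intensity of $m$ METs relative to capacity
is $100 \cdot m \cdot 3.5 / \dot VO_{2peak}$ (%), with 1 MET = 3.5
mL·kg⁻¹·min⁻¹ — the standard convention, exposed as `met_value` since the
protocol never states it. Bands: LPA $[0, 46)$, MPA $[46, 64)$, VPA
$[64, 100]$ %VO2peak; exactly 100 % counts as VPA (the band is "64 to
100 %"), anything above 100 % exceeds capacity. The audit reports band
fractions per group and MET anchor plus where each anchor lands relative to
its intended band (2 METs → LPA, reported descriptively; 3 and 4.5 → MPA;
6 and 8 → VPA).

# Mixed models

Daily minutes are modelled as

$$y_{id} = \beta_0 + f(\text{factor}_{d}) + \beta_a \text{age}_i +
\beta_s \text{sex}_i + \beta_v \dot VO_{2peak,i} \,(+\, \beta_w
\text{wear}_{id}) + b_i + \varepsilon_{id},$$

with subject random intercept $b_i$, fitted by REML via lme4. Daily wear
time is a covariate for PA outcomes only (excluded when wear time is the
outcome). Reference levels: Monday, Spring, male. Factors: day of week
(7 levels), weekend + week index, measurement day (numeric 1–13,
reactivity trend), season (4 levels).

Design decisions where the protocol is silent:

* **Joint factor test**: likelihood-ratio test of the factor against the
  covariates-only model, both refitted by ML — well-defined for multi-level
  factors. Its finite-sample calibration is checked by simulation
  (type-I error within 5 % ± 2 % at α = 0.05 over 1,000 null fits of 40
  subjects × 13 days; "reduced n" is our choice balancing LRT calibration
  against runtime).
* **Heteroscedasticity weights** (`weights = "by_factor_level"`): inverse
  per-factor-level residual variances estimated from one unweighted fit,
  a single re-weighting pass. Under homoscedastic generation weighted and
  unweighted estimates agree (tested).
* **Confidence intervals**: normal approximation (± 1.96 SE), matching the
  estimate ± SE reporting convention; no Satterthwaite machinery.
* **Convergence** is a flag on the result, never an exception;
  rank-deficient fixed-effect designs error naming the collinear columns.

Sleep is compared weekday vs weekend by ordinary least squares (the
protocol's choice), and wear time between groups by the two-sided Wilcoxon
rank-sum test at α = 0.05.

# Most active 10-h window

For each day the 10-h window maximising in-window activity is found by
sliding one epoch at a time (slide granularity is not stated by the
protocol; epoch-level is the finest available and is recorded here). The
default metric is TPA minutes in-window; `enmo_sum` is available. Ties
break to the earliest start — a perfectly uniform day yields a 00:00 start
and 05:00 midpoint, which the tests pin down. Windows do not wrap past
midnight by default (a "day" is the civil day, consistent with the daily
summaries); `wrap = TRUE` treats the day as circular. The incremental
cumulative-sum implementation is tested against exhaustive evaluation of
every start epoch.

# Synthetic data: the stated world

The generators exist because the reference cohort's raw data were never
deposited; they emulate exactly the features the pipeline and models
consume, with known ground truth.

**Raw signals.** A segment schedule plants activity, non-wear and sleep
blocks. Activity samples are random unit directions scaled to norm
$1 + \text{target ENMO}$, so per-sample ENMO equals the target *exactly* —
truth round-trips through the pipeline with no tolerance. Quiet wear and
sleep are unit-norm directions (ENMO 0) following a slowly drifting gravity
vector (< 1°/min random walk) with 3–8° per-sample jitter: at most one axis
can sit near-constant, so wear can never satisfy the ≥ 2-axis non-wear
criterion. Non-wear blocks freeze orientation and add uniform ± 0.008 g
per-axis noise (SD ≈ 0.0046 g, range ≤ 0.016 g) — uniform rather than
Gaussian so that arbitrarily long blocks stay inside the detection
envelope with certainty. Not emulated: biomechanical spectral structure,
circadian autocorrelation, device temperature drift. A green pipeline test
therefore establishes rule correctness (classification, detection windows,
counting), not field performance on real wrist signals.

**Daily summaries.** Minutes per class are baseline + day-of-week effect +
season effect + reactivity × (day − 1) + subject intercept + i.i.d.
residual, truncated to [0, daily wear]. Every class receives the additive
effect, so composite outcomes (MVPA, TPA) carry it once per component
class. Wear time and sleep have small generator blocks of their own
(baseline 1,434 min — the published cohort mean — slope, between/within
SDs; sleep baseline 450 min with an optional weekend shift) because the
wear-trend and sleep-regression analyses need generated outcomes; the build
contract listed those models but gave the generator no fields for them.
Covariates follow the published cohort moments (age, sex proportion,
VO2peak mean/SD/range per group) via rejection-sampled truncated normals —
matching a printed mean/SD/range with minimal machinery. Note the
truncation raises the realised VO2peak mean slightly above the printed
mean (about +0.5 for the heart-failure moments); tests therefore check
against the analytic truncated-normal mean. No within-subject correlation
beyond the random intercept is generated, because the protocol implies
none.

`stagger_weeks` starts subjects on different (Monday-aligned) weeks across
the year, as in rolling recruitment: without it a single shared start date
confounds season completely and the season model is inestimable.

# Determinism and scales

Every generator is a pure function of (parameters, seed); seeds are derived
per stream and the caller's RNG state is restored. The end-to-end command
(`run-all`) is byte-reproducible given (config, seed), which the acceptance
suite verifies by hashing its outputs across two runs at the stated reduced
scale (2 raw subjects × 14 days at 1 Hz with 5-s epochs, plus a small model
cohort). Test fixtures use 5 Hz or 1 Hz sampling and 5-min oracle epochs
where the full 50 Hz / 5 s scale would add runtime without adding
discrimination; nothing about the rules under test depends on the rate.

# Known limitations

* Calibration is a simplified gravity-reference check, not the full
  published auto-calibration (no temperature term, no weighting by window
  quality).
* Sleep windows are accepted as annotations (or synthetic truth); the
  sleep-detection algorithm itself is out of scope.
* The proprietary device binary format is not parsed; raw input is a
  documented CSV dialect.
* The cohort's numerical results are not reproducible here — its raw data
  are available only on request — so all statistical guarantees are
  properties demonstrated on synthetic data at stated effect sizes, not
  replications.
* LRT p-values for factors are asymptotic; at very small cohort sizes they
  run slightly liberal, which is why the calibration simulation fixes the
  reduced size it certifies.
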