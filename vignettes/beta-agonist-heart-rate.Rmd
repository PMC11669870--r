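---
title: "Methods: estimating beta-2 agonist effects on heart rate from wearables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating beta-2 agonist effects on heart rate from wearables}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`beta2hr` implements two estimators for the cardiac side effects of inhaled
beta-2 agonists, together with the synthetic data-generating process used
to validate them. This vignette is the package's own account of the
science: the models, their assumptions, the tunable parameters, and the
places where a design had to be chosen rather than derived.

## Data model

Everything is minute-resolution, naive local clock time. A heart-rate (HR)
series holds one value per *worn* minute; an absent minute means the device
was off and is never zero-filled, because non-wear is informative and a
sentinel would contaminate means. Step series behave differently: step
counters emit zeros while worn, so during the analysis a missing step
minute inside a worn window counts as zero, and only a window with no wear
at all disqualifies an event. Timestamps are floored (not rounded) to the
minute; devices bucket "mean HR per minute", and a fixed convention keeps
the acknowledged ±1-minute alignment uncertainty reproducible. Daylight
saving does not exist in this representation: matching "11 AM to 11 AM" is
defined on the civil clock, which is exactly what naive time encodes.
Medication status (LABA user or not) is carried as inclusive date
intervals — the questionnaire analogue reports weeks, so a finer resolution
would be fictitious; a switch takes effect at its boundary date.

## The group comparison

The primary contrast is HR throughout the day between LABA and non-LABA
person-time. Wear time varies enormously between patients, so the
estimator is patient-first: per patient and status, the mean HR per clock
hour (minute `m` belongs to hour `floor(m/60)`); per group and hour, the
unweighted mean of those profiles; overall, the unweighted mean of the 24
hourly differences present in both groups. Duplicating a patient's wear
changes nothing — this invariance is tested. A patient contributes one
profile per status they ever held, so a switcher appears once in each
group.

Patients with fewer than `min_wear_minutes` worn minutes over follow-up
are removed first. The default is 10,080 — one week of continuous
minutes — with the stricter 25,200 (a week of 12-hour days) available
through the argument; the threshold is evaluated once on the whole
follow-up, not per week.

Uncertainty is reported twice, deliberately. A pooled-minute normal CI
treats every minute as an observation; with millions of minutes it
collapses onto the point estimate, which is informative about the
minute-level sampling error and reproduces the "CI equal to the estimate"
phenomenon that huge wearable datasets produce, but it ignores
between-patient variation. The patient-level bootstrap (default 200
resamples of the hourly profiles within each group, percentile interval)
is the honest uncertainty for the patient-first estimand. Neither is
claimed to be *the* method; they answer different questions and are
labelled accordingly. With fewer than two profiles in a group the
bootstrap is skipped with a warning.

## The self-controlled event study

SABA use is as-needed, so each patient is their own control. For an
actuation at clock minute `m` on date `d`, the reference is the mean HR at
clock minute `m + r` over control days: the nearest ≤ 50 dates before `d`
and ≤ 50 after on which the patient used no SABA and wore the device. The
caps are per side — when only 30 eligible days exist before, the set is
30 + 50, never topped up — reading "50 before and 50 after" literally.
Minutes shifted past midnight are read from the adjacent calendar date.
Self-matching on the clock removes stable between-person differences and
the circadian rhythm in one stroke; a property test verifies that shifting
the generator's acrophase by six hours leaves the recovered landmarks
unchanged up to Monte-Carlo noise.

A control mean built on very few days would be noise, so a relative minute
needs at least `min_control_days` (default 10) control-day values to be
defined. No such rule is inherent to the design — it is a documented,
configurable addition, and small test fixtures lower it.

Exercise is the dominant confounder: relievers are often taken right
before or during exertion. An event is excluded when its step total in the
±60-minute inhalation window strictly exceeds the control-day mean + 2 SD
of the same clock window (sample SD over ≥ 2 covered control days;
equality keeps the event, matching "exceeds"). The filter is
deliberately one-sided — unusually *low* activity never excludes.

At each relative minute the curve takes the included events that have both
an event-day value and a defined control mean there, and reports the
difference of their two means — a paired contrast, so partial wear cannot
misalign the two sides of the subtraction. Minutes failing coverage are
undefined, never zero. Every actuation is an event, including actuations
inside a previous event's window (the data cannot distinguish a second
dose from a new episode); `refractory_min` optionally drops close
repeats, default off.

The unsmoothed curve is summarised by crossings of the 5 bpm threshold —
the level at which cardiological meta-regression of beta-blockade suggests
a sustained change becomes clinically relevant: first pre-event exceedance
(scanning forward from −180), value at minute 0, peak location and height
(first minute of the maximum on ties), and the return time as *last
exceeding minute + 1*, i.e. the first minute after which no exceedance
occurs. The convention matters at the boundary: a curve whose final ≥ 5
bpm minute is 137 reports 138. Smoothing — degree-1 local regression with
tricube weights, span 0.15 of the defined minutes (`stats::loess`) — is
for display and variance reduction only; crossings are always read off the
raw curve because smoothing drags the shallow decay crossing.

For LABA/ICS_LABA actuations no SABA-free reference exists (maintenance
dosing follows the clock, so any "control day" would carry the same
circadian phase and the subtraction would be confounded); the event-aligned
raw mean curve is reported instead, without crossings.

## The synthetic cohort

The generator (`cohort_config()` + `simulate_cohort()`) produces, per
patient: worn-minute HR, steps, an actuation log and a medication
timeline. HR at a worn minute is

    cosinor(mesor, amplitude, acrophase)
      + laba_offset · 1[LABA user]            (scalar or 24-hour profile)
      + Σ drug-effect kernels of nearby actuations
      + activity_gain · 10-min trailing mean of steps
      + N(0, hr_noise_sd²),

clipped to [35, 220] bpm (never binding under defaults) and quantised to
0.1 bpm. Defaults: mesor 70 bpm, amplitude 5 bpm, acrophase 15:00, noise
SD 6 bpm, LABA offset +0.8 bpm, activity gain 0.3 bpm per smoothed
step/min (a brisk 80 steps/min bout raises HR ≈ 24 bpm). Noise is i.i.d.
by default so test tolerances stay closed-form; an AR(1) option exists but
is off.

The drug-effect kernel is anchored at observable landmarks, not
pharmacokinetic constants, because only landmarks are observable in a
minute-level difference curve: zero before `−onset_lead`, linear rise
through `(0, value_at_t0)` to `(peak_lag, peak_amp)`, then exponential
decay with rate `log(peak_amp/threshold)/(return_min − peak_lag)` so the
curve equals the threshold *exactly* at `return_min`. The reference SABA
profile is 9 bpm at t0, 10 bpm at +9 min, back to 5 bpm at 138 min. Its
onset is solved, not free: a linear ramp ending at 9 bpm that first
reaches 5 bpm at −17 min must start at `17·9/(9−5) = 38.25` min before
actuation. (Specifying the onset at 17 min instead would put the 5-bpm
crossing near −8 min and contradict the profile it is meant to encode.)
The pre-actuation ramp deliberately conflates dyspnea arousal with drug
effect — minute-level observational data cannot separate them, so neither
does the generator. Note one boundary consequence: since the kernel
*equals* the threshold at `return_min` and crossings use ≥, the noise-free
kernel's reported return is `return_min + 1`.

SABA timing follows a routine-reliever pattern: a day has 0/1/2 uses with
probabilities (0.130, 0.765, 0.105) — just under one per day — the first
drawn from a daytime profile with an 8 AM peak, the second 8–12 h later.
This reflects maintenance-like reliever use before daily activity
(morning-peaked, occasionally repeated in the evening) and keeps same-day
actuations well separated, so one event's long decay tail does not sit
inside another event's analysis window; with e.g. Poisson daily counts at
the same rate, overlapping kernels would shift the estimated baseline by
1–2 bpm and the recovered return time by tens of minutes — a bias of the
*scenario*, not of the estimator. Half of SABA uses (configurable) are
coupled to an exercise bout spanning −30…+90 min, the structure the step
filter must detect. Maintenance doses land near 08:00 and 20:30 with 84%
per-dose adherence (ICS_LABA for users, ICS otherwise).

Wear: each minute survives with probability `day_retention` (default
0.95), night minutes (00:00–06:00) with `night_retention`, solved in
closed form so the expected share of recorded minutes at night is 18.7%:
`p = 3·d·f/(1−f)`. Charging gaps (default: 120 min on 30% of days)
start at a uniform clock minute, so they thin day and night
proportionally and leave that share unbiased.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: between-patient heterogeneity in circadian
parameters or drug response (every simulated patient shares one mesor and
one kernel, so group-level uncertainty on real cohorts will be wider than
the recovery experiments suggest); autocorrelated or non-Gaussian HR
noise; activity that raises HR without steps (cycling, weightlifting);
device measurement bias; dose–response or tolerance effects; seasonal
structure.

## Numerical and testing choices

Determinism: per-patient seeds derive from the master seed, so equal seeds
give bit-identical bundles. Degenerate inputs have defined behaviour: an
empty control set, an all-excluded event list, or a single-group cohort
raise classed errors naming the dominant reason; a curve undefined at
minute 0 reports `NA` landmarks rather than failing. Equality with the
brute-force oracle is asserted to 1e−10 (sums accumulate in different
orders). Bundle round-trips through CSV write values with `%.10g`.

Problem sizes: the recovery experiments use the study conditions (40
patients × 60 days over 50 seeds for the group contrast; 20 × 120 over 10
seeds, ≈ 2,200 actuations, for the event study); null calibration uses 100
seeds of 10 × 30 cohorts; oracle equivalence uses ≤ 3 patients × 10 days,
where the nested-loop reference is feasible. Statistical properties are
asserted with ≥ 4-sigma margins of their binomial or Gaussian tolerance.

## Known limitations

The return-time landmark is intrinsically fragile: the difference curve
crosses the threshold at ≈ 0.03 bpm/min, so any baseline shift `b` moves
the crossing by `b/0.03` minutes, and minute-level noise extends the last
exceedance past the deterministic crossing by a few minutes. Medians over
seeds are reported for exactly this reason. The step filter conditions on
low event-window activity and therefore trims a fraction of a bpm from the
curve around minute 0 (a selection effect, visible as slightly conservative
t0 values). No formal hypothesis test is attached to the difference curve,
and no multiple-testing correction across its 781 minutes — the estimand
is the curve itself, summarised by pre-registered-style landmarks.
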