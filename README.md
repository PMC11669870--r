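# beta2hr

Heart-rate side effects of inhaled beta-2 agonists, estimated from
minute-resolution wearable data and smart-inhaler actuation logs.

Inhaled beta-2 agonists dilate the airways of people with asthma by
stimulating beta-2 adrenoceptors — receptors that also sit on cardiac
cells, so a tachycardic side effect is plausible. With a wrist-worn tracker
recording heart rate (HR) and steps every minute, and an inhaler add-on
logging the exact minute of every actuation, that side effect can be
studied in daily life. `beta2hr` is for biostatisticians and mHealth
researchers who want to run (or stress-test) that analysis.

## What it computes

**Cohort comparison by LABA status.** For long-acting beta-2 agonists
(LABA, twice-daily maintenance therapy) the package compares HR throughout
the day between LABA and non-LABA person-time. To keep heavy wearers from
dominating, aggregation is patient-first: for patient *i* with status *g*
the hourly profile is

&nbsp;&nbsp;&nbsp;&nbsp;x̄<sub>i,g</sub>(h) = mean of all worn minutes of
patient *i* in clock hour *h*,

the group curve is the unweighted mean of the profiles, and the overall
contrast is Δ = (1/24) Σ<sub>h</sub> [x̄<sub>laba</sub>(h) −
x̄<sub>non</sub>(h)]. Both a pooled-minute normal CI (which degenerates to
the point estimate at millions of minutes) and a patient-level bootstrap CI
are reported. Patients wearing the device less than a configurable total
(default one week of minutes, 10,080) are removed first; a patient who
starts or stops LABA switches groups at the reported date.

**Self-controlled SABA event study.** Short-acting beta-2 agonists (SABA)
are used as needed, so each patient serves as their own control. Around
every actuation at clock minute *m* on day *d*, the curve

&nbsp;&nbsp;&nbsp;&nbsp;D(r) = mean<sub>events</sub> [ HR(d, m + r) −
mean<sub>control days c</sub> HR(c, m + r) ],&nbsp;&nbsp; r = −180 … +600,

is computed over the nearest ≤ 50 SABA-free days before and ≤ 50 after each
event, matched at the same clock minute (spilling across midnight as
needed). Because SABAs are often taken around exercise, an event is dropped
when its steps in the ±1 h inhalation window exceed the control-day mean
+ 2 SD. The unsmoothed curve is summarised by threshold crossings at the
clinically relevant 5 bpm: first pre-event exceedance, value at the
actuation minute, peak lag and amplitude, and the return time (first minute
after the last ≥ 5 bpm exceedance). A degree-1 tricube local regression
(span 0.15) provides the display smooth.

**Synthetic wearable cohorts.** No patient data are shipped. The generator
builds cohorts with the structure the estimators assume: a cosinor
circadian rhythm; an additive LABA offset (constant or by hour of day); a
piecewise drug-effect kernel at each actuation (linear rise through the
actuation minute, exponential decay anchored so the curve equals the
threshold exactly at the return time); exercise bouts that drive HR through
a smoothed step rate, half of them glued to SABA actuations (−30…+90 min);
morning-peaked reliever schedules and twice-daily maintenance dosing with
84% adherence; and a wear model with charging gaps and reduced night
retention solved to yield an 18.7% nighttime data share.

## Worked example

```r
library(beta2hr)
cfg <- cohort_config(n_patients = 12, days_per_patient = 90)
b <- simulate_cohort(cfg, 42)
b
#> Cohort bundle: 12 patient(s)
#>   heart-rate minutes: 1329970
#>   step minutes (>0 or recorded): 108350
#>   inhaler actuations: 2794 (ICS 601, ICS_LABA 1197, SABA 996)
#>   medication-status intervals: 12

group_comparison(b, seed = 1)
#> Heart rate by LABA status (patient-first hourly comparison)
#>   patient segments: 8 LABA, 4 non-LABA
#>   overall LABA - non-LABA difference: 0.80 bpm
#>   pooled-minute estimate 0.79 bpm, 95% CI [0.76, 0.83]
#>   patient bootstrap 95% CI [0.65, 0.98]

event_study(b, "SABA")
#> Event study around SABA actuations
#>   events: 996 total, 471 included (525 step-excluded, 0 without controls, 0 without wear)
#> Threshold-crossing summary (threshold 5.0 bpm, 781 defined minutes)
#>   first pre-event exceedance: -15 min
#>   value at actuation minute: 9.36 bpm
#>   peak: 10.35 bpm at +7 min
#>   return below threshold after: 155 min
```

The generator injected a 0.8 bpm LABA offset and a SABA kernel that is
9 bpm at the actuation minute, peaks at 10 bpm nine minutes later, and
decays to 5 bpm at 138 minutes: the group comparison recovers the offset
exactly here, and the event study recovers the landmarks to within the
Monte-Carlo noise of ~500 included events (the return time is the most
fragile landmark because the curve crosses the threshold at a very shallow
slope). `run_pipeline()` executes the whole analysis from one config (R
list or YAML) and writes curves, summaries, figures and a run log;
`plot()`, `summary()`, `coef()` and `confint()` methods work on both fits.

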