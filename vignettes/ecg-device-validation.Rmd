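---
title: "Validating wearable ECG sensors against a criterion ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating wearable ECG sensors against a criterion ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgvalidate)
```

## The problem

Chest-strap wearables promise laboratory-grade heart-beat timing at consumer
prices, but their validity must be established against a criterion
electrocardiogram — and exercise is the hard case: motion artifact, sweat,
electrode lift-off and beat rates three to four times resting values all
degrade detection exactly when the data are most interesting. `ecgvalidate`
implements the full validation workflow for this setting: reading the device
streams, detecting R-peaks robustly across rest and incremental exercise,
synchronising streams recorded by independent clocks, and computing the
agreement statistics by which such devices are judged.

Three stream types are supported, mirroring what the devices export:

* a **criterion ECG** as plain text: a header with the recording-start epoch
  and one voltage (µV) per row at 1000 Hz;
* a **chest-sensor ECG** as a CSV of 16-sample packets (µV) at 500 Hz, each
  packet carrying a relative timestamp, with a global start epoch;
* an **RR-interval export** as a CSV of per-beat timestamps (in FIT-epoch
  seconds — seconds since midnight 31 December 1989 UTC, offset
  631,065,600 s from the Unix epoch) and RR′ values in ms, where 5000 ms is
  a sentinel code meaning "no beat detected in the preceding 5 s".

No resampling or filtering is ever applied on load; analysis runs at each
stream's native rate.

## The R-peak detection algorithm

`detect_rpeaks()` is built for exercise recordings, where a single global
threshold fails because amplitude and rate both drift.

**Interval segmentation.** The record is split into 10 s windows
(`interval_s`). Ten seconds is short enough that heart rate moves little
within a window even during an incremental ramp (a 70 bpm/min ramp changes
RR′ by only a few percent per window), and long enough to hold 5–40 beats
for stable threshold statistics. Each window is detected with ±250 ms of
context so a QRS apex on a window boundary is still a local maximum;
candidates outside the half-open core are discarded.

**Dual-polarity passes.** Electrode placement can make the S deflection
dominant, so every window is searched twice: once upright ("R" pass) and
once on the negated signal ("S" pass). The merge step collapses candidates
from the two passes that fall within one refractory period (200 ms — no two
true beats can be closer) into a single event, keeping the time of the
larger-magnitude lobe. Preferring the dominant lobe rather than the upright
pass unconditionally is what makes detection invariant to flipping the
signal's sign.

**Voltage-sorted threshold search.** Within a window the candidate
thresholds are the descending 1-percentile quantiles of the (median-centred)
voltage, from the 99th down to the 50th. Each threshold implies an event
count: supra-threshold local maxima, with maxima inside one refractory
window collapsed to their largest sample (they cannot be distinct beats).
The accepted threshold is the highest one inside the *widest stable
plateau* — the run of consecutive thresholds giving the same plausible count
(30–240 bpm for the window length) that spans the largest voltage range.
The plateau criterion matters: taking simply the highest plausible threshold
clips the weakest apexes whenever T-wave overlap or baseline wander
modulates QRS amplitude at high heart rates, silently handing those beats to
the opposite-polarity pass ~40 ms off. A noise floor (threshold must exceed
`noise_floor_mads` = 5 times the window MAD) keeps windows containing only
noise from producing spurious "plausible" solutions.

**Statistical repair.** From the merged beat list, RR′ intervals are
screened against a rolling 11-interval local median: an interval is flagged
when it deviates by more than `anomaly_k` = 4 local MADs (floored at 5 ms so
sampling-grid quantisation of a steady rhythm cannot trigger) or breaches
the ratio gates 1.8×/0.55× of the local median. The rolling median tracks
gradual exercise drift (resting ~930 ms down to ~390 ms mean RR′ over a
ramp), so only step changes — a missed or spurious beat — are flagged.
Repairs act on the ratio-gated flags only: for a long gap the expected beat
positions are re-searched in the raw signal (±150 ms, accepting the best
extremum above half the interval's threshold); for a short gap the
weaker peak is removed only if the merged interval lands within
[0.7, 1.4]× the local median. MAD-only flags are reported in the
diagnostics but never acted on — chasing ordinary beat-to-beat variability
destabilised clean recordings. The detect→flag→repair loop iterates
(intervals with clustered anomalies are re-detected with a lowered starting
quantile) until a pass makes no change, capped at 5 iterations. The whole
pipeline is deterministic.

## Synchronisation

Streams carry global Unix-epoch timestamps, so residual misalignment is a
constant per-device clock error. `refine_by_rr_correlation()` resamples
both RR′ series onto a common 250 ms tachogram grid (piecewise-constant RR′
against time — correlating on time, not beat index, keeps missed beats from
de-phasing the comparison), winsorises each tachogram at median ± 3 MAD (a
missed beat doubles the local RR′ and would otherwise dominate the
correlation as an uncorrelated outlier), and scans offsets on a 50 ms grid
over ±30 s, refining the optimum parabolically. The returned offset is
*added to device times* to map them onto the criterion timeline; an
alignment with peak correlation below 0.5 is flagged unverified and
`apply_alignment()` refuses it without an explicit override. A single
constant offset is estimated per stream; clock drift (linear skew) is out
of scope.

## Validation statistics

**Beat matching.** `match_peaks()` pairs criterion and device beats
one-to-one, greedily in time order, each criterion beat taking the closest
unconsumed device beat within 100 ms (inclusive). The window is wider than
the 75 ms sometimes used because RR-only devices timestamp beats through
their own pipeline; one-to-one pairing is physiologically forced by the
200 ms refractory period. Unmatched criterion beats are FN, unmatched
device beats FP.

**Confusion rates.** Event detection on a continuous signal has no natural
negative class, so true negatives are counted at the criterion sampling
rate: `TN = total samples − TP − FN − FP`. The detection error rate is
`DER = (FP + FN) / (TP + TN + FP + FN) · 100`. These are conventions, not
universals; they are the definitions under which the package reproduces the
published specificity/accuracy/DER of both devices from their printed count
totals (one published RR-device specificity value is not reproducible from
its own printed TN and FP under any standard formula, and is left as a
documented discrepancy rather than matched).

**Agreement.** RR′ pairs are formed only where two *consecutive* criterion
beats are both matched; intervals spanning a missed beat are excluded
rather than compared to a summed interval, which keeps Bland–Altman
differences interpretable. `bland_altman()` reports mean, sample SD
(n − 1), and mean ± 1.96 SD limits of agreement. `icc3_single()` implements
ICC(3,1) — two-way mixed, single measure, consistency form,
`(MS_rows − MS_err)/(MS_rows + (k−1) MS_err)` — chosen because the devices
are fixed "raters"; the consistency form ignores a constant offset between
devices. Stratified reports pool by summing counts and then computing
rates, never by averaging per-stratum rates.

## The synthetic-data generator

No recordings ship with the package; `make_study_fixture()` generates
ground-truthed sessions emulating the validation study design:

* **Protocol.** The default `protocol_profile()` mirrors a laboratory
  session: 5 min seated rest, 6 min warm-up, a 10 min incremental ramp to
  195 bpm, 6 min cool-down, 5 min final rest; resting HR 65 bpm. Segment
  SDNN targets (95/55/40/40/25 ms) descend from rest to post-exercise rest,
  matching the published per-activity RR′-SD scale.
* **Beat times** come from integrate-and-fire on the piecewise-linear
  instantaneous-HR trajectory plus white Gaussian RR′ jitter at the segment
  SDNN, floored at max(250 ms, half the local period). White jitter is
  sufficient for SD-based agreement metrics; no autonomic spectral
  structure (LF/HF, respiratory coupling) is simulated.
* **Waveforms** are analytic templates — Gaussian R lobe centred exactly on
  the true beat time, opposite-sign S lobe half a QRS width later, broad
  low T wave, optional sinusoidal wander and white noise — rather than a
  dynamical-model simulator: detector testing needs controllable apex times
  and R:S ratios, not full PQRST realism.
* **Degradations** reproduce the failure modes seen in commercial
  RR-interval straps: random per-beat misses (optionally gated to high HR),
  periodic every-k-th-beat misses (k = 2 halves the apparent HR — the
  "half-rate diagonal" seen in device-vs-criterion HR scatter), spurious
  beats, Gaussian timing jitter, clock offset, and 5000 ms sentinels after
  detection gaps.

Passing tests on these fixtures show the pipeline's arithmetic and its
robustness to the modelled degradations; they do not certify performance on
real electrode noise, motion artifact with autocorrelated structure, ectopy
or pathological morphologies, none of which the generator attempts.

## Numerical and design choices

* All times are Unix epoch milliseconds; peak times always coincide exactly
  with a sample time (argmax sample, plateau ties to the earliest sample).
* Quantisation: a 500 Hz device matched against a 1000 Hz criterion has
  beat-time error up to ~1.5 ms; paired RR′ differences on clean fixtures
  therefore show SD ≈ 1 ms — the floor the tests assert against.
* FIT-epoch offset is the calendar-exact 631,065,600 s (7304 days of
  1970-01-01→1989-12-31), verified against R's own POSIX calendar.
* The disconnection rule cuts a record at the first 2 s window with
  peak-to-peak range below 50 µV; both values are configurable since the
  underlying phenomenon ("almost absent voltage, flat signal") is
  qualitative.
* Sample SD (n − 1) everywhere; percentages displayed at 2 decimals in
  reports, computed at full precision.
* Stochastic tests fix seeds; test problem sizes (e.g. 2 min sessions,
  5-subject fixtures, 5000-beat Bernoulli runs, 2000 jitter pairs) are
  chosen so every statistical check has the power its tolerance implies
  while the suite stays fast.

## Known limitations

* Single constant clock offset per stream; no drift estimation.
* The detector delineates R-peak times only — no QRS onset/offset, QT, or
  arrhythmia classification.
* Greedy nearest matching is not a globally optimal assignment; with a
  100 ms window against a 200 ms refractory the difference is immaterial.
* The generator's noise is white; real motion artifact is coloured and
  transient, and real baseline wander is not a single sinusoid.
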