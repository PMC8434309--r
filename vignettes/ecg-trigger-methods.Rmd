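---
title: "ECG-gated triggering: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ECG-gated triggering: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgsync)
```

## The conversion model

`ecgsync` models a real-time ECG synchronizer: a device that watches a
single-channel ECG and emits a TTL pulse at a chosen phase of each
cardiac cycle so that an external instrument can measure with the heart
in a repeatable mechanical state.  The detection target is the steep
upstroke of the R-wave, isolated by two devices working together:

* a **derivative estimate**, the un-normalized two-sample difference
  `ecg(t + Δt) − ecg(t)` on the loop tick Δt.  Differencing acts as a
  high-pass filter: slow drift (baseline wander from respiration or
  electrode motion) contributes only its per-tick increment, orders of
  magnitude below the R upstroke, while the sharp QRS slope survives.
  The difference is deliberately not divided by Δt — the threshold
  lives in the same units, so the scale factor cancels;
* an **adaptive decaying threshold**.  At each detection the threshold
  is re-captured from the signal (`thr ← ecg'`), then decays by a
  factor `(1 − x)` every tick until the next crossing.  The decay must
  be slow enough not to reach noise and T/P-wave slopes within one
  beat, yet fast enough to follow genuine amplitude drops.

Triggering is prospective: after the i-th detection at `ti` with period
estimate `Tj`, the line is scheduled to rise at the first tick strictly
after `ti + (Tj − dtMP)` — `dtMP` seconds ahead of the *next predicted*
derivative maximum.  The pulse is lowered at the first tick at which it
has been high at least the pulse width.  Output is suppressed until two
detections exist, because no period estimate exists earlier.

### Assumptions

* A dominant positive R upstroke: only positive differences can cross
  the (always positive) threshold, so negative-going complexes are out
  of scope.
* Quasi-stationary rhythm: the schedule predicts beat `i + 1` from the
  single last interval, with no plausibility filtering by default.  An
  optional `min_hr`/`max_hr` clamp exists but is off, matching the
  modeled device.
* Amplitudes are dimensionless: the threshold re-capture makes every
  detection decision invariant under `ecg ← c · ecg` for any `c > 0`,
  which the test suite asserts bit-exactly.

## Parameters

| parameter     | default  | units   | role |
|---------------|----------|---------|------|
| `tick`        | 0.005    | s       | loop interval; difference spacing; the grid every event snaps to |
| `decay_rate`  | 0.0014   | per tick| threshold decay x; at 60 bpm the threshold falls to ≈ 0.76 of its captured value over one beat |
| `refractory`  | 0.020    | s       | crossing suppression after a detection (strictly more than 20 ms must elapse) |
| `pulse_width` | 0.025    | s       | minimum TTL high time, tick-quantized upward |
| `dt_mp`       | 0        | s       | trigger lead relative to the next predicted derivative maximum |
| `decay_law`   | first_order | —    | `thr·(1−x)`, or `thr·exp(−thr·x)` as `true_exponential` |

The `true_exponential` variant is implemented exactly as stated in its
source, with the current threshold in the exponent.  That form is
dimensionally odd (the decay rate then depends on signal amplitude,
which breaks scale invariance) and is plausibly a typo for
`exp(−x)`, but the package does not guess intent: the printed formula
is what runs, and the default remains `first_order`.

## The synthetic world

`generate_ecg()` renders each beat as five Gaussian bumps (P, Q, R, S,
T) with amplitudes (0.12, −0.10, 1.00, −0.20, 0.30) in arbitrary
units.  Wave centers are placed as fractions of the beat period; Q and
S sit at ∓0.012 of the beat so that the 3σ QRS span stays under the
physiological 100 ms bound across the supported 40–180 bpm range (the
initial choice of ∓0.018 violated that bound at 40 bpm once scaled by a
1.5 s beat, and the overwide QRS produced a double-detection limit
cycle — the constraint is not cosmetic).  Beat periods are truncated
normal with mean `60/mean_hr` and fractional SD `hr_variability`;
broadband sensor noise is additive white Gaussian.

Stressors mirror the bench-adjustment protocol: a pure sinusoid for
baseline wander (default 50% of the R amplitude at 0.3 Hz, a typical
respiratory rate, since no amplitude or frequency is prescribed
anywhere) and transient motion artifacts, either a step offset or a
25 Hz burst under a raised-cosine envelope confined to its window.
Ground-truth annotations list each beat's R-peak time exactly and
describe the clean beat process: stressors never move them.

What the generator does **not** emulate: real QRS morphology variation,
ectopy and arrhythmia, electrode pop, powerline interference, or any
pathological rhythm.  A green test therefore establishes that the
algorithm is implemented correctly and behaves as designed under the
stated stressors — it does not certify clinical performance, and the
in-vivo error rates of the modeled device are not reproducible here
because the source recordings are unpublished.  The desk benchmarks
reproduce the *adjustment-stage* result (zero errors on the
wander-stressed demonstration trace) and property-level substitutes for
the rest.

## Numerical and design choices

* **Grid arithmetic.**  All comparisons run on integer tick indices;
  "strictly after" targets use `floor(q + 1e-9) + 1` so that an
  on-grid target maps to the next tick rather than itself, and float
  noise of a few ulps cannot shift an edge.
* **Initialization.**  The modeled device starts clairvoyantly at a
  derivative maximum; an online algorithm cannot.  The threshold is
  seeded from the first tick's |difference| (floored at 1e-9 to keep it
  positive) and the re-capture rule takes over.  Consequence: before
  the first R-wave the threshold sits at baseline-slope level and the
  detector chatters; the warm-up convention absorbs this.  One subtle
  residue remains: the first genuine R upstroke is usually crossed
  twice (the second crossing just past the 20 ms refractory), so the
  first period estimate is short by up to `refractory + tick` and the
  third-cycle trigger inherits that error.  From the next cycle on,
  periods are exact.  Timing properties are therefore asserted from the
  fourth cycle; the third-cycle offset is left visible in the Δt
  statistics.
* **Warm-up accounting.**  The first two annotated cycles are excluded
  from `n_cycles` and FN counting (no trigger can exist there), and
  edges are classified only inside
  `[truth[3] − window, truth[last] + window]`: initialization chatter
  and the trailing trigger aimed at the first beat after the
  annotation span belong to cycles outside the evaluated surface, and
  counting them would score cycles the denominator excludes.
* **Matching window.**  `min(150 ms, 0.4 · median RR)`: wider than the
  trigger advances actually observed, narrower than half a cycle, so a
  mid-cycle false positive can never be absorbed as a match.  The
  standard deviation of Δt is the sample (n−1) form.
* **Ideal trigger train.**  References default to offline
  derivative-maximum times (the quantity the algorithm chases);
  ground-truth R peaks are an alternative reference, flagged in the
  report.  The first two references are dropped to mirror warm-up.
* **Pending triggers.**  Detection and pulse logic run concurrently on
  the tick.  With `dt_mp = 0` a scheduled edge comes due one tick
  *after* the next detection, so a new detection must not overwrite an
  unfired schedule: pending triggers sit in a small FIFO; any schedule
  coming due while the line is already high is swallowed (the pulse is
  not extended), which both keeps every rising edge traceable to one
  scheduling event and produces the stuck-high FN phenomenology when
  the pulse outlasts a beat.
* **Ties and clamps.**  If `pulse_width < tick`, raise wins and the
  line falls on the next tick, keeping every pulse visible.  If
  `dt_mp ≥ Tj` the request cannot be honored; the trigger clamps to
  the next tick and a warning is logged once per run.
* **Degenerate inputs.**  Non-positive thresholds, non-increasing
  detection times, off-grid step times, signals shorter than two ticks
  and empty reference lists all fail fast with typed errors rather
  than propagating corrupt state.
* **Batch cross-check.**  `run_batch()` re-derives the same TTL trace
  non-causally: closed-form decay powers, jump scan to the next
  crossing, and interval painting.  Streaming and batch must agree
  sample-for-sample; the suite asserts bit-identity on 100 randomized
  traces.  Under the `true_exponential` law no closed form exists and
  the batch scan falls back to explicit decay iteration.

## Known limitations

* Single-lead, positive-upstroke ECG only; no arrhythmia handling — a
  premature beat simply resets the period estimate.
* The period predictor uses one interval; a run of short/long intervals
  propagates one mistimed trigger per change.
* The WFDB reader covers single-file records in formats 16 and 212
  without skew/offset modifiers — enough for the common PhysioNet ECG
  databases, not the full specification.
* Wall-clock real-time guarantees, serial interfacing and hardware
  concerns are out of scope; the tick is the only notion of time.
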