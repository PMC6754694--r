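---
title: "Band-limited HRV biofeedback: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-limited HRV biofeedback: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvband)
```

`hrvband` models a self-delivered HRV-biofeedback training protocol from the
heartbeat up: interbeat intervals (IBIs) stream in, three band-limited HRV
measures come out every two seconds, a pacer guides slow breathing, a flanker
task applies cognitive stress, and a calendar/incentive engine tracks a
yearlong cohort. This vignette explains the models behind each stage, the
parameters that matter, and the choices we made where the design was
genuinely open.

## The HRV measure

All three HRV variants are natural logarithms of band-limited variance of
the IBI signal, in ln(ms²). The processing chain is:

1. **Artifact editing.** Beats deviating more than 25% from a 5-beat running
   median, or outside the hard physiological range 250–3000 ms (20–240 bpm),
   are flagged and (by default) replaced by linear interpolation over beat
   index. The 25% rule is standard IBI-editing practice; the threshold,
   window and policy are parameters of `clean_ibi()`. Editing is idempotent.
2. **Resampling.** The tachogram (interval vs onset) is interpolated to a
   uniform 5 Hz grid spanning `[0, duration]` with a cubic spline. We also
   provide sample-and-hold (`interp = "step"`), but do not default to it: a
   hold of ~1 s attenuates a 0.25 Hz modulation by the sinc factor
   (~0.9 in amplitude, about −0.21 ln-units of variance), which is a large
   bias against the closed-form oracle below. 5 Hz comfortably oversamples
   the 0.03–0.40 Hz analysis range.
3. **Detrending.** Slow non-oscillatory drift is removed with a moving cubic
   polynomial (Savitzky–Golay) filter over a 60-s window. The window length
   is the critical parameter: the residual of a moving cubic over *W*
   seconds behaves as a high-pass whose corner sits near 4/W Hz, so a short
   window (say 10 s) silently removes the very 0.083–0.1 Hz paced-breathing
   oscillation the wideband measure exists to capture. With W = 60 s we
   measured the pipeline's bias at 0.083, 0.1 and 0.25 Hz to be at most
   0.07 ln-units. When an analysis window is shorter than the detrend window
   (the 30-s streaming windows), a single whole-window cubic fit is used —
   the limiting case of the moving filter.
4. **Band-passing.** A zero-phase FFT-domain filter: unit gain in the band,
   raised-cosine transitions of 0.01 Hz, zero elsewhere. We chose this over
   a forward-backward FIR because a FIR sharp enough for a 0.03 Hz band edge
   at 5 Hz needs several hundred taps — longer than the 150-sample streaming
   window — while the FFT filter is deterministic, has no phase distortion,
   and its measured stop-band rejection on test tones far exceeds 40 dB
   (a 0.05 Hz tone analyzed in the RSA band loses > 6 ln-units of variance).
5. **Variance.** `ln(var)` per 30-s epoch offline, or per trailing 30-s
   window every 2 s for the streaming feed (the biofeedback display updates
   every 2 s; only that cadence is fixed by the protocol — the 30-s window
   and epoch are our choices, balancing frequency resolution at 0.03 Hz
   against responsiveness). Variances below 10⁻⁶ ms² report the floor
   `log(1e-6) ≈ −13.8` rather than −∞.

**Bands.** RSA 0.12–0.40 Hz (spontaneous breathing; vagal), LF
0.06–0.10 Hz, wideband 0.03–0.40 Hz. The wideband measure exists because
paced breathing at 5–6 breaths/min (0.083–0.1 Hz) falls *below* the RSA
band: a participant doing the exercise perfectly would otherwise score
near-zero "RSA". All bands are `hrv_config()` parameters.

**Oracle.** A sinusoidal IBI modulation of amplitude *A* ms has variance
*A*²/2, so an in-band tone must yield `ln(A²/2)`. The tests assert this
within ±0.1 ln-units at band centre, a ln(4) shift under amplitude doubling,
and recovery of segment-mean set-points within ±0.2 across 20 seeds.
Values outside [0, 10] ln(ms²) are treated as artifact-driven and masked
per value before any analysis (`filter_hrv_range()`).

## Pacer, stressor, session

**Pacer.** A breath cycle at rate *r* bpm lasts 60/*r* s and is split as
inhale + pause + exhale + pause with an inspiration:expiration ratio of
0.435 and 1.5-s pauses (both parameters). At 6 bpm: 2.12 s inhale, 4.88 s
exhale. The animation ramps are linear by default (a raised-cosine easing is
available); easing affects only the waveform shape, never the timing
invariants, and the guiding tone is the same waveform mapped to pitch.

**Flanker stressor.** 4 minutes of arrow stimuli: one of 4 combinations
(centre × flankers direction) uniformly at random, shown 400 ms, 2.7-s
response window, next stimulus after a uniform 1–3 s interval. The protocol
does not say whether that interval runs from stimulus offset or from
response-window end; we default to window end (inter-onset spacing
3.7–5.7 s, hence 42–64 trials in 4 minutes) with an `isi_origin` switch for
the other reading. Responses before 400 ms count (the window opens at
onset). Schedules are bit-reproducible from a seed.

**Session.** Basic sessions are rest 180 s + training 300 s; training-game
sessions are rest 180 + stressor 240 + recovery 180 + training 300.
Segments are half-open `[start, end)` intervals; a streaming record is
tagged by the segment containing its window-end time, and the record ending
exactly at session end is clamped into the final segment. Biofeedback-off
arms disable the display flag while HRV is still computed — analyses never
differ between arms.

**Meter.** The display semantics are only "green calm / red stressed", so
the mapping is ours: calibrate on the session's own rest segment (mean μ and
SD σ of the wideband values after range filtering), then
`meter = clamp((x − (μ − 2σ)) / 4σ, 0, 1)` with zones red < 1/3 ≤ yellow <
2/3 ≤ green. A degenerate σ = 0 baseline steps at μ. Calibrating on the
current session (not history) keeps the meter meaningful on a participant's
first day; both the band and the thresholds are parameters.

## Protocol engine

Calendars derive deterministically from each participant's entry date
(day 0). Week *k* is days 7(k−1)+1…7k; months are 30-day blocks (the
protocol defines neither), so the quarterly windows are days 61–90, 151–180,
241–270 and the final window days 331–360. Weeks 1–6 require 3 trainings
(2 basic + 1 game) plus a weekly survey; incentives are $15/$5/$5 for the
baseline parts, $10 per completed week, $20 per quarterly survey, $20 final.
Weekly incentives have a **strict** mode (all trainings + survey completed)
and a **relaxed** mode (3 trainings of any kind + survey at least
initiated), because the study itself relaxed its criteria mid-stream; an
incomplete weekly survey expires from the daily menu 4 days after
scheduling. The nightly `fulfillment_scan()` pays every earned, unpaid
entry exactly once; ledger tests assert idempotence and conservation
(total paid = total fulfilled ≤ total earned). "Completing the 6-week
regimen" is operationalized as ≥ 3 training sessions in each of weeks 1–6.
Compliance is completed/scheduled per activity, adjusted to each start
date, as a percentage rounded to one decimal.

## Synthetic data

The generator is an additive-sinusoid model:

IBI(t) = m + A·sin(2π f_resp t) + B·sin(2π f_lf t + φ) + ε,  ε ~ N(0, σ²)

with beats placed sequentially (each interval starts where the previous
ended). We chose this over an integral-pulse-frequency-modulation model
because it gives a transparent closed-form variance (A²/2) for oracle
tests; IPFM is a possible extension. Defaults: m = 1000 ms, f_resp =
0.25 Hz at rest (the pacing frequency during training), A = 56.34 ms
(so the respiratory ln-variance is 7.37, a typical resting wideband value),
f_lf = 0.08 Hz, B = 15 ms, σ = 3 ms. Artifacts are injected as halved or
doubled beats at a per-beat rate. Segment effects are multipliers on A and
m: stressor 0.80/0.92 (vagal withdrawal, heart rate up), recovery
0.90/0.97, training 1.52/1.0 — chosen once so the segment means reproduce
the direction and approximate spacing seen in field data (an amplitude
ratio ρ maps to a 2·ln ρ shift in ln-variance).

What the generator does *not* emulate: non-stationary breathing rates,
1/f fractal structure, ectopy morphology, circadian trends, or motion
artifacts with serial structure. Passing tests therefore demonstrate the
correctness of the pipeline's arithmetic and its band selectivity on
quasi-stationary signals, not robustness to every failure mode of
field recordings.

The cohort simulator completes each scheduled activity in week *k* with
probability p₁·decay^(k−1) (defaults 0.9 and 0.85, giving the
characteristic one-third drop over the first weeks), with an optional
completer fraction whose members perform all of weeks 1–6.

## Problem sizes and numerical notes

Tests and the acceptance script use 180–900 s series (≈ 180–900 beats),
20-seed replicate sets, and a 10,000-replicate null calibration of the
Welch t test (rejection rate asserted at 0.05 ± 0.01); the whole suite runs
in under two minutes on one core. Sequential segment comparisons default to
Welch's unequal-variance t test (pooled available by flag); the degenerate
all-equal case reports t = 0, p = 1. Segment-level inference pools measures
across windows and participants exactly as the reporting convention it
mirrors does — repeated measures are not modelled, which is a known
limitation, not an accident. The segment ANOVA is a fixed-effects one-way
model on segment label.

Two further numerical notes: 30-s windows hold only 3 cycles of a 0.1 Hz
tone, so single-window estimates wobble by ~0.15 ln-units around the epoch
value (the streaming-vs-epoch test tolerance of 0.2 reflects this); and FFT
band edges assume quasi-stationarity within a window — strongly chirped
signals will leak. Both effects shrink as windows lengthen, which is the
usual resolution/latency trade of real-time biofeedback.
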