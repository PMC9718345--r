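---
title: "Methods: respiration monitoring from nasal air temperature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: respiration monitoring from nasal air temperature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoresp)
```

## The measurement principle

Nasal air sits at ambient temperature while an animal inspires and warms
toward body temperature while it expires. A fast thermosensor placed at the
nostril therefore converts breathing into an oscillating temperature trace:
maxima mark expiration ends, minima mark expiration starts. Two quantities
summarize the pattern: the **inter-peak interval** (IPI, the time between
successive same-kind extrema; its reciprocal is the breathing frequency) and
the **inspiration/expiration time ratio** (I/E, the within-cycle ratio of
phase durations). A chest band measures the same physiology through a
different transduction chain — chest diameter rises during inspiration — and
serves as the reference modality when both are recorded.

`thermoresp` implements the full analysis (cycle extraction, IPI/I-E
summaries, cross-modal delay, lick-artifact assessment, stimulus-block
contrasts) together with a ground-truthed generator of synthetic sessions
that emulates the recording chain, so every estimator is exercised against
known truth without any recordings.

## The synthetic session generator

The generator is first-class, tested code, not a fixture. Its default
parameters are the study conditions the analysis assumes:

* **Cycle train.** Successive inspiration-start intervals are gamma draws
  with mean `mean_ipi` (default 2.0 s, i.e. 0.5 Hz, a typical resting rate
  for a seated macaque) and coefficient of variation `ipi_cv` (default 0.1),
  truncated below at 0.3 s by redrawing. The gamma family was chosen for
  positivity and an independently tunable CV; the truncation keeps
  physiologically impossible sub-300-ms breaths out of the tail. Within a
  cycle, inspiration takes `ipi * ie_ratio / (1 + ie_ratio)` and expiration
  the remainder; the default `ie_ratio` of 0.88 is the thermosensor estimate
  reported for anesthetized macaques. While a music block plays, the mean
  IPI is multiplied by `music_ipi_factor` (default 0.85), emulating
  music-accelerated breathing.
* **Chest channels.** The chest diameter rises over each inspiration and
  falls over each expiration as raised-cosine segments (peak at inspiration
  end). The recorded movement channel is the finite-difference derivative of
  the noiseless diameter plus white noise. The finite difference is
  *trapezoid-consistent* — it solves `(m[k-1]+m[k])/(2 fs) = d[k]-d[k-1]` —
  so cumulative trapezoidal integration, the analysis-side inverse, recovers
  the diameter to machine precision rather than to discretization error.
* **Nasal temperature.** An idealized airflow temperature (cooling to
  ambient over inspiration, warming toward the expired-air temperature over
  expiration, extrema exactly on the true phase boundaries) is shifted by a
  transport delay `intercept + per_kg * body_weight` (defaults 0 s and
  0.01 s/kg, free parameters calibrated only to the qualitative trends that
  delay grows with weight), attenuated by a probe-position gain
  (−5 mm outside: 0.5, 0 mm: 0.75, +5 mm inside: 1.0), filtered by the exact
  discrete first-order lag with the sensor's 100-ms time constant, and
  corrupted with Gaussian noise. The inspiration limb is rendered as a
  strictly monotone raised cosine rather than a literal flat-at-ambient
  segment: a flat segment has no strict local minimum at zero noise, which
  would make the trough location degenerate; the monotone ramp preserves the
  extrema timing exactly, which is the property the analysis consumes.
* **Session protocol.** The default schedule is six 180-s blocks — music at
  212, 113 and 85 beats/min (65–70 dB SPL) and three white-noise blocks
  (40 dB SPL) — in seeded shuffled order with 60-s gaps (total span 1380 s),
  and six 0.2-ml rewards per block drawn uniformly with at least 10 s
  spacing (about one per 30 s; the count of six per block follows the
  published session example).
* **Lick channel.** Each reward spawns a burst of licks (8 at ~4 Hz with
  jitter), rendered as damped transients on a Gaussian noise floor, sampled
  at 1 kHz (vibration sensors are sampled faster than the thermal
  channels). Only the onset times matter downstream; the burst
  microstructure is plumbing.

What the generator does *not* emulate: sniffing and panting dynamics,
apneas, sensor drift, movement artifacts on the chest band, or any acoustic
property of the stimuli. Passing recovery tests on this generator therefore
demonstrates correctness of the estimators under the stated model, not
robustness to everything real recordings can contain.

The sampling rate defaults to 100 Hz for the thermal and chest channels; the
acquisition rate of the original recordings is not stated, and 100 Hz
resolves every quantity of interest here (breath periods of 1.5–2.5 s,
delays of tens of milliseconds via sub-sample interpolation).

## Cycle extraction

`detect_extrema()` smooths with a centered moving average (default 0.15 s),
takes strict local maxima/minima whose topographic prominence exceeds
`min_prominence_frac` (default 0.3) of the robust amplitude (90th − 10th
percentile of the smoothed trace), enforces a refractory spacing within each
kind (default 0.6 s, well under any plausible breath period), and finally
enforces peak/trough alternation by discarding the lower-prominence of two
consecutive same-kind extrema. Event times are refined by a parabolic fit
through the extremum sample and its two neighbours, because downstream delay
targets are of order one sample at 100 Hz. A windowed least-squares
quadratic vertex was evaluated as an alternative refinement and rejected: on
waveforms whose curvature differs between the rising and falling limbs the
wide window biases the vertex toward the flatter limb, which is worse than
the 3-point fit it would replace.

Degenerate inputs (constant traces, traces shorter than three refractory
periods, fewer than two surviving extrema) raise a typed
`thermoresp_no_respiration` error rather than returning empty results.

`segment_cycles()` encodes the phase conventions: on temperature,
inspiration is the cooling peak-to-trough limb; on chest diameter the labels
swap. Partial cycles at the trace edges are dropped rather than
extrapolated. `summarize_cycles()` anchors the IPI series on peaks by
default (the marked events in published traces); trough anchoring is a
flag. The I/E ratio is the mean of per-cycle duration ratios, not the ratio
of summed durations, so that a per-cycle SD is well defined.

The detector is verified against an exhaustive brute-force scan that applies
the same documented rules sample by sample on hundreds of random traces; the
greedy event matcher (below) is verified against an exhaustive minimum-cost
assignment on small instances.

## Cross-modal delay

`match_events()` pairs thermosensor events with chest-band events by greedy
nearest-neighbour matching within a tolerance (default 0.45 × median IPI,
which forbids cross-cycle pairing), each event used at most once, ties
broken toward the earlier chest event. Delays are reported as thermo minus
chest, so a positive delay means the thermosensor lags.

Which events to pair is a genuine convention choice. Temperature *peaks*
mark expiration ends, while chest-diameter *peaks* mark inspiration ends —
different transitions. The default (`mode = "physiological"`) matches
temperature peaks to chest-diameter troughs, the same physiological event,
so the delay is a pure measurement lag; `mode = "peak-peak"` reproduces the
literal peak-to-peak convention, which folds an inspiration duration into
the offset. Both are provided because the published convention pairs
"peaks" of both signals without resolving the transition mismatch.

For a first-order sensor driven sinusoidally at frequency $f$, the output
peak lags by $\arctan(2\pi f\tau)/(2\pi f)$ — about 97 ms at 0.5 Hz for
$\tau$ = 100 ms — and this closed form anchors the generator's lag model in
the tests. At breathing frequencies of 0.4–0.5 Hz the simulated inside-probe
delay comes out near 85–95 ms, consistent with the published 0–100 ms bound
for the inside position.

## Known estimator bias

The first-order lag does not delay peaks and troughs equally when the two
limbs of the waveform have different curvature: with I/E < 1 the expiration
limb is flatter, the trough lags ~10–20 ms more than the peak, and the
estimated I/E ratio inherits a systematic excess of roughly +0.03 at zero
noise and up to +0.05 at 10% measurement noise (noise wander of the argmax
toward the flatter limb adds the difference). This is physics of the
modelled sensor, not an estimator defect; it is documented here because
recovery tests budget for it (the I/E recovery tolerance is ±0.05).
Compensating it would require deconvolving the known sensor lag before
detection, which would also remove the very delay the cross-modal module is
designed to measure, so no compensation is applied by default.

## Lick events and artifact assessment

`detect_lick_onsets()` rectifies the vibration channel about its median,
smooths it into a short envelope (10 ms), and thresholds at
`median + k_mad × mad` (default `k_mad` = 5); a manual threshold can be
supplied instead, mirroring bench practice of adjusting the threshold per
session. Upward crossings are onsets; a 100-ms refractory period suppresses
re-triggers within one lick. Raising `k_mad` can only reduce the number of
onsets (tested as a monotonicity property).

`triggered_average()` aligns temperature segments on event onsets over a
±2-s window (the window length and pre-event-mean baseline are this
package's choices; the original alignment window is unstated), interpolates
them onto a common lag grid, baseline-subtracts each segment by its
pre-event mean, and averages. The **modulation index** — the largest
absolute post-event mean deviation divided by the robust respiratory
amplitude of the whole trace — makes "the signal did not change around
licks" assertable: on sessions where licking is independent of respiration
it stays below the simulated null's 95th percentile in ≥90% of seeds, and an
injected 0.5-amplitude event-locked artifact pushes it past the null's 99th
percentile.

## Statistics

The block contrasts (music-pooled-vs-noise unpaired t, among-music one-way
ANOVA, delay-vs-covariate Pearson regression) are implemented from their
formulas, with p-values from the regularized incomplete beta function
evaluated by a Lentz continued fraction (absolute accuracy far below 1e-8),
so the pipeline's core inferences carry no opaque statistical dependency.
They are cross-checked against R's reference implementations to 1e-6 on
random instances, the two-group ANOVA satisfies $F = t^2$ to 1e-10, and the
unpaired t test's type-I error over 2000 null replicates is required to sit
inside the binomial band [0.040, 0.061] at α = 0.05.

Conventions for degenerate inputs, which the formulas leave open: both
samples constant and equal gives p = 1; zero variance with unequal means is
reported as p = 0 with a `degenerate` flag (the paired test behaves the same
on constant differences); perfectly collinear regressions report r = ±1,
p = 0, flagged. The unpaired test is pooled-variance Student by default —
the classical "unpaired t test" — with Welch as a flag; p-values are raw by
default with Holm adjustment as a flag, matching how multiple music×subject
contrasts are conventionally reported in this literature.

Where repeated sessions exist, contrasts are intended to be run on session
means; the pipeline itself operates within sessions.

## Session pipeline

`analyze_session()` consumes a bundle (directory or in-memory), requires the
temperature channel and schedule, and runs: cycle extraction →
IPI-to-block assignment → contrasts; optional chest and lick channels add
the delay and lick-artifact stages. An IPI is assigned to a block only when
*both* bounding anchors fall inside that block; straddling and gap IPIs are
counted as discarded, and assigned + discarded always equals the total
(a conservation property tested explicitly). An `exclude_after_reward`
window (default off) optionally drops IPIs beginning within a set time after
each reward. Reports carry a provenance block (config hash, seed, package
version) and serialize to JSON byte-stably — no timestamps — so identical
inputs yield identical reports.

Stage failures are re-raised with the stage name attached, and every default
parameter actually used is recorded in the report's provenance config.

## Problem sizes used in the tests

The test suite and acceptance checks run on deliberately compact problem
sizes chosen to estimate each quantity well: 10-minute single-block sessions
for I/E recovery (about 300 cycles each), 1–2-minute sessions for delay and
IPI recovery sweeps (20 seeds), full 23-minute six-block sessions where the
block structure itself is under test, 2000 replicates for t-test
calibration, and 200 random traces for the detector/oracle equivalence.
These sizes put Monte-Carlo error well inside each stated tolerance.
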