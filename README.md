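# thermoresp

Respiration analysis from nasal air temperature recordings.

## The problem

Monitoring breathing in behaving macaques is hard: chest bands and face
masks touch the body, and monkeys remove them. A fast thermosensor placed at
the nostril entrance sidesteps this — nasal air stays at ambient temperature
during inspiration and warms toward body temperature during expiration, so
the temperature trace oscillates with every breath and nothing touches the
animal. `thermoresp` is for researchers who record such traces (or simulate
them) and want breathing summaries and their standard downstream analyses:

* respiratory cycle extraction with sub-sample extremum timing;
* inter-peak interval (IPI) and inspiration/expiration (I/E) ratio
  estimation — the IPI is the time between successive same-kind extrema,
  its reciprocal the breathing frequency, and the I/E ratio the within-cycle
  ratio of inspiration to expiration duration;
* the timing lag of the thermosensor against a simultaneous chest-band
  channel, and its dependence on probe position and body weight (the sensor
  is a first-order system with time constant τ = 100 ms: a sinusoidal drive
  at frequency *f* emerges delayed by arctan(2π*f*τ)/(2π*f*));
* whether licking a liquid reward distorts the temperature signal
  (event-triggered averaging around lick onsets detected from a spout
  vibration sensor);
* breathing-frequency contrasts between music and white-noise stimulus
  blocks (unpaired *t*), and among music tempos (one-way ANOVA), with the
  statistics implemented from formulas and verified against reference
  distributions.

A ground-truthed synthetic session generator emulates the whole recording
chain — gamma-distributed breath intervals, raised-cosine chest mechanics
whose movement channel integrates exactly back to the diameter, a
first-order sensor lag with position-dependent attenuation and
weight-dependent transport delay, reward-locked lick bursts, and the
six-block music/noise session protocol — so every estimator is tested
against known truth without any recordings.

## Worked example

```r
library(thermoresp)

bundle <- simulate_session(seed = 42)   # full 1380-s music/noise session
report <- analyze_session(bundle)
report
```

```
<session_report> 743 cycles, mean IPI 1.858 s, I/E 0.921
  block 1 music 212 bpm: 106 IPIs, mean 1.692 s
  block 2 noise        :  89 IPIs, mean 1.987 s
  block 3 noise        :  90 IPIs, mean 1.973 s
  block 4 noise        :  90 IPIs, mean 1.975 s
  block 5 music 113 bpm: 105 IPIs, mean 1.697 s
  block 6 music  85 bpm: 106 IPIs, mean 1.670 s
  music vs noise: t = -20.6736, df = 584, p = 1.148e-71 (mean diff -0.2923)
  among music:    F(2, 314) = 1.0061, p = 0.3668
  delay:          <peak_match> 742 pairs (mean delay 146.3 ms), 2 unmatched
  licks:          294 detected, modulation index 0.011
```

Reading the output: the generator shortens breath intervals by 15% during
music, and the pipeline recovers exactly that — music-block IPIs (~1.69 s)
are shorter than noise-block IPIs (~1.98 s), the pooled music-vs-noise
contrast is decisive, while the among-tempo ANOVA correctly finds no tempo
effect (none was simulated). The thermosensor lags the chest band by
~146 ms here: ~90 ms of first-order sensor lag plus a 60-ms transport delay
for a 6-kg animal (0.01 s/kg). The lick modulation index of 0.011 says the
temperature signal around lick onsets deviates by about 1% of the
respiratory amplitude — licking does not distort the trace.

The estimated I/E of 0.921 against a generator truth of 0.88 illustrates a
documented measurement bias: the sensor lag delays troughs slightly more
than peaks on waveforms whose expiration limb is flatter. See the methods
vignette (`vignettes/thermoresp-methods.Rmd`) for the analysis.

Individual stages are ordinary functions:

```r
ex  <- detect_extrema(bundle$temperature)          # peaks/troughs, sub-sample times
cyc <- segment_cycles(ex, "temperature")           # inspiration/expiration per breath
summarize_cycles(cyc)                              # IPI series, mean/sd, I/E ratio

chest <- integrate_chest_movement(bundle$chest_movement)
session_delay(bundle$temperature, chest)           # thermo-vs-chest peak lag
```

Bundles round-trip through plain-text directories (`write_session_bundle()`
/ `read_session_bundle()`: one CSV per channel, `schedule.json`,
`truth.json`, `config.yaml`), and a thin command-line front end is installed
at `exec/thermoresp` (`simulate`, `analyze`, `compare`).

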