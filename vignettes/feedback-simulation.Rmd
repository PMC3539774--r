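---
title: "Simulated closed-loop auditory feedback for birdsong: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated closed-loop auditory feedback for birdsong: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songtrigger)
```

## What this package simulates

Experiments on distorted auditory feedback (DAF) in songbirds need an
apparatus that detects a specific song syllable within milliseconds of its
occurrence and plays a sound back contingently. `songtrigger` is an
offline, sample-accurate simulation of such an apparatus: the same
two-mode, circular-buffer, spectrogram-correlation architecture a
real-time rig uses, but driven from recorded or synthesized waveforms, so
every component can be tested against ground truth. No real-time
scheduling guarantees are made or measured; the simulation is faithful to
the *logic* of the processing chain, not to device latencies.

The package has three layers:

1. **Detection engine** (`engine_config()`, `run_stream()`): an rms-gated
   state machine with streaming short-time spectrograms and Pearson
   template correlation.
2. **Contingent feedback** (`feedback_policy()`, `run_closed_loop()`):
   playback decisions (always / probabilistic / pitch-conditional), FFT-peak
   pitch estimation, delayed playback with microphone-pickup mixing and
   self-trigger lockout.
3. **Synthetic songs and evaluation** (`synth_song()`, `bird_agent()`,
   `match_detections()`, `ks_two_sample()`, ...): an annotated generator of
   Bengalese-finch-like song, a virtual bird for multi-day conditioning
   experiments, and the statistics used to evaluate both.

## The detection model

### Two modes, two circular buffers

Audio arrives one sample at a time. In **idle** mode the engine computes,
every 1 ms, the rms of the last 10 ms of input; when it exceeds a
threshold the engine switches to **triggered** mode. While triggered, a
256-point FFT of the most recent samples is computed every hop (1 ms
nominal) and its magnitude column pushed into a spectrogram ring buffer;
the most recent columns form a patch that is correlated against each
stored template. Every 1 s the rms of the last 200 ms is checked and the
engine returns to idle when the sound has stopped, closing the recorded
"triggered segment".

Both buffers are fixed-capacity rings (`sample_ring()`, `spectro_ring()`)
with overwrite-oldest semantics: reads of the most recent *n* elements are
constant-time and never perturb acquisition order. Spectrogram columns are
computed only while triggered, and the column ring is cleared on each
idle-to-triggered transition so a patch can never straddle a silent
inter-bout period.

### Timing conventions

All times are integer sample indices (sample 1 is the first sample of the
stream); millisecond configuration values are converted once to sample
counts by rounding, so a 1 ms hop at 30.3 kHz is exactly 30 samples
(0.990 ms) and "every 1 ms" logic counts hops. This makes long streams
drift-free and makes event logs exactly reproducible: the same input and
configuration give bit-identical logs regardless of how the stream is
chunked, because gate checks, hops and idle checks live on global sample
grids rather than on wall-clock time.

### Template matching

A template (`build_template()`) is a spectrogram patch cut from an
annotated recording: `pre_roll_ms` of pre-onset audio (part of the
inter-syllable gap) plus the first `duration_ms` of the target syllable,
20 ms by default. The detection statistic is the Pearson correlation over
all time-frequency cells between the template and the equally shaped patch
ending at the current hop; a detection is declared at the first hop where
the correlation reaches the template's threshold (0.8 by default), and the
detection time is the time of the last sample of the matched window, which
therefore lands *inside* the syllable (about its middle for a 20 ms
template on a 40 ms syllable). Because the statistic is evaluated at every
hop, the first crossing typically precedes the best alignment by a few
hops while the correlation is still rising; evaluation against annotations
uses a 10 ms tolerance for exactly this reason, while the *peak* of the
offline correlation trace recovers annotated times to within one hop.

Choices where the architecture left room, and why:

- **Correlated window length equals the template length.** Descriptions of
  this architecture variously give 20 ms and 40 ms for the correlated
  window; the package ties the window to the template patch, which is the
  only shape for which the correlation is defined, and makes the length
  configurable through the template.
- **Hann taper, linear magnitudes.** The taper is standard sidelobe
  suppression for spectrogram matching. Linear magnitude makes the Pearson
  correlation *exactly* gain-invariant (scaling audio by any c > 0 scales
  every cell by c and leaves the correlation unchanged), so detection
  depends on spectral shape, not loudness; `log1p` magnitudes are
  available as an option.
- **Zero-variance patches are errors, not zero.** Whether sound is present
  at all is the amplitude gate's decision; a silent patch reaching the
  correlator indicates misconfiguration, and the streaming engine simply
  treats it as a non-match.
- **Refractory.** One patch span per template after each detection
  (configurable). Without it the correlation stays above threshold for
  several consecutive hops and a single rendition would emit a burst of
  events.
- **Ties.** If two templates cross threshold at the same hop both events
  are emitted, ordered by template id. Event logs are therefore
  non-decreasing (not strictly increasing) in time.
- **Gate thresholds** have no canonical values; they are calibrated as
  multiples of a noise-floor rms (3x for trigger, 1.5x for idle-return;
  `calibrate_gate()`), with hysteresis so the mode cannot oscillate.
  Pipelines calibrate from the first 100 ms of each recording, which also
  makes the whole detection chain invariant to input gain.

## Contingent feedback

On each detection of the designated target template the policy decides
whether to play feedback: never, always, with fixed probability p per
detection (p = 0.05 keeps playbacks sparse enough that songs almost never
contain two), or conditionally on the syllable's pitch being strictly
below/strictly above a threshold. Equality at the threshold triggers in
neither direction.

**Pitch** is the frequency of the largest FFT magnitude peak of the latest
256 samples, refined by parabolic interpolation of the log-magnitudes of
the peak bin and its neighbours, computed at every hop; the syllable's
summary pitch is the *minimum* of this contour between 3 and 12 ms after
the detection time. At 30.3 kHz/256 points the raw bin spacing is ~118 Hz,
far coarser than the 20 Hz threshold differences these experiments use;
sub-bin interpolation is the minimal mechanism that supplies the needed
precision (on synthetic harmonic stacks it is accurate to ~2 Hz).

**Playback** is scheduled at `syllable onset + delay_ms` (40 ms default),
where the onset is recovered as `detection time - template post-onset
extent`. The rendered sound (white noise burst or a stored syllable) is
mixed into the not-yet-processed input scaled by a microphone pickup gain,
and the engine is locked out from registering detections until one full
patch length *after* the playback ends -- slightly stronger than
forbidding detections during playback only, so that no correlation window
overlapping the playback can fire. The closed loop is processed in blocks
no longer than the detection-to-playback margin, so playback insertion is
always causal.

## The synthetic song generator

The generator is the package's study population, not a fixture: its
defaults define the conditions under which every end-to-end claim is
tested.

A song is a first-order Markov sequence of syllables separated by
inter-syllable gaps over a broadband noise floor. The default grammar has
five syllable types: an introductory note `i` (2.6 kHz stack) that opens
every song, the target `a` -- a near-tonal 3.5 kHz harmonic stack, 40 ms,
the kind of element whose pitch escape-conditioning manipulates -- a
descending 6 to 4 kHz sweep `b` that always follows the target, a low
2.2 kHz four-harmonic stack `c`, and a rising 3 to 5 kHz sweep `d` that
crosses the target's band (discriminated by spectrogram pattern, not
instantaneous frequency). The deterministic core `a - b - c` makes `c` the
second syllable after the target, which the interval estimator needs.

Rendition-to-rendition variability: per-rendition fundamental jitter of
30 Hz s.d., gap timing jitter of 2 ms s.d. around a 40 ms mean gap, and a
noise floor 40 dB below syllable amplitude -- values a recordist would
call typical for clean colony recordings of a stereotyped adult song. The
sequence itself is the dominant song-to-song variability, as in the real
species. Syllables are rendered as harmonic stacks or linear chirps under
a 5 ms attack/decay envelope; every song carries exact ground-truth
annotations (label, onset, offset, rendition f0).

What the generator does *not* emulate -- and what passing tests therefore
do not show about real data: natural amplitude modulation within
syllables, spectral variability beyond a global f0 shift (formant-like
changes, noisy/aperiodic syllables), cage noise transients, or any
immediate sensitivity of song timing to feedback. In particular the
interval-timing analysis on synthetic song measures a true null: the
virtual bird's gaps do not react to playback, so control and feedback
interval distributions differ only by sampling noise. The analysis code is
exercised end to end, but a real timing effect can only come from real
birds.

### The virtual bird

The multi-day conditioning experiment needs a singer that reacts to
feedback. `bird_agent()` implements a deliberately minimal escape rule:
sing `day_length` songs a day with the target centred on the current mean
f0 (plus the grammar's 30 Hz rendition jitter); after every rendition that
earned feedback, move the mean `learning_rate` Hz away from the feedback
region. The rule reproduces the phenomenon -- gradual drift away from the
conditioned region, with feedback becoming rarer as the bird escapes --
without claiming anything about learning mechanisms.

Defaults: 200 songs/day (a realistic daily rendition count for this
paradigm), 0.1 Hz per fed-back rendition, starting mean 3460 Hz against a
3530 Hz threshold. These were chosen, before any end-to-end runs, from a
simple design calculation: with ~200 renditions/day the s.e.m. of a day
mean is ~2 Hz while the expected daily drift stays above ~7 Hz across six
days, so the conditioned trend is resolvable above rendition noise every
single day. The detection template for the experiment is built once from a
clean pre-experiment reference recording, with its threshold calibrated to
0.65 on a small set so the template keeps catching renditions across the
whole conditioning range (the drifting fundamental moves the harmonics by
up to ~0.8 FFT bins, which costs correlation).

## Evaluation statistics

- **Confusion counts** (`match_detections()`): detections are matched
  one-to-one to expected detection points (annotated onset + template
  post-onset extent) within a 10 ms tolerance -- a numeric stand-in for
  matching by visual inspection; a quarter of a typical syllable. The
  matcher is chronological earliest-feasible greedy, which for 1-D
  interval-structured matching provably attains the maximum number of
  pairs (verified in the tests against exhaustive assignment).
- **Half-difference intervals** (`half_difference_intervals()`): playback
  overlaps the syllable right after the target, so the target-to-next
  interval is estimated as half the detection-time difference between the
  target and the *second* syllable after it; applied identically to
  control trials.
- **Two-sample Kolmogorov-Smirnov** (`ks_two_sample()`): D is the sup of
  the pooled ECDF difference (tie-aware); the p-value is the asymptotic
  Kolmogorov tail at `sqrt(nm/(n+m)) D`, standard at the sample sizes of
  timing experiments (hundreds of intervals); an exact no-ties
  permutation-distribution option (lattice-path recursion) is available
  for small samples.
- **Daily pitch summaries** (`daily_pitch_summary()`): per-day mean,
  s.e.m. and n; a single-rendition day reports s.e.m. 0 and is flagged
  rather than dropped.

## Numerical and degenerate-input policy

- Pearson correlations use the centred two-pass formula; engine templates
  are pre-centred once.
- Pitch on an all-zero window is an undefined marker (`NA`), not an error;
  a pitch-conditional decision with no defined pitch in the summary window
  plays nothing.
- The peak-interpolation offset is clamped to half a bin; peaks at the
  spectrum edges are not interpolated.
- PCM-16 audio is normalized by 32768 symmetrically on read and write;
  64-bit float WAV round trips are bit-exact.
- Annotation files are validated structurally (ordering, overlap,
  inversion) with the offending line named.
- Unknown configuration keys are errors, not warnings: a typo in a
  threshold name must not silently run a different experiment.

## Problem sizes

The shipped tests and the acceptance script run, by design, at desk scale:
50-song corpora (~90 target renditions) for detection performance, 150
songs for the interval analysis, and 6 + 6 simulated days x 200 songs for
the conditioning experiment. These sizes were chosen so the full suite
recomputes every claim from scratch in a few minutes on one core while
keeping every estimate's sampling error well inside the margins the claims
need.

## Known limitations

- Pure-R hop loop: throughput is roughly 3-5x real time on one core --
  ample for simulation, irrelevant for deployment; a real rig needs a
  compiled inner loop and device I/O this package deliberately does not
  model.
- The engine correlates only while triggered, so a target syllable at the
  very start of a bout (less than one patch length after the gate opens)
  cannot be detected; songs here open with an introductory note, as the
  real species' songs typically do.
- Template drift: large conditioned pitch shifts degrade the correlation
  against a fixed template; the experiment driver compensates with a
  calibrated threshold, a real experiment would re-template.
- The KS exact option requires tie-free samples; millisecond-rounded
  intervals generally have ties, so the asymptotic p is the default.
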