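---
title: "Models, detectors and the synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, detectors and the synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sleepcoupler)
```

This vignette explains the science behind each stage of the pipeline,
the tunable parameters and their defaults, and the design choices made
where the design was genuinely open. It states no empirical result that
the package's tests and acceptance script do not themselves compute.

## Sleep staging

Rodent vigilance states are scored in fixed epochs (default 4 s, the
common mouse convention; configurable via `staging_params()`). Per
epoch the scorer computes the EMG root-mean-square and the EEG delta
(0.5–4 Hz) and theta (6–9 Hz) band powers from a Hann periodogram, then
applies the standard rule set:

1. **WAKE** when EMG tone is high,
2. otherwise **REM** when the theta/delta power ratio exceeds
   `theta_delta_rem_ratio` (default 1.5, muscle atonia being implied by
   the failed EMG criterion),
3. otherwise **NREM**.

Labels are then majority-smoothed over `smoothing_epochs` (default 3),
and REM epochs entered directly from WAKE are relabelled NREM, because
REM is physiologically entered only from sleep.

The EMG criterion is two-pronged: an epoch is WAKE when its RMS exceeds
either a robust z-threshold (`emg_wake_z` = 1, z computed against the
median/MAD over epochs) **or** an absolute floor (`emg_wake_abs_uv` =
50 µV). The floor exists because a purely epoch-relative criterion is
ill-posed in two regimes a tool must survive: a recording that is
almost entirely wake (the robust z of every epoch is then ≈ 0), and a
session in which wake occupies about half the epochs, where the median
RMS falls between the wake and sleep clusters and the MAD scale becomes
unstable. Fifty microvolts sits well above mouse nuchal EMG atonia and
well below waking tone; it is configurable for other preparations or
gains. Staging uses only signal content, never channel names, so
relabelling channels cannot change the result.

Stage spectra are per-epoch Hann periodograms averaged within a stage
and normalized to unit sum over the analysis band (default 0.5–30 Hz),
i.e. power is expressed relative to the total power of the same stage.
Band summaries default to delta 0.5–4, theta 6–9, alpha 9–12 and beta
12–30 Hz; the alpha/beta edges are package conventions.

## Event detection

All three detectors share one scheme — zero-phase band-pass, amplitude
envelope, z-scoring by the mean and SD over *all* samples of the
transformed trace, threshold runs, duration criterion:

* **Ripples** (CA1, 100–250 Hz): envelope = squared signal low-pass
  filtered at `envelope_lowpass_hz`; maximal runs at or above the
  boundary threshold (default 3 SD, equal to the peak threshold; a
  lower boundary can be configured for two-threshold operation) are
  kept when the run maximum reaches 3 SD and the run lasts 30–100 ms
  inclusive. The envelope low-pass default is 30 Hz: an envelope's
  temporal resolution is roughly `1/(2 × cutoff)`, and a 20 Hz envelope
  (≈ 25 ms resolution) smears bursts shorter than the 30 ms minimum
  into threshold runs that pass it, making the minimum-duration rule
  unenforceable. 30 Hz resolves the criterion while still bridging
  within-event envelope dips.
* **Delta waves** (mPFC, 0.1–5 Hz): candidates are half-waves of the
  filtered, z-scored trace delimited by consecutive zero crossings
  (polarity `BOTH` by default, since deflection sign depends on
  referencing); kept when the extremum |z| exceeds 2 and the half-wave
  lasts 150–500 ms inclusive.
* **Spindles** (mPFC, 9–17 Hz): envelope = Gaussian-smoothed RMS
  (smoothing SD 100 ms); runs sustained at or above 2.5 SD for more
  than 500 ms (strict) whose maximum reaches 5 SD. A 3 s cap bounds
  pathological runs and can be disabled.

Event boundaries sit at the half-sample threshold (or zero) crossings,
so the peak is strictly interior and durations are exact multiples of
the sample interval. Zero-phase filtering keeps peak times unbiased for
the lag analysis downstream.

Numerically, filtering is a Butterworth applied forward and backward
with odd-reflection padding at both ends and unit-SD pre-scaling of the
input. The symmetric padding makes the operation commute with time
reversal up to edge transients; the pre-scaling conditions the
narrow-band recursion and makes detections exactly invariant under
positive rescaling of the trace. Degenerate (zero-variance) inputs are
rejected with an explicit error.

## Coupling

During sleep — NREM by default, configurable, since the underlying
events are NREM phenomena — a spindle couples to a delta when its peak
follows the delta peak by more than 100 ms and at most 1300 ms, and a
delta couples to a ripple at a lag in (50, 250] ms. Windows are
half-open `(lo, hi]`: a lag exactly at the lower edge is not coupled,
one exactly at the upper edge is, so adjacent definitions cannot
double-count a degenerate lag (a 1 ns float tolerance absorbs rounding
of times). The default pairing is greedy one-to-one — leaders scanned
in time order, each assigned the earliest unassigned in-window
follower — because "sequences" are discrete joint occurrences;
`ALL_PAIRS` is available for sensitivity analyses. An R–D–S sequence is
the conjunction of an R–D and a D–S pair through the shared delta.

Rates are normalized per minute of NREM within the session window; the
result object also carries rates per recording minute and per leader
event, since the appropriate denominator is a judgement call. Pre- vs
post-encoding comparison takes matched replicate (animal) lists,
computes post − pre per-minute rates, and reports the group mean with a
seeded bootstrap percentile confidence interval over replicates (2000
resamples; a single replicate yields an NA interval).

## The synthetic session generator

The generator exists so that every stage of the pipeline can be scored
against known ground truth. It emulates:

* a semi-Markov state sequence: alternating bouts with exponential
  durations (means WAKE 200 s, NREM 120 s, REM 60 s), wake always
  followed by NREM, REM entered only from NREM (`nrem_to_rem` = 0.4,
  `rem_to_nrem` = 0.5), discretized to epochs by majority occupancy;
* background signals: 1/f EEG (40 µV SD) with a 0.5–4 Hz component
  whose amplitude in NREM is three times its wake value and a 6–9 Hz
  theta component dominant in REM; EMG noise at 120/30/10 µV SD in
  wake/NREM/REM (atonia); LFP background with spectral exponent 2, the
  textbook deep-electrode spectrum — a flatter exponent would place a
  physiologically implausible share of variance in the 100–250 Hz
  band;
* events restricted to NREM (ripples, deltas and spindles are NREM
  phenomena), with densities 20, 18 and 3 per NREM minute, and
  coupling: each ripple spawns a delta with probability
  `coupling_prob_rd` at a lag uniform on [0.05, 0.25] s, each delta a
  spindle with probability `coupling_prob_ds` at a lag uniform on
  [0.2, 0.8] s — supports strictly inside the analysis windows. A
  Poisson fill tops up each kind to its density. Same-kind overlap is
  rejected; a Poisson-fill delta that is due to spawn a spindle is
  placed jointly with its child, so a spawning delta always carries
  one.

Event amplitudes are specified in detector-envelope SD units (ripple 7,
delta 4, spindle 8) so detector tests are self-calibrating: typical
detected events in real recordings sit well above their thresholds, and
these targets reproduce that margin. Because the injected events
themselves inflate the envelope SD they are measured in — and the
analytic first guess ignores event/background cross terms — amplitudes
are set by a measure-and-correct loop: build the trace, measure each
event's achieved envelope peak, trim, rebuild (three passes). Note a
structural ceiling: with events occupying a fraction *f* of the trace,
the achievable mean z saturates near `1/sqrt(f)`; the spindle target
sits deliberately below that ceiling.

Waveforms are stylized for testability while staying physiological:

* ripples and spindles carry an envelope with a sustained body plus a
  curved central crest, so the smoothed envelope stays above the
  boundary threshold for the intended duration *and* has a unique,
  sharply curved maximum that localizes the detected peak (a flat-top
  envelope lets the argmax wander tens of milliseconds under
  background cross terms);
* within a ripple's envelope the pre-existing ripple-band background
  is suppressed before the burst is added — in a recorded trace the
  event *is* the local in-band signal — which removes the cross-term
  dips that would otherwise fragment threshold runs;
* delta waves are biphasic: a half-sine main lobe flanked by opposite
  0.7 s lobes at 65% amplitude emulating the slow-oscillation cycle.
  The lobes pin the zero crossings of the 0.1–5 Hz trace to the
  main-lobe edges (otherwise slow background fluctuations extend the
  half-wave past 500 ms), and their duration exceeds the 500 ms cap so
  they can never be scored as delta waves themselves. The waveform's
  9–17 Hz content is removed with a zero-phase FFT notch so a delta
  cannot masquerade as, or interfere with, a spindle on the shared
  mPFC channel.

Nominal waveform supports (ripple 60–90 ms, delta 180–300 ms, spindle
900–1300 ms) are chosen so that the *operational* durations — the time
the detection envelope spends above threshold, which is how the
detectors define duration — fall inside the published bounds after
filter widening.

What the generator does **not** model: biophysical neural-mass
dynamics, travelling-wave geometry, electrode artifacts, state-dependent
LFP spectra, genotype effects (REM theta amplitude is exposed as a
parameter, not a mechanism). Passing tests therefore demonstrate that
the pipeline recovers events and coupling structure of the stated
shapes and SNRs embedded in 1/f-type backgrounds — not that it is
robust to every artifact of real recordings.

## Behavioral metrics

The discrimination index is the exact formula
`DI = (t_displaced − t_stationary)/(t_displaced + t_stationary) × 100`,
antisymmetric under swapping its arguments, ±100 only when one time is
zero, undefined (an error) when both are zero. Zone summaries consume
labelled position tracks (zone assignment is the tracking software's
job); each inter-sample interval's time and Euclidean step length are
attributed to the zone of the interval's *starting* sample, a
deterministic convention at crossings that makes per-zone times sum
exactly to the track duration.

## Signals on disk

EDF was chosen as the signal carrier because it is the de-facto sleep
EEG standard; the package includes a minimal 16-bit reader/writer (1 s
data records, so sampling rates must be integer Hz; a 3000 Hz LFP
channel round-trips). Physical limits are symmetric around zero,
quantization error is at most one part in 65535 of the range, and the
limits actually written to the fixed-width header are the ones used for
quantization. EDF labels are free text, so channel modality/region
lives in a JSON sidecar (`write_channel_map()`). Hypnograms and event
tables are headered TSV — diffable fixtures — with sorting,
non-overlap and duration-consistency invariants enforced on read and
on construction. Configuration round-trips through YAML with named
vectors written as maps.

## Orchestration and reproducibility

`run_pipeline()` simulates a pre- and a post-encoding window (the post
window can override the coupling probabilities, emulating a
consolidation effect), writes EDF + ground truth, scores, detects,
couples and renders the report, recording a JSON manifest with the
config snapshot, seed, per-stage output digests and wall-clock. Stages
whose outputs match their recorded digests are skipped on re-run. One
master seed fans out to per-stage child seeds by a stable hash of the
stage name, so inserting a stage does not reshuffle the others'
randomness; identical config and seed give byte-identical event tables
and coupling reports. The report is Markdown with TSV sidecars — a
deliberately text-only, diffable artifact.

## Problem sizes used by the test suite

The test suite validates detector recovery on ten 30-minute synthetic
sessions (1000 Hz LFP), staging on two 2-hour sessions, the analytic
coupling null on twenty 600 s Poisson streams, cohort recovery on ten
simulated six-animal cohorts, and exact oracle equivalence on several
hundred short random traces and event tables. The acceptance script
uses six 30-minute sessions and two 2-hour sessions. These sizes give
stable statistics (hundreds to thousands of events per estimate) while
keeping a full run to minutes on a single core.

## Known limitations

* The EMG absolute floor assumes µV-calibrated input; uncalibrated
  recordings should rely on the robust-z prong (set the floor to
  `Inf`).
* Delta "waves" are implemented as zero-crossing-delimited half-waves;
  referencing conventions that produce full-wave morphology would halve
  measured durations.
* The EDF writer emits plain EDF (no annotation channel), one-second
  records, integer sampling rates.
* Coupling rates are normalized per NREM minute by default; per
  recording minute and per leader event are also reported because the
  appropriate denominator for a "joint occurrence rate" is ambiguous.
* The synthetic generator's stylized waveforms make detector scoring
  crisp; they are not a substitute for validation on real recordings.
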