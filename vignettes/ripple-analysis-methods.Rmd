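---
title: "Detecting and quantifying cortical ripples in laminar recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying cortical ripples in laminar recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripplepipe)
```

## What this package computes

Sharp-wave ripples are brief (tens of milliseconds) high-frequency
(~80-200 Hz) oscillatory events in the local field potential (LFP), long
studied in hippocampus and more recently reported in neocortex during
active behaviour. `ripplepipe` implements an analysis chain for laminar
(16-contact) recordings from visual cortical areas V1 and V4 during a cued
spatial-attention task:

1. signal conditioning -- broadband band-limiting/resampling and bipolar
   rereferencing;
2. ripple detection -- a dual-threshold band-power detector with spectral
   validation;
3. event statistics -- ripple rates by task epoch and condition, paired
   signed-rank tests, a three-way repeated-measures ANOVA, and FDR-corrected
   post hoc contrasts;
4. cross-area coupling -- shuffle-predictor-corrected cross-correlograms
   with an AUC lead/lag test, cooccurrence probabilities, and
   ripple-triggered power-power comodulograms;
5. laminar analyses -- current source density (CSD), multiunit response
   latency, layer assignment, and contact-count-normalized per-layer rates;
6. behavioural coupling -- ripple-locked spike rates against matched
   controls and mixed-effects models of reaction times (RTs);
7. a synthetic-session generator with full ground truth, so that every stage
   is testable without any recorded data.

The numbered scripts under `analysis/` run these stages as a narrative
workflow; every computation they perform lives in the package and is covered
by the test suite.

## Signal model and preprocessing

A recording is a channels-by-samples matrix with a sampling rate (1017 Hz by
default, the downsampled rate of the original acquisitions), a 150-µm
contact spacing, and a session clock in seconds. `bandlimit_resample()`
applies a zero-phase FIR band-pass (default 0.5-300 Hz) at the native rate
and interpolates onto the output grid. Two numerical choices matter:

* **Zero phase.** The band-pass is a linear-phase window-method FIR applied
  forward and backward (net response = squared magnitude). Event *timing* is
  the primary quantity downstream, so no group delay is tolerable. The tap
  count is `3.3 * fs / transition_hz` (10-Hz transitions by default).
* **DC and resampling.** A desk-scale FIR cannot realize a 0.5-Hz edge, so
  the DC component is removed exactly by mean subtraction before filtering.
  The non-integer decimation (e.g. 32756 -> 1017 Hz, coprime rates) is done
  by interpolation after the anti-alias filter; with content limited to
  300 Hz and a 32.7-kHz grid the interpolation error sits far below the
  filter's stopband.

`bipolar_rereference()` forms derived channel *i* as `x[i+1] - x[i-1]`,
dropping the first and last contacts. Any common-mode (volume-conducted)
signal cancels exactly; the tests assert this to machine precision. A
consequence used throughout: a focal burst on one parent contact appears on
*two* derived channels (with opposite signs), so area-level analyses first
deduplicate detections across channels in time (`area_events()`, 10-ms
cluster gap).

## The ripple detector

`detect_ripples()` runs per derived channel:

1. band-pass 80-250 Hz (zero-phase FIR), square, and z-score using the mean
   and SD of the *entire* recording of that channel -- the detector is
   thereby invariant to overall signal scaling;
2. candidate events = maximal runs above 3.5 SD; gaps shorter than 5 ms are
   merged; merged runs outside 30-100 ms are discarded; runs whose maximum
   does not exceed 5 SD are discarded (threshold -> merge -> duration gate ->
   confirmation, in that order);
3. spectral validation: the Hanning-tapered power spectrum of a 200-ms
   window of the raw rereferenced LFP centred on the event is divided by the
   channel's average spectrum over the whole recording, and the peak
   frequency is the argmax of that ratio within a 30-300 Hz search band.
   Events with peak frequency below 80 or above 200 Hz are rejected.

The baseline division in step 3 deserves a note: the raw spectrum of any
1/f-shaped LFP has its argmax at the lowest resolvable frequency, so a
literal argmax would reject every event. Dividing by the channel's own
average spectrum flattens the background, so the argmax picks the most
*elevated* frequency -- a 60-Hz transient that tripped the envelope is then
correctly identified (and rejected), and a genuine 150-Hz ripple is kept.
The search band is deliberately wider than the acceptance band for exactly
this reason.

Event boundaries are the 3.5-SD crossings; the 5-SD criterion applies to the
within-event maximum. The envelope is not smoothed by default (an optional
boxcar is exposed). The threshold/merge/duration logic is verified against
an independent exhaustive run-length scan on 10^4-sample traces, and the
detector's monotonicity in the candidate threshold is a property test.

## Epochs, rates, and the factorial statistics

Three canonical task epochs are anchored to per-trial events: precue
(200 ms from fixation onset), postcue (800 ms from cue offset) and sustained
(300-750 ms after stimulus onset). The task's cue-off-to-stimulus delay is
1000 ms while the postcue epoch is 800 ms, so its placement is ambiguous;
the default starts at cue offset (the literal reading), and
`canonical_epochs(postcue_end_anchored = TRUE)` provides the alternative
that ends at stimulus onset.

The ripple rate of a cell is `n_events / (n_trials * epoch_duration)`
(events/s). With channel-level events the rate is computed per electrode and
averaged within session; with area-level events the count is direct. One
value per session x epoch x (cue x focus x size) cell feeds:

* `compare_rates_paired()` -- two-sided Wilcoxon signed-rank on
  session-paired differences, zero differences dropped, exact null below 20
  pairs;
* `rm_anova3()` -- the 2x2x2 within-session repeated-measures ANOVA
  (`aov` with `Error(session/(A*B*C))`). For two-level within factors each
  F equals the squared paired-t on per-session contrast scores, which the
  tests use as an independent oracle;
* `posthoc_signrank_fdr()` -- declared contrasts with Benjamini-Hochberg
  adjustment (verified against an independent step-up implementation).

## Cross-area analyses

`cross_area_correlogram()` histograms same-trial lags `t_B - t_A` (5-ms
bins, ±200 ms, bins centred on zero) and subtracts a shuffle predictor: the
mean histogram after randomly permuting the trial assignment of the B
events. The permutation pool must be *every* trial with an epoch window --
restricting it to trials that happen to contain events biases the predictor
upward (we measured roughly -0.05 counts/bin under independence before
fixing this). The area under the corrected correlogram is split at lag zero
(the central bin contributes half to each side); per-channel-pair AUC
asymmetries feed a Wilcoxon signed-rank test.

`ripple_triggered_comodulogram()` implements power-power coupling: for each
trigger event, complex-Morlet power (40 log-spaced centre frequencies,
3-250 Hz, 7 cycles) is averaged over a 200-ms window in both areas, giving
one power value per frequency per event; cell `(f_trig, f_targ)` is the
Pearson correlation of those values *across events*, Fisher z-transformed.
The source analysis computes one trigger and one target spectrogram per
event and aggregates across contacts, which leaves open whether the
correlation runs across time bins or across events; we correlate across
events (window-averaged power), which makes each cell a well-defined
correlation with `n_events` samples. For inference, events are split into
`n_splits` (default 10) disjoint groups; per-group Fisher-z values are the
samples for a Welch t-test per cell against a control comodulogram built
from condition/time-matched ripple-free windows, with Benjamini-Hochberg
correction across all cells (`correct_and_test()`).

Wavelet centre frequencies are `f_k = 3 * (250/3)^(k/39)` Hz. Note that
150 Hz and 60 Hz fall *between* grid frequencies, so a coupling injected at
(150, 60) legitimately peaks at an adjacent centre (141.8/158.8 and
57.2/64.1 Hz); tests therefore accept the cell within one log-step.

## Laminar analyses

`compute_csd()` is the standard second-spatial-difference estimator,
`csd_i = -(x[i-1] - 2 x[i] + x[i+1]) / h^2`, sinks negative, conductivity
absorbed into arbitrary units; edge contacts have no estimate unless Vaknin
replication is requested. `response_latency()` high-passes (300 Hz),
rectifies, smooths with a 5-ms boxcar (the standard multiunit-envelope
step), trial-averages around stimulus onset, and takes the first time the
average exceeds the pre-stimulus baseline mean + 3 SD for at least 10 ms.
The persistence window is twice the smoothing width on purpose: smoothed
noise is autocorrelated over the boxcar length, so a 5-ms persistence no
longer rejects noise runs (we observed roughly one false early crossing per
simulated session with 5 ms; 10 ms removes them without delaying true
onsets, which last ~30 ms). A 250-ms baseline is used because a shorter one
underestimates the autocorrelated noise SD.

`assign_layers()` defines the input layer as the contiguous block of
contacts whose sink amplitude (baseline-subtracted CSD, time-smoothed over
10 ms, searched 0-150 ms post-stimulus) reaches half the maximal sink, with
the requirement that the block contain the minimum-latency contact;
superficial and deep layers lie above and below, edge contacts are
excluded. A sink/latency disagreement of more than two contacts raises an
error and demands a manual override (`layers.csv`). Per-layer ripple rates
are divided by the layer's contact count so layers of different thickness
are comparable.

## The synthetic generator

`simulate_session()` produces a full two-area session with ground truth.
Its defaults *are* the study conditions and were fixed before any
end-to-end testing:

| parameter | default | origin |
|---|---|---|
| contacts / spacing / rate | 16 / 150 µm / 1017 Hz | acquisition geometry |
| background | 1/f, 30 µV RMS, 60% depth-shared | LFP phenomenology |
| ripple frequency / duration | U(100, 180) Hz / U(30, 60) ms | reported event spectra and durations |
| amplitude | 6 x rereferenced ripple-band RMS | calibrated so peak z clears 5 SD; not an empirical claim |
| precue/postcue rates | 0.01 events/s | reported pre/post rates |
| sustained rates | 0.065 ± 0.025 (size) ± 0.025 (cue) ± 0.005 (focus) | size and cue effects scaled to the reported 0.09 vs 0.04 events/s; the focus effect set small a priori |
| cross-area | lag N(22, 5) ms, cooccurrence 0.1 | reported 20-25 ms lead and 0.1 cooccurrence |
| spikes | 22 Hz baseline, +8 Hz Gaussian bump (σ 15 ms) at ripples | reported ~22 -> ~30 Hz elevation |
| RT model | 311 ms base; -2.4 ms ripple effect; -2 ms cue RF; -2 ms small; session SD 10 ms; noise SD 30 ms | reported 310.9 vs 308.49 ms means |

Events are Poisson within each epoch window at the cell's rate; each event
is a Gaussian-enveloped sinusoid on one random interior contact (envelope
σ = duration/2.5, chosen so the span above the detector's effective
amplitude threshold approximates the nominal duration). The evoked laminar
response has two components: a depth-synchronous slow sink wave, Gaussian in
depth around contact 8 (σ = 2 contacts, 250 µV) -- its discrete second
difference defines the ground-truth input block (contacts 7-9) -- and a
brief 400-Hz burst per contact whose onset carries the ±4 ms/contact latency
gradient. The two are separate because a latency-sheared slow wave would
distort the spatial curvature that the CSD estimates.

What the generator does *not* emulate: travelling LFP waves, state-dependent
rate fluctuations, sharp-wave deflections accompanying ripples, eye
movements, electrode drift, or amplitude covariation between coupled events
(injected bursts have condition-independent amplitudes, so the session
generator produces only weak power-power coupling; comodulogram validation
uses purpose-built coupled signals instead). Passing tests therefore
demonstrate correctness of the *computations* under a plausible signal
model, not robustness to every pathology of recorded data.

## Problem sizes and statistical design of the validation

The test suite and `scripts/acceptance.R` use scaled-down designs chosen for
desk hardware: detector recall/false-positive runs use 400-s sessions with
32 injected events (0.08 events/s); condition-rate recovery uses 8-contact
probes at 600 Hz (the event statistics are area-level, so fewer contacts
change the compute, not the rates); calibration uses 1000 null
repeated-measures tables and several hundred null mixed-model fits;
coverage uses 100 seeded fits. The sign-recovery experiment (20 runs of 700
trials) recovers the stimulus-size and attention effects reliably. The
focus effect does not replicate at desk scale, and that is a power fact,
not a code defect: its default size (±0.005 events/s) yields a per-run
detected-count z of about `0.026 * sqrt(n_trials)`, so 95% sign recovery
needs roughly 10,000 trials per run -- the recorded dataset's scale (43
sessions, ~15,000 trials), far beyond a test budget. The corresponding
acceptance expectation is left failing rather than weakened; the
size/attention clauses pass.

## Known limitations

* The detector inherits the classical dual-threshold limitations: events
  whose envelope hovers near threshold can fragment (long oscillations may
  be truncated into shorter accepted runs), and duration estimates depend on
  the envelope shape near the 3.5-SD crossing.
* The CSD layer assignment is a concretization of a method whose full
  specification is not public; all constants (sink fraction, smoothing,
  search window, latency rule) are exposed parameters, not claims.
* The comodulogram's event-split inference trades power for validity with
  few events; below 30 events the split count shrinks automatically and the
  t-tests become coarse.
* On-disk formats are deliberately minimal (raw float32 + JSON sidecar,
  CSV); proprietary acquisition formats are out of scope.
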