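---
title: "Closed-loop slow-oscillation stimulation: models and methods"
author: "sdrtes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop slow-oscillation stimulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdrtes)
```

## The protocol in one paragraph

During non-REM sleep the cortex generates slow oscillations (SOs): large
(<1 Hz) waves with a hyperpolarised down-state, visible at the scalp as
a deep negative deflection, followed by a depolarised up-state.
Closed-loop short-duration repetitive transcranial electrical
stimulation (SDR-tES) detects SOs in real time and, five seconds after
each detected negative peak, delivers four seconds of 0.75-Hz
oscillating current (0 to 2 mA, bilateral frontal anodes), with at
least 30 s between stimulation cycles. Each cycle costs about 8 s of
EEG (4 s stimulation + 4 s amplifier recovery), leaving 22 s of clean
signal before the next cycle can fire. The scientific questions around
the protocol — does it increase the SO rate, deepen sleep, help
declarative memory, and when is a stimulation most effective? — define
the analysis pipeline this package implements: offline SO labeling with
a per-participant dynamic threshold, sleep-architecture summaries with
an artifact-aware epoch relabeling rule, spectral power and coherence
measures, up-state-locked spindle energy, per-stimulation efficacy
predictors, and the statistics toolbox (paired tests, BH-FDR channel
topography, Greenhouse-Geisser repeated-measures ANOVA, exact
noncentral-t power analysis).

Because no public recordings accompany the protocol, the package ships
a synthetic-data generator whose structure matches the assumptions of
the analyses. Every analysis function is exercised end-to-end on
generator output, and parameter-recovery tests check that the pipeline
recovers what the generator injected.

## The synthetic nap generator

`simConfig()` collects the generative parameters; `simulateHypnogram()`,
`simulateEEG()` and `applyStimulationResponse()` produce a nap.

**Stage dynamics.** Stages \{W, N1, N2, N3, R\} evolve as an epoch-level
Markov chain: each 30-s epoch the current stage persists with
probability $1 - 1/\bar d_s$ ($\bar d_s$ = mean dwell in epochs) and
otherwise switches according to configurable weights. Geometric dwell
times keep the epoch process exactly Markov, which gives a closed-form
stationary distribution used as a test oracle. Defaults produce a
nap-like mix (N2-dominant, substantial N3, little REM). Real nap
hypnograms have more structure (sleep cycles, consolidated REM late in
long naps); none of the analyses depend on that structure, only on
stage occupancy and N2/N3 gating.

**Slow oscillations.** SOs are injected at per-stage Poisson rates
(defaults: 7/min in N3, 2/min in N2, none elsewhere) as a half-sine
negative deflection (duration drawn 0.3–0.6 s) followed by a half-sine
positive up-state hump (0.4–0.8 s, peak 0.45 of the negative peak).
The template's negative half-wave is bounded by exact zero crossings,
so it satisfies the detector's criterion by construction. Negative-peak
amplitudes are normal (mean 115, SD 20 µV) truncated to [80, 180] µV.
Events are placed in stratified slots within each epoch so injected
waveforms never overlap. Per-channel gains impose frontal-dominant SO
topography (F3/Fz/F4 = 1.0 down to 0.5 parietally).

**Spindles.** With probability 0.5 an up-state carries a spindle burst:
a Hann-enveloped sinusoid, slow (9–12 Hz, frontal-dominant gains) or
fast (12–15 Hz, parietal-dominant), 20 µV peak, starting just after the
down-to-up transition.

**Background.** Each channel receives $1/f$ Gaussian noise (spectral
exponent 1, flattened below a 0.5-Hz knee so variance is finite),
SD 35 µV. During wake and N1 epochs the background is scaled up by
1.15: real wake EEG carries ocular, muscle and desynchronised activity
absent from artifact-free NREM, and the dynamic threshold deliberately
references this noisier signal. With these defaults the 3σ threshold
lands near 70 µV, inside the tens-of-microvolt range the protocol
reports, and the offline detector reaches precision and recall ≥ 0.85
against ground truth. Channels are generated independently, so
background coherence between channels is near the estimator floor;
only injected events create cross-channel structure.

**Stimulation response.** `applyStimulationResponse()` implements the
efficacy model: for stimulation $i$ with pre-stimulation broadband
power z-score $z_i$ (mean square over the 1-s window before onset,
averaged over channels, z-scored across stimulations), the number of
SOs induced in the 20 s after artifact recovery is
$\mathrm{Poisson}(\lambda_0 e^{-\gamma z_i})$ with defaults
$\lambda_0 = 2.5$, $\gamma = 0.6$ — stimulation during quiescent EEG
produces more SOs, the sign structure the retrospective efficacy
analysis is designed to detect. The artifact itself is modeled as a
rail value (3 mV) during stimulation with an exponential return over
the recovery span; its shape is irrelevant because masked samples are
excluded from every analysis. Ground-truth events overwritten by an
artifact are dropped from the truth tables.

## Slow-oscillation detection

**Dynamic threshold.** `computeThreshold()` returns
$3\sigma$, with $\sigma$ the pooled SD of the band-filtered (0.2–4 Hz,
zero-phase second-order Butterworth), artifact-free samples of F3, Fz
and F4 across all wake and N1 epochs. Computing $\sigma$ on the
filtered signal keeps threshold and detection statistic in the same
units; a `filter_sigma = FALSE` switch reproduces the raw-signal
variant since the convention is not standardised.

**Offline labeling.** `detectSOEvents()` band-filters each channel and
accepts every negative half-wave bounded by zero crossings whose
duration lies in 0.25–1.0 s, whose minimum is at or below $-3\sigma$,
and whose samples lie in N2/N3 epochs outside the artifact mask. For
each event it records the negative-peak time and amplitude, the
down-to-up (positive-going) zero crossing, and the following positive
half-wave's length and maximum as up-state duration and amplitude.
The zero-phase filter smears the up-state hump, so measured up-state
durations run somewhat longer than the injected template hump; the
multi-channel concurrence and slope refinements of the original
labeling criterion are deliberately omitted — only the dynamic
threshold variant is specified by the protocol. Cross-channel merging
(`mergeEventsAcrossChannels()`) collapses detections within a 0.4-s
single-linkage window into one physiological SO stamped at the
earliest peak, which prevents double-counting one SO seen on five
electrodes.

**Causal detection.** The online detector (`onlineDetect()`) must emit
an event only after the down-to-up crossing confirms the half-wave.
Its band signal is a difference of two causal moving averages (0.16-s
smoother minus ~2-s baseline), normalised to unit gain at 1 Hz. Boxcar
averages are exactly linear-phase with integer group delay, so the
detector reports negative-peak times on the offline time base while
remaining strictly causal (latency ≈ 1 s, irrelevant next to the 5-s
stimulation delay). The 0.16-s smoother was chosen so that the causal
detector recovers essentially all offline detections; it admits some
extra near-threshold triggers that the heavier offline filter rejects,
which mirrors deployed closed-loop systems — permissive triggering,
with the scheduler's stage and spacing gates doing the vetting.

## Scheduler and waveform

`scheduleStimulation()` fires at $t_{\mathrm{negpeak}} + 5$ s iff the
sleep stage **at onset** is N2 or N3 and the onset is at least 30 s
(onset-to-onset) after the previous onset; the first cycle is
unconstrained and suppressed triggers are logged with a reason. Stage
gating at onset rather than trigger time is the conservative reading —
if the stage changes during the 5-s delay the cycle is cancelled. No
look-ahead veto is applied: the delay does not preclude stimulating
during a subsequent SO, matching the protocol's stated behaviour. Sham
mode logs every trigger and fires nothing. The waveform is a unipolar
raised sine $I(t) = (i_{\max}/2)(1 - \cos 2\pi f t)$ with $f = 0.75$ Hz
and $i_{\max} = 2$ mA, oscillating between 0 and $i_{\max}$ and
starting/ending at zero — the anodal oscillating convention of the
protocol family this design copies; a bipolar sine sits behind a flag.

## Spectral measures

`psdWelch()` averages Hann-tapered periodograms over 10-s windows (50%
overlap) restricted to sleep epochs; any window touching a masked
sample is dropped. The 10-s window gives 0.1-Hz resolution, needed for
the narrow 0.7–0.8 Hz band around the stimulation frequency.
`bandPower()` integrates the density by the trapezoid rule.

`phaseLockedSpindleEnergy()` band-filters the channel, takes the
analytic (Hilbert) envelope, and integrates the squared envelope over
[down-to-up, +1 s] per event. The 1-s window is a fixed convention for
"during the up state". Event energies are z-scored within channel and
band across the session — the normalisation that makes small-amplitude
spindle measures comparable across participants; channels with fewer
than three events are flagged missing, and zero-variance channels get
all-zero z-scores rather than a division by zero.

`coherenceMatrix()` and the per-stimulation features use a multitaper
estimate with three sine tapers, which keeps magnitude-squared
coherence defined on a single 1-s window without sub-segmentation. With
$K$ tapers the no-coupling bias is about $1/K$; all coherence values
are interpreted relative to that floor, and the tests check the floor
explicitly. Band edges (delta 0.5–4, theta 4–8, alpha 8–12, sigma
12–15, beta 15–30, gamma 30–50, total 0.5–50 Hz) are conventional,
configurable, and always reported with the numbers they produce.

## Pre-stimulation efficacy analysis

For each stimulation: per-band power in the 1-s pre-window
[onset − 1 s, onset), measured per channel over \{Fp1, Fp2, F7, Fz,
FC1\} and averaged; mean pairwise coherence over the ten pairs; and the
outcome — the number of merged SOs on that channel set with negative
peak in (artifact end, artifact end + 20 s] (right-closed boundary,
fixed convention). Pre-windows overlapping an earlier artifact drop the
event with a log entry. `correlateEfficacy()` reports Spearman's rank
correlation (mid-rank ties, t-approximation p) between each feature
and the outcome, separately for N3 and N2 stimulations. Power features
are not log-transformed — Spearman is rank-based, so a monotone
transform would change nothing.

## Sleep architecture

`relabelStimEpochs()` implements the stimulated-session scoring rule:
an epoch more than half covered by artifact takes the label of the next
epoch that is at least half clean (skipping artifact chains; a trailing
dirty epoch keeps its label with a warning). The rule is idempotent.
`sleepSummary()` reports TST (0.5 min × non-wake epochs), SOL, WASO,
SE = 100·TST/time-in-bed with time in bed the full hypnogram span (a
lights-off window is not separately modeled), and stage percentages of
TST.

## Statistics toolbox

Group memory performance is the mean of per-participant ratios
(100 × test/baseline), not the ratio of group means — the construction
that matches how this protocol family summarises recall. Channel
topography tests are paired t-tests with Benjamini–Hochberg step-up
FDR control at 0.05 across channels. The two-way fully-within
repeated-measures ANOVA computes Greenhouse–Geisser ε from the
covariance of orthonormal within-factor contrast scores
($\varepsilon = \mathrm{tr}(S)^2 / (d \cdot \Sigma S_{ij}^2)$),
ε-corrected p-values and partial eta-squared; two-level factors have
ε = 1 exactly, and the implementation is cross-checked against the
`aov()` error-stratum decomposition in the tests. The Wilcoxon
matched-pairs test uses the exact distribution for n ≤ 25 without
ties and the continuity-corrected normal approximation otherwise.
`sampleSizePairedT()` searches n = 2, 3, … for the first sample size
whose exact noncentral-t power (df = n − 1, noncentrality
$d\sqrt{n}$, two-sided α) reaches the target; two-sided testing is the
default since power-analysis sidedness is rarely printed.

## Numerical choices and problem sizes

Stochastic tests freeze seeds and state tolerance bands inline. The
test suite runs the generator at nap lengths of 10–35 min for detector
validation and a full 90-min nap at 250 Hz (all spectral content of
the generator lies far below that Nyquist) with stimulation cycles at
the minimum 30-s spacing (~177 cycles per run) for efficacy-model
recovery — per-run stimulation counts chosen so that ten replicate
runs pool to the cohort-scale event count the retrospective analysis
operates at. The pipeline's cohort default is 17 participants × two
conditions at 90 min and 500 Hz; pipeline tests use three participants
at 8 min.

## Known limitations

* The generator has no K-complexes, arousals, REM phenomenology,
  traveling SOs, or ocular/cardiac channels; passing tests show the
  pipeline recovers the generative structure, not that it handles every
  pathology of real sleep EEG.
* Background noise is independent across channels, so coherence
  dynamics beyond injected events are absent.
* EDF export carries signals, labels and sampling rate only; the
  artifact mask travels separately (stimulation log).
* The online/offline detectors share the threshold but not the filter;
  agreement is near-total on SO-scale events but not bitwise.
* One-way repeated-measures designs are expressed as a two-factor call
  with a dummy second factor; the ANOVA requires complete balanced
  data.
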