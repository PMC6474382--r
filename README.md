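# sdrtes

Closed-loop slow-oscillation stimulation during sleep — protocol logic,
synthetic sleep EEG, and the full analysis pipeline, in R.

## What this package is for

Slow oscillations (SOs) are the large (<1 Hz) waves of deep non-REM
sleep: a hyperpolarised down-state (a deep negative deflection at the
scalp) followed by a depolarised up-state that hosts sleep spindles and
is thought to drive memory consolidation. Closed-loop short-duration
repetitive transcranial electrical stimulation (SDR-tES) tries to
promote SOs: the system detects an SO in real time and, **5 s** after
its negative peak, delivers **4 s** of 0.75-Hz oscillating current
(0–2 mA), with at least **30 s** between stimulation cycles; each cycle
costs ~8 s of EEG (stimulation + amplifier recovery), leaving 22 s of
clean signal per cycle.

The package is for researchers who want to study, extend or reanalyse
this protocol without hardware in the loop. It provides:

* **Synthetic nap EEG** (`simConfig`, `simulateHypnogram`,
  `simulateEEG`, `applyStimulationResponse`): stage-structured
  hypnograms, SOs with frontal-dominant topography, up-state-coupled
  spindles, 1/f background, stimulation artifacts, and an efficacy
  model in which the number of SOs induced by a stimulation is
  Poisson(λ₀·e^(−γz)) with z the pre-stimulation broadband power
  z-score.
* **SO detection** (`computeThreshold`, `detectSOEvents`,
  `mergeEventsAcrossChannels`, `soRate`): the dynamic per-participant
  threshold — 3σ of wake/N1 EEG at F3/Fz/F4 — and zero-crossing-bounded
  negative half-wave labeling during N2/N3, plus up-state metrics.
* **The closed loop** (`onlineDetect`, `scheduleStimulation`,
  `generateStimWaveform`, `applyArtifactMask`): causal detection,
  the 5-s-delay/30-s-spacing scheduler with stage gating and sham
  mode, the raised-sine current waveform, and artifact bookkeeping.
* **Spectral layer** (`psdWelch`, `bandPower`,
  `phaseLockedSpindleEnergy`, `coherenceMatrix`): mask-aware Welch PSD
  at 0.1-Hz resolution, band power, up-state-locked spindle energy
  z-scores, and short-window multitaper coherence.
* **Efficacy analysis** (`prestimFeatures`, `poststimSOCount`,
  `correlateEfficacy`): 1-s pre-stimulation power/coherence features
  versus the SO count in the 20 s after artifact recovery, by sleep
  stage.
* **Sleep architecture** (`relabelStimEpochs`, `sleepSummary`) and the
  **statistics toolbox** (`channelTopographyTest` with BH-FDR,
  `rmAnovaGG` with Greenhouse–Geisser correction and partial η²,
  `descriptiveTests`, `performanceChange`, `sampleSizePairedT`).
* **I/O and orchestration** (`writeEDF`/`readEDF`,
  `writeHypnogramCSV`, `pipelineConfig`, `runPipeline`): EDF and CSV
  round trips and a seeded cohort pipeline that writes the full report
  bundle with a reproducibility manifest.

## Worked example

Simulate a 30-min nap, run the closed loop, and analyse it:

```r
library(sdrtes)

cfg  <- simConfig(duration_s = 1800, seed = 42)
hyp  <- simulateHypnogram(cfg)
sim  <- simulateEEG(cfg, hyp)

thr  <- computeThreshold(sim$eeg, hyp)        # 68.8 uV (3 sigma of wake/N1)
det  <- onlineDetect(sim$eeg, "Fz", thr)
sch  <- scheduleStimulation(det, hyp, recordingDuration = 1800)
nrow(sch$log); nrow(sch$events)               # 68 triggers, 25 fired

head(sch$events[, c("trigger_negpeak_t", "onset", "artifact_end")], 3)
#   trigger_negpeak_t   onset artifact_end
# 1           233.572 238.572      246.572   <- onset = peak + 5 s,
# 2           304.988 309.988      317.988      8-s artifact span
# 3           336.310 341.310      349.310

resp <- applyStimulationResponse(sim$eeg, sim$truth, sch$events, cfg)
hyp2 <- relabelStimEpochs(hyp, artifactMask(resp$eeg), 500)
ev   <- detectSOEvents(resp$eeg, hyp2, computeThreshold(resp$eeg, hyp2))
round(soRate(ev, hyp2, resp$eeg), 2)
#   F4  Fp1   F7  FC1  Fp2   Fz   F3   P3   P4   Pz
# 4.56 4.00 3.69 4.00 4.56 4.21 4.31 1.54 1.49 1.95
```

The threshold lands in the tens-of-microvolt range typical for this
protocol; every onset is exactly 5 s after its trigger; and the SO rate
(events per N2+N3 minute) shows the frontal-dominant topography the
generator injected — frontal channels around 4/min, parietal around
1.5–2/min. A sleep summary of the same session gives TST 28.5 min,
SOL 0.5 min, WASO 1.0 min, SE 95%.

The power-analysis helper reproduces the protocol's sample-size
computation from its effect size:

```r
sampleSizePairedT(d = 0.74, alpha = 0.05, power = 0.92)
# 23  (smallest n whose exact noncentral-t power reaches 0.92)
```

`runPipeline(pipelineConfig(...))` chains all of the above over a
simulated cohort (active and sham nap per participant) and writes
per-session event tables, the sleep-architecture comparison, the
SO-rate channel topography with BH-FDR decisions, the pooled
pre-stimulation efficacy correlations and a JSON manifest.

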