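test_that("threshold is sigma_mult times the wake-noise SD", {
  set.seed(1)
  fs <- 500
  nEp <- 20
  n <- nEp * 30 * fs
  # noise band-limited well inside the detection band, so filtering is
  # transparent and the oracle is a direct SD computation
  sig <- sapply(1:3, function(i) bandNoise(n, fs, lo = 0.8, hi = 2))
  colnames(sig) <- c("F3", "Fz", "F4")
  rec <- EEGRecording(sig, fs)
  h <- flatHypnogram("W", nEp)
  thr <- computeThreshold(rec, h)
  sdPooled <- sqrt(mean(sig^2))
  expect_equal(thr / sdPooled, 3, tolerance = 0.02)
})

test_that("threshold scales linearly with the signal", {
  set.seed(2)
  fs <- 200
  n <- 10 * 30 * fs
  sig <- sapply(1:3, function(i) bandNoise(n, fs))
  colnames(sig) <- c("F3", "Fz", "F4")
  h <- flatHypnogram("W", 10)
  t1 <- computeThreshold(EEGRecording(sig, fs), h)
  t10 <- computeThreshold(EEGRecording(10 * sig, fs), h)
  expect_equal(t10 / t1, 10, tolerance = 1e-6)
})

test_that("generator defaults give thresholds in the expected range", {
  cfg <- simConfig(duration_s = 1200, seed = 17)
  h <- simulateHypnogram(cfg)
  sim <- simulateEEG(cfg, h)
  thr <- computeThreshold(sim$eeg, h)
  expect_gt(thr, 40)
  expect_lt(thr, 110)
})

test_that("threshold errors on missing stages, channels, zero variance", {
  fs <- 100
  sig <- matrix(0, 30 * fs, 3, dimnames = list(NULL, c("F3", "Fz", "F4")))
  rec <- EEGRecording(sig, fs)
  expect_error(computeThreshold(rec, flatHypnogram("N3", 1)), "wake")
  expect_error(computeThreshold(rec, flatHypnogram("W", 1)),
               "zero variance")
  rec2 <- EEGRecording(sig[, 1:2], fs, c("F3", "Fz"))
  expect_error(computeThreshold(rec2, flatHypnogram("W", 1)), "F4")
})

test_that("detection fires on supra-threshold templates only", {
  h <- flatHypnogram("N3", 4)
  recHi <- templateRecording(10, amp = 90)
  ev <- detectSOEvents(recHi, h, threshold = 70, channels = "Fz")
  expect_identical(nrow(ev), 1L)
  # template negative peak is at onset + negDur/2
  expect_equal(ev$t_negpeak, 10 + 0.225, tolerance = 3 / 500)
  expect_equal(ev$t_down_up, 10.45, tolerance = 5 / 500)
  # the zero-phase band filter smears the positive hump, so the measured
  # up-state is somewhat longer than the 0.6-s template hump
  expect_gt(ev$upstate_duration, 0.5)
  expect_lt(ev$upstate_duration, 1.6)
  expect_gt(ev$upstate_amplitude, 0.45 * 90 * 0.6)

  recLo <- templateRecording(10, amp = 50)
  expect_identical(nrow(detectSOEvents(recLo, h, 70, channels = "Fz")),
                   0L)
  flat <- EEGRecording(matrix(0, 120 * 500, 1, dimnames =
                                list(NULL, "Fz")), 500)
  expect_identical(nrow(detectSOEvents(flat, h, 70)), 0L)
})

test_that("detection respects stage gating and the artifact mask", {
  rec <- templateRecording(c(10, 70), amp = 90, duration_s = 120)
  # first template in N3, second in wake
  h <- Hypnogram(c(rep("N3", 2), rep("W", 2)))
  ev <- detectSOEvents(rec, h, 70, channels = "Fz")
  expect_identical(nrow(ev), 1L)
  expect_lt(ev$t_negpeak, 30)

  h3 <- flatHypnogram("N3", 4)
  masked <- rec
  artifactMask(masked) <- seq_len(nSamples(rec)) %in%
    (round(69 * 500):round(72 * 500))
  ev2 <- detectSOEvents(masked, h3, 70, channels = "Fz")
  expect_identical(nrow(ev2), 1L)
  expect_lt(abs(ev2$t_negpeak - 10.225), 0.01)
})

test_that("detection is translation-equivariant", {
  fs <- 500
  k <- 777L
  rec <- templateRecording(10, amp = 90, duration_s = 60)
  x <- signalMatrix(rec)[, "Fz"]
  shifted <- c(numeric(k), x[seq_len(length(x) - k)])
  rec2 <- EEGRecording(matrix(shifted, dimnames = list(NULL, "Fz")), fs)
  h <- flatHypnogram("N3", 2)
  e1 <- detectSOEvents(rec, h, 70, channels = "Fz")
  e2 <- detectSOEvents(rec2, h, 70, channels = "Fz")
  expect_equal(e2$t_negpeak - e1$t_negpeak, k / fs, tolerance = 2 / fs)
})

test_that("SO rate arithmetic and degenerate cases", {
  h <- flatHypnogram("N3", 4)   # 2 minutes
  ev <- data.frame(channel = rep("Fz", 14),
                   t_negpeak = seq(1, 110, length.out = 14))
  expect_equal(unname(soRate(ev, h)["Fz"]), 7.0)
  none <- ev[0, ]
  expect_equal(unname(soRate(none, h, channels = "Fz")["Fz"]), 0)
  expect_error(soRate(ev, flatHypnogram("W", 4)), "NREM")
})

test_that("fully masked epochs drop out of the rate denominator", {
  fs <- 100
  h <- flatHypnogram("N3", 4)
  rec <- EEGRecording(matrix(0, 4 * 30 * fs, 1,
                             dimnames = list(NULL, "Fz")), fs)
  m <- rep(FALSE, nSamples(rec)); m[1:(30 * fs)] <- TRUE
  artifactMask(rec) <- m
  ev <- data.frame(channel = rep("Fz", 3), t_negpeak = c(40, 60, 80))
  expect_equal(unname(soRate(ev, h, rec)["Fz"]), 3 / 1.5)
})

test_that("detector recovers the injected N3 rate at high SNR", {
  cfg <- allN3Config(duration_s = 21 * 60, seed = 31,
                     so_rate = c(W = 0, N1 = 0, N2 = 0, N3 = 5, R = 0),
                     noise = c(exponent = 1, sd = 25, knee = 0.5,
                               wake_scale = 1.15))
  h <- simulateHypnogram(cfg)
  sim <- simulateEEG(cfg, h)
  thr <- computeThreshold(sim$eeg, h)
  ev <- detectSOEvents(sim$eeg, h, thr, channels = "Fz")
  r <- unname(soRate(ev, h, sim$eeg, channels = "Fz")["Fz"])
  minutes <- sum(stages(h) %in% c("N2", "N3")) / 2
  truthRate <- nrow(sim$truth$so_events) / minutes
  expect_gte(r / truthRate, 0.85)
  expect_lte(r / truthRate, 1.15)
})

test_that("cross-channel merging follows single linkage", {
  cfgd <- detectionConfig()
  one <- data.frame(channel = "Fz", t_negpeak = c(5, 9))
  m1 <- mergeEventsAcrossChannels(one, cfgd)
  expect_identical(nrow(m1), 2L)
  expect_equal(m1$t_negpeak, c(5, 9))

  five <- data.frame(channel = c("Fp1", "Fp2", "F7", "Fz", "FC1"),
                     t_negpeak = 10 + c(0, .02, .04, .06, .1))
  m5 <- mergeEventsAcrossChannels(five, cfgd)
  expect_identical(nrow(m5), 1L)
  expect_equal(m5$t_negpeak, 10)
  expect_identical(m5$n_channels, 5L)

  chain <- data.frame(channel = c("Fz", "F3", "F4"),
                      t_negpeak = c(10.0, 10.3, 10.9))
  mc <- mergeEventsAcrossChannels(chain, cfgd)
  expect_identical(nrow(mc), 2L)
  expect_equal(mc$t_negpeak, c(10.0, 10.9))
})

test_that("no detected event overlaps the artifact mask", {
  cfg <- allN3Config(duration_s = 600, seed = 13)
  h <- simulateHypnogram(cfg)
  sim <- simulateEEG(cfg, h)
  onsets <- seq(45, 555, by = 40)
  st <- data.frame(trigger_negpeak_t = onsets - 5, onset = onsets,
                   stim_end = onsets + 4, artifact_end = onsets + 8,
                   stage_at_onset = "N3")
  out <- applyStimulationResponse(sim$eeg, sim$truth, st, cfg)
  thr <- computeThreshold(out$eeg, h)
  ev <- detectSOEvents(out$eeg, h, thr, channels = c("Fz", "F3"))
  fs <- samplingRate(out$eeg)
  idx <- round(ev$t_negpeak * fs) + 1
  expect_false(any(artifactMask(out$eeg)[idx]))
})
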