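test_that("degenerate transitions lock the hypnogram in N3", {
  cfg <- allN3Config(duration_s = 900)
  h <- simulateHypnogram(cfg)
  st <- stages(h)
  expect_identical(st[1], "W")          # recordings start awake
  expect_true(all(st[-1] == "N3"))
})

test_that("the seed fully determines hypnogram and EEG", {
  cfg <- simConfig(duration_s = 300, seed = 5)
  h1 <- simulateHypnogram(cfg)
  h2 <- simulateHypnogram(cfg)
  expect_identical(stages(h1), stages(h2))
  s1 <- simulateEEG(cfg, h1)
  s2 <- simulateEEG(cfg, h2)
  expect_identical(signalMatrix(s1$eeg), signalMatrix(s2$eeg))
  expect_identical(s1$truth$so_events, s2$truth$so_events)
})

test_that("stage occupancy matches the chain's stationary distribution", {
  cfg <- simConfig(duration_s = 10000 * 30, seed = 2)
  h <- simulateHypnogram(cfg)
  # oracle: stationary left eigenvector of the epoch transition matrix
  P <- sdrtes:::epochTransitionMatrix(cfg)
  ev <- eigen(t(P))
  k <- which.min(abs(ev$values - 1))
  pi0 <- Re(ev$vectors[, k]); pi0 <- pi0 / sum(pi0)
  names(pi0) <- colnames(P)
  emp <- table(factor(stages(h), levels = names(pi0))) / nEpochs(h)
  for (s in names(pi0)) {
    se <- sqrt(pi0[s] * (1 - pi0[s]) / nEpochs(h))
    # mixing inflates the binomial error; allow 3 sigma on an effective
    # sample a tenth of the epochs (conservative for dwell <= 10)
    expect_lt(abs(emp[s] - pi0[s]), 3 * se * sqrt(10) + 0.002)
  }
})

test_that("rate-zero configuration yields pure noise and empty truth", {
  cfg <- simConfig(duration_s = 300,
                   so_rate = c(W = 0, N1 = 0, N2 = 0, N3 = 0, R = 0),
                   spindle_prob = 0, seed = 4)
  h <- simulateHypnogram(cfg)
  sim <- simulateEEG(cfg, h)
  expect_identical(nrow(sim$truth$so_events), 0L)
  expect_identical(nrow(sim$truth$spindles), 0L)
  # pure 1/f noise: roughly the configured scale, no huge deflections
  expect_lt(max(abs(signalMatrix(sim$eeg))),
            30 * cfg$noise["sd"])
})

test_that("noiseless injection reproduces the template at channel gains", {
  cfg <- allN3Config(duration_s = 300,
                     noise = c(exponent = 1, sd = 0, knee = 0.5,
                               wake_scale = 1),
                     spindle_prob = 0, seed = 9)
  h <- simulateHypnogram(cfg)
  sim <- simulateEEG(cfg, h)
  tr <- sim$truth$so_events
  expect_gt(nrow(tr), 0)
  sig <- signalMatrix(sim$eeg)
  fs <- samplingRate(sim$eeg)
  g <- cfg$topography$so
  for (k in seq_len(min(nrow(tr), 5))) {
    ipk <- round(tr$t_negpeak[k] * fs) + 1
    ref <- sig[ipk, "Fz"]
    expect_equal(unname(sig[ipk, "P3"] / ref),
                 unname(g["P3"] / g["Fz"]), tolerance = 1e-9)
    expect_equal(unname(ref), tr$amp_negpeak[k], tolerance = 0.02)
    # down-to-up transition is a zero crossing by construction
    iup <- round(tr$t_down_up[k] * fs) + 1
    expect_lt(abs(sig[iup, "Fz"]), abs(ref) * 0.05)
  }
})

test_that("injected N3 SO counts are Poisson around rate * time", {
  cfg <- allN3Config(duration_s = 21 * 60, seed = 6)  # 20 min of N3 + wake
  h <- simulateHypnogram(cfg)
  sim <- simulateEEG(cfg, h)
  minutesN3 <- sum(stages(h) == "N3") / 2
  expected <- cfg$so_rate["N3"] * minutesN3
  expect_lt(abs(nrow(sim$truth$so_events) - expected),
            3 * sqrt(expected))
})

test_that("stimulation response leaves the recording untouched without events", {
  cfg <- allN3Config(duration_s = 120, seed = 8)
  h <- simulateHypnogram(cfg)
  sim <- simulateEEG(cfg, h)
  out <- applyStimulationResponse(sim$eeg, sim$truth,
                                  data.frame()[0, ], cfg)
  expect_identical(signalMatrix(out$eeg), signalMatrix(sim$eeg))
  expect_identical(out$truth$so_events, sim$truth$so_events)
})

test_that("overlapping stimulation spans are rejected", {
  cfg <- allN3Config(duration_s = 120, seed = 8)
  h <- simulateHypnogram(cfg)
  sim <- simulateEEG(cfg, h)
  st <- data.frame(trigger_negpeak_t = c(30, 33), onset = c(35, 38),
                   stim_end = c(39, 42), artifact_end = c(43, 46),
                   stage_at_onset = "N3")
  expect_error(applyStimulationResponse(sim$eeg, sim$truth, st, cfg),
               "overlap")
})

test_that("ground-truth peaks never sit inside the artifact mask", {
  cfg <- allN3Config(duration_s = 600, seed = 12)
  h <- simulateHypnogram(cfg)
  sim <- simulateEEG(cfg, h)
  onsets <- seq(60, 540, by = 35)
  st <- data.frame(trigger_negpeak_t = onsets - 5, onset = onsets,
                   stim_end = onsets + 4, artifact_end = onsets + 8,
                   stage_at_onset = "N3")
  out <- applyStimulationResponse(sim$eeg, sim$truth, st, cfg)
  fs <- samplingRate(out$eeg)
  pk <- round(out$truth$so_events$t_negpeak * fs) + 1
  expect_false(any(artifactMask(out$eeg)[pk]))
  expect_identical(nrow(out$truth$stim_induced), length(onsets))
})

test_that("gamma > 0 makes low-power pre-windows more productive", {
  cfg <- allN3Config(duration_s = 2400, seed = 21,
                     efficacy = c(lambda0 = 2.5, gamma = 1.0))
  h <- simulateHypnogram(cfg)
  sim <- simulateEEG(cfg, h)
  onsets <- seq(60, 2340, by = 35)
  st <- data.frame(trigger_negpeak_t = onsets - 5, onset = onsets,
                   stim_end = onsets + 4, artifact_end = onsets + 8,
                   stage_at_onset = "N3")
  fs <- samplingRate(sim$eeg)
  # oracle pre-power: mean square over the 1-s pre-window, computed here
  prePow <- vapply(onsets, function(on) {
    idx <- (round((on - 1) * fs) + 1):round(on * fs)
    mean(signalMatrix(sim$eeg)[idx, ]^2)
  }, numeric(1))
  out <- applyStimulationResponse(sim$eeg, sim$truth, st, cfg)
  counts <- out$truth$stim_induced$count
  q <- cut(prePow, stats::quantile(prePow, c(0, .25, .75, 1)),
           include.lowest = TRUE, labels = c("lo", "mid", "hi"))
  expect_gt(mean(counts[q == "lo"]), mean(counts[q == "hi"]))
})
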