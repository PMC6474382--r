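# Shared fixtures: all built in code at test time.

# Transition setup that locks the chain in N3 after the initial wake epoch.
allN3Config <- function(duration_s = 600, ...) {
  tr <- matrix(0, 5, 5,
               dimnames = list(c("W", "N1", "N2", "N3", "R"),
                               c("W", "N1", "N2", "N3", "R")))
  tr[, "N3"] <- 1
  tr["N3", "N2"] <- 1e-12       # needs a nonzero off-diagonal row sum
  simConfig(duration_s = duration_s,
            stage_dwell = c(W = 1, N1 = 1, N2 = 1, N3 = 1e9, R = 1),
            stage_transitions = tr, ...)
}

# Hypnogram of one repeated stage.
flatHypnogram <- function(stage, nEpochs) {
  Hypnogram(rep(stage, nEpochs))
}

# Noiseless recording containing SO templates at given onset times on
# every channel (unit gain), embedded in an all-N3 context.
templateRecording <- function(onsets, amp = 90, negDur = 0.45,
                              upDur = 0.6, fs = 500, duration_s = 120,
                              channels = c("F3", "Fz", "F4")) {
  n <- duration_s * fs
  x <- numeric(n)
  tpl <- soTemplate(fs, negDur, upDur, amp)
  for (t0 in onsets) {
    i0 <- round(t0 * fs) + 1
    x[i0:(i0 + length(tpl) - 1)] <- tpl
  }
  sig <- matrix(rep(x, length(channels)), ncol = length(channels),
                dimnames = list(NULL, channels))
  EEGRecording(sig, fs, channels)
}

# Band-limited Gaussian noise (flat in [lo, hi]) of unit variance.
bandNoise <- function(n, fs, lo = 1, hi = 2.5) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]
  X[f < lo | f > hi] <- 0
  y <- Re(stats::fft(X, inverse = TRUE) / n)
  y / stats::sd(y)
}
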