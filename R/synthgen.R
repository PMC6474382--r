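# Synthetic nap-EEG generator: stage-structured hypnograms, slow
# oscillations with frontal-dominant topography, up-state-coupled spindle
# bursts, 1/f background, and a stimulation-response model.

DEFAULT_CHANNELS <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "FC1",
                      "P3", "Pz", "P4")

defaultTopography <- function(channels) {
  so <- c(Fp1 = 0.90, Fp2 = 0.90, F7 = 0.80, F3 = 1.00, Fz = 1.00,
          F4 = 1.00, FC1 = 0.90, P3 = 0.50, Pz = 0.50, P4 = 0.50)
  slow <- c(Fp1 = 0.90, Fp2 = 0.90, F7 = 0.80, F3 = 1.00, Fz = 1.00,
            F4 = 1.00, FC1 = 0.85, P3 = 0.45, Pz = 0.45, P4 = 0.45)
  fast <- c(Fp1 = 0.40, Fp2 = 0.40, F7 = 0.40, F3 = 0.55, Fz = 0.55,
            F4 = 0.55, FC1 = 0.65, P3 = 1.00, Pz = 1.00, P4 = 1.00)
  pick <- function(g) {
    out <- g[channels]
    out[is.na(out)] <- 0.6        # unlisted channels get a neutral gain
    names(out) <- channels
    out
  }
  list(so = pick(so), slow_spindle = pick(slow), fast_spindle = pick(fast))
}

defaultTransitions <- function() {
  # row = from, col = to; weights among non-self stages, renormalised at
  # draw time. Tuned to yield a nap-like stage mix (N2-dominant, sizable
  # N3, little REM).
  m <- matrix(0, 5, 5, dimnames = list(STAGE_LEVELS, STAGE_LEVELS))
  m["W", ] <- c(0, 0.90, 0.10, 0.00, 0.00)
  m["N1", ] <- c(0.15, 0, 0.80, 0.00, 0.05)
  m["N2", ] <- c(0.05, 0.15, 0, 0.70, 0.10)
  m["N3", ] <- c(0.02, 0.08, 0.85, 0, 0.05)
  m["R", ] <- c(0.20, 0.30, 0.50, 0.00, 0)
  m
}

#' Simulation configuration
#'
#' Builds the parameter set for the synthetic nap-EEG generator. Defaults
#' describe a ~90-min nap sampled at 500 Hz on a 10-channel frontal/parietal
#' montage, with slow-oscillation (SO) rates strongly stage dependent
#' (NREM3 >> NREM2, none in wake/NREM1/REM), SO negative-peak amplitudes
#' around 115 microvolt, up-states carrying sleep-spindle bursts, a
#' 1/f background calibrated so the dynamic 3-sigma detection threshold
#' lands in the tens-of-microvolt range, and a stimulation-efficacy model
#' in which the induced post-stimulation SO rate decreases with
#' pre-stimulation broadband power.
#'
#' @param duration_s recording length, s.
#' @param fs sampling rate, Hz.
#' @param channels ordered 10-20-system channel labels.
#' @param stage_dwell named vector, mean stage dwell time in 30-s epochs.
#' @param stage_transitions 5x5 non-negative weight matrix (rows = from,
#'   cols = to, zero diagonal) for stage switches.
#' @param so_rate named vector, SO events per minute per stage.
#' @param so_amp c(mean, sd, min, max): truncated-normal negative-peak
#'   amplitude distribution, microvolt.
#' @param so_shape list with \code{neg_dur} (negative half-wave duration
#'   range, s), \code{up_dur} (up-state hump duration range, s) and
#'   \code{up_frac} (up-state peak as a fraction of the negative peak).
#' @param spindle_prob probability that an SO up-state carries a spindle.
#' @param spindle_bands list of slow/fast spindle bands, Hz.
#' @param spindle_amp spindle burst peak amplitude, microvolt.
#' @param topography list of per-channel gain maps (\code{so},
#'   \code{slow_spindle}, \code{fast_spindle}).
#' @param noise c(exponent, sd, knee, wake_scale): 1/f background
#'   parameters (spectral exponent, standard deviation in microvolt,
#'   low-frequency knee in Hz, and the multiplicative factor applied to
#'   background amplitude during wake and NREM1 epochs). The wake/NREM1
#'   scale-up emulates the ocular, muscle and desynchronised activity
#'   that contaminates real wake EEG and that the dynamic 3-sigma
#'   threshold deliberately references.
#' @param efficacy c(lambda0, gamma): baseline induced-SO count per
#'   stimulation and its sensitivity to the pre-stimulation broadband
#'   power z-score (rate = lambda0 * exp(-gamma * z)).
#' @param seed integer seed; fully determines the generator output.
#' @return A list of class \code{"SimConfig"}.
#' @examples
#' cfg <- simConfig(duration_s = 600, seed = 7)
#' h <- simulateHypnogram(cfg)
#' @export
simConfig <- function(duration_s = 5400,
                      fs = 500,
                      channels = DEFAULT_CHANNELS,
                      stage_dwell = c(W = 3, N1 = 3, N2 = 10, N3 = 8,
                                      R = 4),
                      stage_transitions = defaultTransitions(),
                      so_rate = c(W = 0, N1 = 0, N2 = 2, N3 = 7, R = 0),
                      so_amp = c(mean = 115, sd = 20, min = 80,
                                 max = 180),
                      so_shape = list(neg_dur = c(0.3, 0.6),
                                      up_dur = c(0.4, 0.8),
                                      up_frac = 0.45),
                      spindle_prob = 0.5,
                      spindle_bands = list(slow = c(9, 12),
                                           fast = c(12, 15)),
                      spindle_amp = 20,
                      topography = NULL,
                      noise = c(exponent = 1, sd = 35, knee = 0.5,
                                wake_scale = 1.15),
                      efficacy = c(lambda0 = 2.5, gamma = 0.6),
                      seed = 1L) {
  if (length(channels) < 1L) stop("channel list must not be empty")
  if (fs <= 0 || duration_s <= 0)
    stop("fs and duration_s must be positive")
  if (any(so_rate < 0)) stop("per-stage SO rates must be >= 0")
  if (spindle_prob < 0 || spindle_prob > 1)
    stop("spindle_prob must lie in [0, 1]")
  if (is.null(topography)) topography <- defaultTopography(channels)
  if (any(unlist(topography) < 0)) stop("topography gains must be >= 0")
  stopifnot(all(STAGE_LEVELS %in% names(stage_dwell)),
            all(STAGE_LEVELS %in% names(so_rate)),
            all(stage_dwell >= 1))
  structure(list(duration_s = duration_s, fs = fs, channels = channels,
                 stage_dwell = stage_dwell,
                 stage_transitions = stage_transitions,
                 so_rate = so_rate, so_amp = so_amp, so_shape = so_shape,
                 spindle_prob = spindle_prob,
                 spindle_bands = spindle_bands,
                 spindle_amp = spindle_amp,
                 topography = topography, noise = noise,
                 efficacy = efficacy, seed = as.integer(seed)),
            class = "SimConfig")
}

#' Simulate a stage-structured hypnogram
#'
#' Epoch-level Markov chain over \{W, N1, N2, N3, R\}: at each 30-s epoch
#' the stage persists with probability 1 - 1/dwell and otherwise switches
#' according to the (renormalised) transition weights. The recording
#' starts in wake. Geometric dwell times make the epoch process exactly
#' Markov, so its stationary distribution is available in closed form for
#' testing.
#'
#' @param config a [simConfig()] list.
#' @return A [Hypnogram-class] covering \code{config$duration_s}.
#' @export
simulateHypnogram <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  nep <- floor(config$duration_s / 30)
  if (nep < 1L) stop("duration shorter than one 30-s epoch")
  set.seed(config$seed)
  P <- epochTransitionMatrix(config)
  st <- character(nep)
  st[1] <- "W"
  for (i in seq_len(nep - 1L)) {
    st[i + 1L] <- sample(STAGE_LEVELS, 1L, prob = P[st[i], ])
  }
  Hypnogram(st, 30)
}

# Epoch-level transition matrix implied by dwell times + switch weights.
epochTransitionMatrix <- function(config) {
  P <- matrix(0, 5, 5, dimnames = list(STAGE_LEVELS, STAGE_LEVELS))
  for (s in STAGE_LEVELS) {
    pLeave <- 1 / config$stage_dwell[s]
    w <- config$stage_transitions[s, ]
    w <- if (sum(w) > 0) w / sum(w) else
      stats::setNames(rep(0.25, 5), STAGE_LEVELS)
    P[s, ] <- pLeave * w
    P[s, s] <- 1 - pLeave
  }
  P
}

#' Slow-oscillation waveform template
#'
#' Half-sine negative deflection of duration \code{negDur} followed by a
#' half-sine positive up-state hump of duration \code{upDur}. The template
#' satisfies the zero-crossing detection criteria by construction: its
#' negative half-wave is bounded by exact zero crossings and the
#' down-to-up transition sits at \code{negDur}.
#'
#' @param fs sampling rate, Hz.
#' @param negDur negative half-wave duration, s.
#' @param upDur up-state hump duration, s.
#' @param amp negative-peak magnitude, microvolt (positive number).
#' @param upFrac up-state peak as a fraction of \code{amp}.
#' @return Numeric vector of length \code{round((negDur + upDur) * fs)}.
#' @export
soTemplate <- function(fs, negDur = 0.45, upDur = 0.6, amp = 100,
                       upFrac = 0.45) {
  n1 <- round(negDur * fs)
  n2 <- round(upDur * fs)
  t1 <- seq_len(n1) / fs
  t2 <- seq_len(n2) / fs
  c(-amp * sin(pi * t1 / negDur), amp * upFrac * sin(pi * t2 / upDur))
}

# Place nEv non-overlapping event start times in [t0, t0 + span), each of
# length evDur, by stratified slots. Returns numeric vector (possibly
# shorter than nEv if span is too crowded).
slotTimes <- function(nEv, t0, span, evDur) {
  nEv <- min(nEv, floor(span / (evDur + 0.2)))
  if (nEv < 1L) return(numeric())
  slot <- span / nEv
  t0 + (seq_len(nEv) - 1L) * slot +
    stats::runif(nEv, 0, pmax(slot - evDur, 0))
}

#' Simulate a multichannel nap EEG with ground truth
#'
#' Injects per-stage Poisson slow oscillations (half-sine template, scaled
#' by the frontal-dominant SO topography), spindle bursts phase-locked to
#' SO up-states (Hann-enveloped sinusoid in the slow or fast band, scaled
#' by the band topography), and 1/f background noise. Event placement is
#' stratified within each epoch so injected waveforms never overlap.
#'
#' @param config a [simConfig()].
#' @param hypnogram a [Hypnogram-class] covering the duration, usually
#'   from [simulateHypnogram()].
#' @return A list with elements \code{eeg} ([EEGRecording-class]) and
#'   \code{truth}: \code{so_events} (channel, t_negpeak, amp_negpeak,
#'   t_down_up, induced), \code{spindles} (channel, onset, band, energy)
#'   and \code{stim_induced} (empty until
#'   [applyStimulationResponse()] runs).
#' @export
simulateEEG <- function(config, hypnogram) {
  stopifnot(inherits(config, "SimConfig"), is(hypnogram, "Hypnogram"))
  if (duration(hypnogram) < config$duration_s - 1e-9)
    stop("hypnogram does not cover the configured duration")
  if (length(config$channels) < 1L) stop("channel list must not be empty")
  set.seed(config$seed + 1L)
  fs <- config$fs
  n <- round(config$duration_s * fs)
  nch <- length(config$channels)

  sig <- matrix(0, n, nch, dimnames = list(NULL, config$channels))
  if (config$noise["sd"] > 0) {
    wakeScale <- config$noise["wake_scale"]
    if (is.na(wakeScale)) wakeScale <- 1
    inWake <- samplesInStages(hypnogram, fs, n, c("W", "N1"))
    for (j in seq_len(nch)) {
      nz <- oneOverFNoise(n, fs, config$noise["exponent"],
                          config$noise["sd"], config$noise["knee"])
      if (wakeScale != 1) nz[inWake] <- wakeScale * nz[inWake]
      sig[, j] <- nz
    }
  }

  soRef <- config$channels[which.max(config$topography$so)]
  maxDur <- max(config$so_shape$neg_dur) + max(config$so_shape$up_dur)
  soRows <- list(); spRows <- list()
  epl <- epochLength(hypnogram)
  nepCovered <- floor(config$duration_s / epl)

  for (ep in seq_len(nepCovered)) {
    stg <- stages(hypnogram)[ep]
    rate <- config$so_rate[stg]
    if (rate <= 0) next
    nEv <- stats::rpois(1, rate * epl / 60)
    if (nEv < 1L) next
    t0s <- slotTimes(nEv, (ep - 1L) * epl, epl, maxDur)
    for (t0 in t0s) {
      ev <- drawSOEvent(fs, t0, config, colnames(sig), n)
      sig[ev$idx, ] <- sig[ev$idx, ] + ev$add
      soRows[[length(soRows) + 1L]] <- ev$so
      if (!is.null(ev$spindle)) {
        sp <- ev$spindle
        sig[sp$idx, ] <- sig[sp$idx, ] + sp$add
        spRows[[length(spRows) + 1L]] <- sp$row
      }
    }
  }

  truth <- list(
    hypnogram = hypnogram,
    so_events = bindEventRows(soRows, c("channel", "t_negpeak",
                                        "amp_negpeak", "t_down_up",
                                        "induced")),
    spindles = bindEventRows(spRows, c("channel", "onset", "band",
                                       "energy")),
    stim_induced = data.frame(stim_id = integer(), count = integer())
  )
  list(eeg = EEGRecording(sig, fs, config$channels), truth = truth)
}

bindEventRows <- function(rows, cols) {
  if (!length(rows)) {
    out <- as.data.frame(stats::setNames(
      lapply(cols, function(x) {
        if (x %in% c("channel", "band")) character() else numeric()
      }), cols))
    if ("induced" %in% cols) out$induced <- logical()
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out[[2L]]), , drop = FALSE]
}

# Draw one SO (and possibly a coupled spindle). Returns the sample
# indices and the per-channel additive waveform (small matrices, so the
# caller can add them in place without copying the recording), plus the
# ground-truth rows. Uses the current RNG stream.
drawSOEvent <- function(fs, t0, config, channels, nTotal,
                        induced = FALSE) {
  d1 <- runif1(config$so_shape$neg_dur[1], config$so_shape$neg_dur[2])
  d2 <- runif1(config$so_shape$up_dur[1], config$so_shape$up_dur[2])
  A <- truncNorm1(config$so_amp["mean"], config$so_amp["sd"],
                  config$so_amp["min"], config$so_amp["max"])
  tpl <- soTemplate(fs, d1, d2, A, config$so_shape$up_frac)
  i0 <- round(t0 * fs) + 1L
  idx <- i0:(i0 + length(tpl) - 1L)
  idx <- idx[idx <= nTotal]
  gains <- config$topography$so
  soRef <- channels[which.max(gains)]
  so <- data.frame(channel = soRef,
                   t_negpeak = t0 + d1 / 2,
                   amp_negpeak = -A * max(gains),
                   t_down_up = t0 + d1,
                   induced = induced)

  spindle <- NULL
  if (stats::runif(1) < config$spindle_prob) {
    bandName <- sample(names(config$spindle_bands), 1L)
    band <- config$spindle_bands[[bandName]]
    f0 <- runif1(band[1], band[2])
    sdur <- max(0.4, min(d2, 0.8))
    onset <- t0 + d1 + 0.02
    ns <- round(sdur * fs)
    tt <- seq_len(ns) / fs
    burst <- config$spindle_amp * sin(pi * tt / sdur)^2 *
      sin(2 * pi * f0 * tt)
    sGains <- config$topography[[paste0(bandName, "_spindle")]]
    j0 <- round(onset * fs) + 1L
    sidx <- j0:(j0 + ns - 1L)
    sidx <- sidx[sidx <= nTotal]
    spindle <- list(idx = sidx,
                    add = outer(burst[seq_along(sidx)], sGains),
                    row = data.frame(channel = channels[which.max(sGains)],
                                     onset = onset, band = bandName,
                                     energy = sum((max(sGains) *
                                                     burst)^2) / fs))
  }
  list(idx = idx, add = outer(tpl[seq_along(idx)], gains), so = so,
       spindle = spindle)
}

truncNorm1 <- function(mean, sd, lo, hi) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

#' Apply the stimulation-response model to a simulated recording
#'
#' For each stimulation cycle: (i) replaces samples in
#' [onset, artifact_end] with a saturating artifact (rail value during the
#' stimulation span, exponential return during amplifier recovery) and
#' flags them in the artifact mask; (ii) draws the number of induced slow
#' oscillations from Poisson(lambda0 * exp(-gamma * z)), where z is the
#' z-score (across stimulations) of mean broadband signal power in the 1-s
#' pre-stimulation window, and injects them in the 20 s after recovery.
#' Endogenous ground-truth events whose negative peak falls inside an
#' artifact span are removed from the truth tables (the artifact
#' overwrites them).
#'
#' @param eeg an [EEGRecording-class] from [simulateEEG()].
#' @param truth the matching ground-truth list.
#' @param stimEvents data.frame of stimulation cycles as returned by
#'   [scheduleStimulation()] (columns \code{trigger_negpeak_t},
#'   \code{onset}, \code{stim_end}, \code{artifact_end},
#'   \code{stage_at_onset}).
#' @param config the [simConfig()] used to build the recording.
#' @return A list \code{list(eeg, truth)} with the artifacted recording
#'   and the updated ground truth (\code{stim_induced} filled in).
#' @export
applyStimulationResponse <- function(eeg, truth, stimEvents, config) {
  stopifnot(is(eeg, "EEGRecording"), inherits(config, "SimConfig"))
  if (is.null(stimEvents) || nrow(stimEvents) == 0L)
    return(list(eeg = eeg, truth = truth))
  fs <- samplingRate(eeg)
  n <- nSamples(eeg)
  ord <- order(stimEvents$onset)
  stimEvents <- stimEvents[ord, , drop = FALSE]
  if (any(stimEvents$artifact_end > n / fs + 1e-9) ||
      any(stimEvents$onset < 0))
    stop("stimulation events must lie within the recording")
  if (nrow(stimEvents) > 1L &&
      any(utils::head(stimEvents$artifact_end, -1) >
          utils::tail(stimEvents$onset, -1)))
    stop("overlapping stimulation spans")

  set.seed(config$seed + 2L)
  sig <- signalMatrix(eeg)
  mask <- artifactMask(eeg)

  # pre-stimulation broadband power (mean square across channels, 1-s
  # window before onset), z-scored across stimulations
  prePower <- vapply(seq_len(nrow(stimEvents)), function(k) {
    i1 <- max(1L, round((stimEvents$onset[k] - 1) * fs) + 1L)
    i2 <- round(stimEvents$onset[k] * fs)
    mean(sig[i1:i2, , drop = FALSE]^2)
  }, numeric(1))
  z <- if (stats::sd(prePower) > 0)
    (prePower - mean(prePower)) / stats::sd(prePower) else prePower * 0

  lambda0 <- config$efficacy["lambda0"]
  gamma <- config$efficacy["gamma"]
  counts <- stats::rpois(nrow(stimEvents), lambda0 * exp(-gamma * z))

  rail <- 3000
  soRows <- list()
  for (k in seq_len(nrow(stimEvents))) {
    iOn <- round(stimEvents$onset[k] * fs) + 1L
    iStimEnd <- round(stimEvents$stim_end[k] * fs)
    iArtEnd <- min(round(stimEvents$artifact_end[k] * fs), n)
    stimIdx <- iOn:iStimEnd
    recIdx <- if (iStimEnd < iArtEnd) (iStimEnd + 1L):iArtEnd else
      integer()
    decay <- rail * exp(-(seq_along(recIdx) / fs) /
                          ((stimEvents$artifact_end[k] -
                              stimEvents$stim_end[k]) / 5))
    for (j in seq_len(ncol(sig))) {
      sig[stimIdx, j] <- rail
      sig[recIdx, j] <- decay
    }
    mask[iOn:iArtEnd] <- TRUE

    kInd <- counts[k]
    if (kInd > 0L) {
      maxDur <- max(config$so_shape$neg_dur) + max(config$so_shape$up_dur)
      span <- min(20, n / fs - stimEvents$artifact_end[k])
      t0s <- slotTimes(kInd, stimEvents$artifact_end[k], span, maxDur)
      counts[k] <- length(t0s)
      for (t0 in t0s) {
        ev <- drawSOEvent(fs, t0, config, colnames(sig), n,
                          induced = TRUE)
        sig[ev$idx, ] <- sig[ev$idx, ] + ev$add
        if (!is.null(ev$spindle))
          sig[ev$spindle$idx, ] <- sig[ev$spindle$idx, ] +
            ev$spindle$add
        soRows[[length(soRows) + 1L]] <- ev$so
        # spindle truth rows for induced SOs are not tracked: the
        # efficacy analyses only count SOs
      }
    }
  }

  # drop endogenous events overwritten by artifacts
  pk <- round(truth$so_events$t_negpeak * fs) + 1L
  keep <- !mask[pmin(pmax(pk, 1L), n)]
  truth$so_events <- truth$so_events[keep, , drop = FALSE]
  if (nrow(truth$spindles)) {
    onIdx <- pmin(pmax(round(truth$spindles$onset * fs) + 1L, 1L), n)
    truth$spindles <- truth$spindles[!mask[onIdx], , drop = FALSE]
  }

  newSO <- bindEventRows(soRows, c("channel", "t_negpeak", "amp_negpeak",
                                   "t_down_up", "induced"))
  truth$so_events <- rbind(truth$so_events, newSO)
  truth$so_events <-
    truth$so_events[order(truth$so_events$t_negpeak), , drop = FALSE]
  rownames(truth$so_events) <- NULL
  truth$stim_induced <- data.frame(stim_id = seq_len(nrow(stimEvents)),
                                   count = as.integer(counts))

  out <- eeg
  out@signals <- sig
  out@mask <- mask
  validObject(out)
  list(eeg = out, truth = truth)
}
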