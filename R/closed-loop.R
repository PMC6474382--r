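# Causal SO detection and the SDR-tES stimulation scheduler: 5-s delay
# from the SO negative peak, 30-s minimum cycle spacing, 4-s 0.75-Hz
# stimulation followed by 4-s amplifier recovery.

#' Closed-loop protocol configuration
#'
#' @param delay_s delay from the trigger SO negative peak to stimulation
#'   onset, s (default 5).
#' @param min_interval_s minimum onset-to-onset spacing between
#'   stimulation cycles, s (default 30).
#' @param stim_duration_s stimulation duration, s (default 4).
#' @param recovery_s amplifier recovery after stimulation, s (default 4).
#' @param stim_freq stimulation frequency, Hz (default 0.75).
#' @param i_max maximum current intensity, mA (default 2.0).
#' @param gate_stages stages in which stimulation may fire.
#' @param enabled \code{FALSE} gives sham mode: detections are logged but
#'   no stimulation fires and the recording is untouched.
#' @param waveform \code{"raised"} (unipolar raised sine, 0 to i_max) or
#'   \code{"sine"} (bipolar).
#' @return A list of class \code{"ClosedLoopConfig"}.
#' @export
closedLoopConfig <- function(delay_s = 5, min_interval_s = 30,
                             stim_duration_s = 4, recovery_s = 4,
                             stim_freq = 0.75, i_max = 2.0,
                             gate_stages = c("N2", "N3"),
                             enabled = TRUE,
                             waveform = c("raised", "sine")) {
  stopifnot(delay_s > 0, min_interval_s > 0, stim_duration_s > 0,
            recovery_s > 0, stim_freq > 0, i_max >= 0)
  if (min_interval_s < stim_duration_s + recovery_s)
    stop("min_interval_s must cover stimulation plus recovery")
  structure(list(delay_s = delay_s, min_interval_s = min_interval_s,
                 stim_duration_s = stim_duration_s,
                 recovery_s = recovery_s, stim_freq = stim_freq,
                 i_max = i_max, gate_stages = gate_stages,
                 enabled = enabled,
                 waveform = match.arg(waveform)),
            class = "ClosedLoopConfig")
}

#' Causal (streaming) slow-oscillation detection
#'
#' Detects SO negative half-waves using only past samples: the band
#' signal is an exactly linear-phase difference of two causal moving
#' averages (a 0.16-s smoother minus a ~2-s baseline), so the detector
#' can compensate the integer group delay and report negative-peak times
#' on the offline time base. An event is emitted only after the
#' positive-going (down-to-up) zero crossing confirms the half-wave; the
#' emission time (\code{t_emit}) therefore trails \code{t_down_up} by the
#' filter latency.
#'
#' @param eeg an [EEGRecording-class] (treated as the stream).
#' @param channel channel monitored by the online system (default
#'   \code{"Fz"}).
#' @param threshold negative-peak threshold, microvolt.
#' @param config a [detectionConfig()] (duration bounds are shared with
#'   the offline detector).
#' @return data.frame with \code{t_negpeak}, \code{t_down_up},
#'   \code{t_emit}, sorted by time.
#' @export
onlineDetect <- function(eeg, channel = "Fz", threshold,
                         config = detectionConfig()) {
  stopifnot(is(eeg, "EEGRecording"), threshold > 0)
  fs <- samplingRate(eeg)
  x <- channelSignal(eeg, channel)
  L1 <- makeOdd(round(0.16 * fs))
  L2 <- makeOdd(round(2 * fs))
  b <- centeredMA(x, L1) - centeredMA(x, L2)
  # normalise to unit gain at 1 Hz (the SO fundamental) so the
  # microvolt threshold keeps its offline meaning
  b <- b / (boxcarGain(L1, 1, fs) - boxcarGain(L2, 1, fs))
  latency <- (L2 - 1) / 2 / fs
  hw <- negativeHalfwaves(b)
  if (!nrow(hw))
    return(data.frame(t_negpeak = numeric(), t_down_up = numeric(),
                      t_emit = numeric()))
  dur <- (hw$end - hw$start + 1L) / fs
  keep <- dur >= config$neg_halfwave_bounds[1] &
    dur <= config$neg_halfwave_bounds[2] &
    hw$vmin <= -threshold
  hw <- hw[keep, , drop = FALSE]
  data.frame(t_negpeak = (hw$imin - 1L) / fs,
             t_down_up = (hw$iup - 1L) / fs,
             t_emit = (hw$iup - 1L) / fs + latency)
}

makeOdd <- function(n) if (n %% 2 == 0) n + 1L else n

# Magnitude response of a length-L boxcar average at frequency f.
boxcarGain <- function(L, f, fs) {
  abs(sin(pi * f * L / fs) / (L * sin(pi * f / fs)))
}

# Centered moving average with zero-padded edges (delay-compensated view
# of a causal boxcar of length L).
centeredMA <- function(x, L) {
  y <- stats::filter(c(rep(0, L), x, rep(0, L)), rep(1 / L, L),
                     sides = 2)
  as.numeric(y[(L + 1):(L + length(x))])
}

#' Schedule stimulation cycles from detections
#'
#' Implements the SDR-tES trigger rule: a stimulation fires at
#' \code{t_negpeak + delay_s} iff the sleep stage at onset is in
#' \code{gate_stages} and the onset is at least \code{min_interval_s}
#' after the previous onset (onset-to-onset; the first cycle is
#' unconstrained). Suppressed triggers are logged with a reason. In sham
#' mode every trigger is logged as suppressed and no cycle fires.
#'
#' @param detections data.frame with a \code{t_negpeak} column (from
#'   [onlineDetect()] or [detectSOEvents()]), time-sorted or not.
#' @param hypnogram the stage stream as a [Hypnogram-class].
#' @param config a [closedLoopConfig()].
#' @param recordingDuration optional recording length, s; cycles whose
#'   artifact span would overrun the recording are suppressed.
#' @return List with \code{events} (fired cycles: data.frame
#'   \code{trigger_negpeak_t}, \code{onset}, \code{stim_end},
#'   \code{artifact_end}, \code{stage_at_onset}) and \code{log} (every
#'   trigger with a \code{suppressed_reason}, empty string if fired).
#' @export
scheduleStimulation <- function(detections, hypnogram,
                                config = closedLoopConfig(),
                                recordingDuration = NULL) {
  stopifnot(is(hypnogram, "Hypnogram"))
  tn <- sort(detections$t_negpeak)
  lastOnset <- -Inf
  rows <- vector("list", length(tn))
  for (k in seq_along(tn)) {
    onset <- tn[k] + config$delay_s
    stimEnd <- onset + config$stim_duration_s
    artEnd <- stimEnd + config$recovery_s
    stg <- stageAt(hypnogram, onset)
    reason <- ""
    if (!config$enabled) {
      reason <- "sham"
    } else if (is.na(stg) || !(stg %in% config$gate_stages)) {
      reason <- "stage"
    } else if (onset - lastOnset < config$min_interval_s) {
      reason <- "spacing"
    } else if (!is.null(recordingDuration) &&
               artEnd > recordingDuration) {
      reason <- "end_of_recording"
    }
    if (reason == "") lastOnset <- onset
    rows[[k]] <- data.frame(trigger_negpeak_t = tn[k], onset = onset,
                            stim_end = stimEnd, artifact_end = artEnd,
                            stage_at_onset = as.character(stg),
                            suppressed_reason = reason)
  }
  log <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trigger_negpeak_t = numeric(), onset = numeric(),
               stim_end = numeric(), artifact_end = numeric(),
               stage_at_onset = character(),
               suppressed_reason = character())
  events <- log[log$suppressed_reason == "",
                setdiff(names(log), "suppressed_reason"), drop = FALSE]
  rownames(events) <- NULL
  list(events = events, log = log)
}

#' Stimulation current waveform
#'
#' Four seconds (by default) of 0.75-Hz oscillating current. The default
#' unipolar raised sine \eqn{I(t) = (i_{max}/2)(1 - \cos 2\pi f t)}
#' oscillates between 0 and \code{i_max} and starts and ends at zero; a
#' bipolar pure sine is available behind the \code{waveform} flag.
#'
#' @param config a [closedLoopConfig()].
#' @param fs sampling rate, Hz.
#' @return Numeric vector of current values, mA.
#' @export
generateStimWaveform <- function(config = closedLoopConfig(), fs) {
  stopifnot(fs > 2 * config$stim_freq)
  n <- round(config$stim_duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  if (config$waveform == "raised")
    (config$i_max / 2) * (1 - cos(2 * pi * config$stim_freq * t))
  else
    config$i_max * sin(2 * pi * config$stim_freq * t)
}

#' Flag stimulation artifacts in the recording mask
#'
#' Marks every sample in [onset, artifact_end] of each stimulation cycle
#' in the artifact mask; all analysis operations exclude masked samples.
#'
#' @param eeg an [EEGRecording-class].
#' @param stimEvents fired cycles from [scheduleStimulation()].
#' @return The recording with an updated mask.
#' @export
applyArtifactMask <- function(eeg, stimEvents) {
  stopifnot(is(eeg, "EEGRecording"))
  if (is.null(stimEvents) || nrow(stimEvents) == 0L) return(eeg)
  ev <- stimEvents[order(stimEvents$onset), , drop = FALSE]
  if (nrow(ev) > 1L &&
      any(utils::head(ev$artifact_end, -1) > utils::tail(ev$onset, -1)))
    stop("overlapping stimulation events")
  fs <- samplingRate(eeg)
  n <- nSamples(eeg)
  if (any(ev$onset < 0) || any(ev$artifact_end > n / fs + 1e-9))
    stop("stimulation events must lie within the recording")
  mask <- artifactMask(eeg)
  for (k in seq_len(nrow(ev))) {
    i1 <- round(ev$onset[k] * fs) + 1L
    i2 <- min(round(ev$artifact_end[k] * fs), n)
    mask[i1:i2] <- TRUE
  }
  artifactMask(eeg) <- mask
  eeg
}
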