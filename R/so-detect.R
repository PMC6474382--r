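# Offline slow-oscillation detection with a per-participant dynamic
# threshold, SO-rate and up-state metrics, and cross-channel merging.

#' Detection configuration
#'
#' Parameters for offline and causal slow-oscillation labeling. The
#' detection statistic is the zero-phase band-filtered signal; a negative
#' half-wave bounded by zero crossings is an SO when its duration lies in
#' \code{neg_halfwave_bounds} and its minimum is at or below minus the
#' dynamic threshold (3 sigma of wake/NREM1 EEG at the frontal threshold
#' channels).
#'
#' @param band SO band-pass corner frequencies, Hz.
#' @param sigma_mult threshold multiplier on the wake/NREM1 standard
#'   deviation (default 3).
#' @param neg_halfwave_bounds admissible negative half-wave duration, s.
#' @param threshold_channels channels pooled for the sigma estimate.
#' @param merge_window cross-channel merge window, s.
#' @param filter_sigma if \code{TRUE} (default) sigma is computed on the
#'   band-filtered signal, so threshold and detection statistic share
#'   units; \code{FALSE} uses the raw signal.
#' @return A list of class \code{"DetectionConfig"}.
#' @export
detectionConfig <- function(band = c(0.2, 4),
                            sigma_mult = 3,
                            neg_halfwave_bounds = c(0.25, 1.0),
                            threshold_channels = c("F3", "Fz", "F4"),
                            merge_window = 0.4,
                            filter_sigma = TRUE) {
  stopifnot(band[1] < band[2], sigma_mult > 0,
            neg_halfwave_bounds[1] < neg_halfwave_bounds[2],
            merge_window >= 0)
  structure(list(band = band, sigma_mult = sigma_mult,
                 neg_halfwave_bounds = neg_halfwave_bounds,
                 threshold_channels = threshold_channels,
                 merge_window = merge_window,
                 filter_sigma = filter_sigma),
            class = "DetectionConfig")
}

#' Dynamic SO detection threshold
#'
#' Computes the per-participant negative-peak detection threshold as
#' \code{sigma_mult} times the pooled standard deviation of the
#' band-filtered, artifact-free EEG of the frontal threshold channels
#' (F3, Fz, F4 by default) restricted to all wake and NREM1 epochs.
#'
#' @param eeg an [EEGRecording-class].
#' @param hypnogram the matching [Hypnogram-class].
#' @param config a [detectionConfig()].
#' @return Threshold in microvolt (positive scalar).
#' @export
computeThreshold <- function(eeg, hypnogram, config = detectionConfig()) {
  stopifnot(is(eeg, "EEGRecording"), is(hypnogram, "Hypnogram"))
  miss <- setdiff(config$threshold_channels, channelNames(eeg))
  if (length(miss))
    stop("threshold channel(s) absent: ", paste(miss, collapse = ", "))
  fs <- samplingRate(eeg)
  sel <- samplesInStages(hypnogram, fs, nSamples(eeg), c("W", "N1")) &
    !artifactMask(eeg)
  if (!any(sel))
    stop("no wake/NREM1 epochs available for threshold estimation")
  pooled <- unlist(lapply(config$threshold_channels, function(ch) {
    x <- channelSignal(eeg, ch)
    if (config$filter_sigma)
      x <- bandpassFilter(x, fs, config$band)
    x[sel]
  }))
  sigma <- sqrt(mean((pooled - mean(pooled))^2))
  if (sigma == 0) stop("degenerate input: zero variance in wake/NREM1")
  config$sigma_mult * sigma
}

#' Offline slow-oscillation event detection
#'
#' Per channel: zero-phase band-filter, locate negative half-waves bounded
#' by zero crossings, keep those with duration inside the configured
#' bounds, minimum at or below \code{-threshold}, and all samples inside
#' NREM2/NREM3 epochs and outside the artifact mask. For each event the
#' down-to-up transition (positive-going zero crossing), up-state
#' amplitude (maximum of the following positive half-wave) and up-state
#' duration (that half-wave's length) are recorded.
#'
#' @inheritParams computeThreshold
#' @param threshold negative-peak threshold, microvolt (positive scalar,
#'   usually from [computeThreshold()]).
#' @param channels channels to scan; default all.
#' @return data.frame with columns \code{channel}, \code{t_negpeak},
#'   \code{amp_negpeak}, \code{t_down_up}, \code{upstate_duration},
#'   \code{upstate_amplitude}, sorted by time.
#' @export
detectSOEvents <- function(eeg, hypnogram, threshold,
                           config = detectionConfig(),
                           channels = channelNames(eeg)) {
  stopifnot(is(eeg, "EEGRecording"), threshold > 0)
  miss <- setdiff(channels, channelNames(eeg))
  if (length(miss))
    stop("channel(s) absent: ", paste(miss, collapse = ", "))
  fs <- samplingRate(eeg)
  ok <- samplesInStages(hypnogram, fs, nSamples(eeg), c("N2", "N3")) &
    !artifactMask(eeg)
  out <- lapply(channels, function(ch) {
    x <- bandpassFilter(channelSignal(eeg, ch), fs, config$band)
    detectOnFiltered(x, fs, threshold, config, ok, ch)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$t_negpeak), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Shared half-wave criterion on an already-filtered channel.
detectOnFiltered <- function(x, fs, threshold, config, okSample, channel) {
  hw <- negativeHalfwaves(x)
  empty <- data.frame(channel = character(), t_negpeak = numeric(),
                      amp_negpeak = numeric(), t_down_up = numeric(),
                      upstate_duration = numeric(),
                      upstate_amplitude = numeric())
  if (!nrow(hw)) return(empty)
  dur <- (hw$end - hw$start + 1L) / fs
  keep <- dur >= config$neg_halfwave_bounds[1] &
    dur <= config$neg_halfwave_bounds[2] &
    hw$vmin <= -threshold
  # all half-wave samples in N2/N3 and unmasked
  keep <- keep & vapply(seq_len(nrow(hw)), function(k)
    all(okSample[hw$start[k]:hw$end[k]]), logical(1))
  hw <- hw[keep, , drop = FALSE]
  if (!nrow(hw)) return(empty)

  # following positive half-wave (up state)
  up <- lapply(seq_len(nrow(hw)), function(k) {
    i <- hw$iup[k]
    if (i > length(x)) return(NULL)
    j <- i
    while (j <= length(x) && x[j] >= 0) j <- j + 1L
    if (j == i) return(NULL)          # no positive half-wave
    seg <- x[i:(j - 1L)]
    c(dur = (j - i) / fs, amp = max(seg))
  })
  has <- !vapply(up, is.null, logical(1))
  hw <- hw[has, , drop = FALSE]
  up <- do.call(rbind, up[has])
  if (!nrow(hw)) return(empty)
  data.frame(channel = channel,
             t_negpeak = (hw$imin - 1L) / fs,
             amp_negpeak = hw$vmin,
             t_down_up = (hw$iup - 1L) / fs,
             upstate_duration = up[, "dur"],
             upstate_amplitude = up[, "amp"])
}

#' Per-channel SO rate
#'
#' Events per minute of NREM2 + NREM3 sleep. Epochs that are fully inside
#' the artifact mask contribute no denominator time.
#'
#' @param events data.frame from [detectSOEvents()].
#' @param hypnogram the matching [Hypnogram-class].
#' @param eeg optional [EEGRecording-class]; when given, its artifact
#'   mask is used to exclude fully masked epochs from the denominator.
#' @param channels channels to report; defaults to those present in
#'   \code{events}.
#' @return Named numeric vector, events/minute.
#' @export
soRate <- function(events, hypnogram, eeg = NULL, channels = NULL) {
  stopifnot(is(hypnogram, "Hypnogram"))
  epl <- epochLength(hypnogram)
  isNREM <- stages(hypnogram) %in% c("N2", "N3")
  if (!any(isNREM)) stop("hypnogram has no NREM2/NREM3 epochs")
  usable <- isNREM
  if (!is.null(eeg)) {
    fs <- samplingRate(eeg)
    m <- artifactMask(eeg)
    spe <- round(epl * fs)
    fullMasked <- vapply(seq_len(nEpochs(hypnogram)), function(ep) {
      i1 <- (ep - 1L) * spe + 1L
      i2 <- min(ep * spe, length(m))
      i1 <= length(m) && all(m[i1:i2])
    }, logical(1))
    usable <- usable & !fullMasked
  }
  minutes <- sum(usable) * epl / 60
  if (minutes <= 0) stop("zero NREM2/NREM3 minutes")
  if (is.null(channels))
    channels <- unique(events$channel)
  counts <- vapply(channels, function(ch)
    sum(events$channel == ch), numeric(1))
  stats::setNames(counts / minutes, channels)
}

#' Merge detections across channels
#'
#' Single-linkage collapse of per-channel detections: events on different
#' channels whose negative peaks are within \code{merge_window} of the
#' running cluster are one physiological SO, stamped at the earliest
#' negative peak.
#'
#' @param events data.frame with at least \code{channel} and
#'   \code{t_negpeak}, sorted or not.
#' @param config a [detectionConfig()] providing \code{merge_window}.
#' @return data.frame with columns \code{t_negpeak} (earliest peak),
#'   \code{n_channels} and \code{channels} (comma-joined labels).
#' @export
mergeEventsAcrossChannels <- function(events,
                                      config = detectionConfig()) {
  if (nrow(events) == 0L)
    return(data.frame(t_negpeak = numeric(), n_channels = integer(),
                      channels = character()))
  ev <- events[order(events$t_negpeak), , drop = FALSE]
  gap <- c(Inf, diff(ev$t_negpeak))
  cluster <- cumsum(gap > config$merge_window)
  agg <- split(seq_len(nrow(ev)), cluster)
  out <- data.frame(
    t_negpeak = vapply(agg, function(i) min(ev$t_negpeak[i]), numeric(1)),
    n_channels = vapply(agg, function(i)
      length(unique(ev$channel[i])), integer(1)),
    channels = vapply(agg, function(i)
      paste(sort(unique(ev$channel[i])), collapse = ","), character(1)))
  rownames(out) <- NULL
  out
}

#' Match detected events to ground truth
#'
#' Greedy one-to-one matching of detected to true negative-peak times
#' within a tolerance, for precision/recall evaluation of the detector
#' against the generator's ground truth.
#'
#' @param detected numeric vector of detected negative-peak times, s.
#' @param truth numeric vector of true negative-peak times, s.
#' @param tol matching tolerance, s.
#' @return List with \code{tp}, \code{fp}, \code{fn}, \code{precision},
#'   \code{recall}.
#' @export
matchEvents <- function(detected, truth, tol = 0.4) {
  detected <- sort(detected); truth <- sort(truth)
  usedT <- rep(FALSE, length(truth))
  tp <- 0L
  for (d in detected) {
    j <- which(!usedT & abs(truth - d) <= tol)
    if (length(j)) {
      usedT[j[which.min(abs(truth[j] - d))]] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- length(detected) - tp
  fn <- length(truth) - tp
  list(tp = tp, fp = fp, fn = fn,
       precision = if (length(detected)) tp / length(detected) else NA,
       recall = if (length(truth)) tp / length(truth) else NA)
}
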