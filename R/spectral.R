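# Spectral layer: Welch PSD over sleep, band power, phase-locked spindle
# energy around SO up-states, and short-window multitaper coherence.

#' Frequency band set
#'
#' Named frequency intervals (Hz) used throughout the analyses. Band edges
#' are conventional and configurable; outputs are always labeled with the
#' edges used.
#'
#' @param ... name = c(low, high) overrides of the defaults.
#' @return Named list of length-2 numeric vectors, class
#'   \code{"BandSet"}.
#' @examples
#' bandSet()$delta
#' bandSet(delta = c(1, 4))$delta
#' @export
bandSet <- function(...) {
  bands <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
                sigma = c(12, 15), beta = c(15, 30), gamma = c(30, 50),
                slow_spindle = c(9, 12), fast_spindle = c(12, 15),
                so_narrow = c(0.7, 0.8), total = c(0.5, 50))
  over <- list(...)
  for (nm in names(over)) bands[[nm]] <- over[[nm]]
  for (b in bands) stopifnot(length(b) == 2L, b[1] < b[2])
  structure(bands, class = "BandSet")
}

#' Welch power spectral density over sleep
#'
#' Hann-tapered Welch average over 10-s windows with 50% overlap,
#' restricted to sleep epochs (wake excluded); windows containing any
#' masked sample are dropped, so stimulation artifacts never influence
#' the estimate. The 10-s window gives 0.1-Hz resolution, enough to
#' resolve the narrow 0.7-0.8 Hz band around the stimulation frequency.
#'
#' @param eeg an [EEGRecording-class].
#' @param hypnogram the matching [Hypnogram-class].
#' @param winSec window length, s.
#' @param overlap fractional overlap between successive windows.
#' @param channels channels to include (default all).
#' @param stageSet epochs to include (default all sleep stages).
#' @return List of class \code{"WelchPSD"}: \code{freq} (Hz), \code{psd}
#'   (frequency x channel matrix, microvolt^2/Hz), \code{nWindows}.
#' @export
psdWelch <- function(eeg, hypnogram, winSec = 10, overlap = 0.5,
                     channels = channelNames(eeg),
                     stageSet = SLEEP_STAGES) {
  stopifnot(is(eeg, "EEGRecording"), is(hypnogram, "Hypnogram"))
  fs <- samplingRate(eeg)
  nw <- round(winSec * fs)
  step <- max(1L, round(nw * (1 - overlap)))
  ok <- samplesInStages(hypnogram, fs, nSamples(eeg), stageSet) &
    !artifactMask(eeg)
  starts <- seq(1L, nSamples(eeg) - nw + 1L, by = step)
  usable <- starts[vapply(starts, function(s)
    all(ok[s:(s + nw - 1L)]), logical(1))]
  if (!length(usable))
    stop("no usable windows (sleep-stage and artifact constraints)")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))  # Hann
  U <- sum(w^2)
  nf <- nw %/% 2 + 1L
  freq <- (seq_len(nf) - 1L) * fs / nw
  sig <- signalMatrix(eeg)[, channels, drop = FALSE]
  acc <- matrix(0, nf, length(channels),
                dimnames = list(NULL, channels))
  for (s in usable) {
    seg <- sig[s:(s + nw - 1L), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg))         # detrend (mean)
    X <- stats::mvfft(seg * w)[seq_len(nf), , drop = FALSE]
    P <- (Mod(X)^2) / (fs * U)
    P[2:(nf - 1L), ] <- 2 * P[2:(nf - 1L), ]    # one-sided
    acc <- acc + P
  }
  structure(list(freq = freq, psd = acc / length(usable),
                 nWindows = length(usable)),
            class = "WelchPSD")
}

#' Band power from a PSD
#'
#' Trapezoidal integral of the spectral density over a frequency band.
#'
#' @param psd a \code{"WelchPSD"} from [psdWelch()], or any list with
#'   \code{freq} and \code{psd} elements.
#' @param band length-2 numeric, Hz.
#' @return Named numeric vector, one value per channel, microvolt^2.
#' @export
bandPower <- function(psd, band) {
  stopifnot(length(band) == 2L, band[1] < band[2])
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  if (sum(sel) < 2L)
    stop("band [", band[1], ", ", band[2],
         "] Hz contains fewer than two frequency bins")
  apply(psd$psd[sel, , drop = FALSE], 2, function(y)
    trapz(psd$freq[sel], y))
}

#' Phase-locked spindle energy during SO up-states
#'
#' For each detected SO: band-filter the channel, take the analytic
#' (Hilbert) envelope, and integrate the squared envelope over the
#' up-state window [t_down_up, t_down_up + window]. Event energies are
#' z-scored within channel and band across the session, reducing
#' between-participant amplitude variability; the per-channel mean
#' z-score is reported. Channels with fewer than 3 events are flagged
#' missing (NA). Zero-variance channels get all-zero z-scores.
#'
#' @param eeg an [EEGRecording-class].
#' @param events SO events from [detectSOEvents()] (needs \code{channel}
#'   and \code{t_down_up}).
#' @param band spindle band, Hz (e.g. \code{bandSet()$fast_spindle}).
#' @param window up-state integration window, s.
#' @return List with \code{perEvent} (events plus \code{energy},
#'   \code{z}) and \code{perChannel} (named mean-z vector, NA when
#'   undefined).
#' @export
phaseLockedSpindleEnergy <- function(eeg, events, band, window = 1.0) {
  stopifnot(is(eeg, "EEGRecording"))
  if (nrow(events) == 0L)
    return(list(perEvent = cbind(events, energy = numeric(0),
                                 z = numeric(0)),
                perChannel = stats::setNames(numeric(0), character(0))))
  fs <- samplingRate(eeg)
  n <- nSamples(eeg)
  chs <- unique(events$channel)
  perEvent <- events
  perEvent$energy <- NA_real_
  perEvent$z <- NA_real_
  perChannel <- stats::setNames(rep(NA_real_, length(chs)), chs)
  for (ch in chs) {
    idx <- which(events$channel == ch)
    filt <- bandpassFilter(channelSignal(eeg, ch), fs, band, order = 4)
    env2 <- analyticEnvelope(filt)^2
    en <- vapply(idx, function(k) {
      i1 <- round(events$t_down_up[k] * fs) + 1L
      i2 <- min(round((events$t_down_up[k] + window) * fs), n)
      if (i1 > n) return(NA_real_)
      sum(env2[i1:i2]) / fs
    }, numeric(1))
    perEvent$energy[idx] <- en
    if (length(idx) >= 3L && all(is.finite(en))) {
      s <- stats::sd(en)
      z <- if (s > 0) (en - mean(en)) / s else en * 0
      perEvent$z[idx] <- z
      perChannel[ch] <- mean(z)
    }
  }
  list(perEvent = perEvent, perChannel = perChannel)
}

# Multitaper (sine-taper) spectra of a segment matrix (samples x
# channels): returns freq, per-channel eigenspectra array X
# [nfreq x ch x k] and auto-spectra Sxx [nfreq x ch].
mtSpectra <- function(seg, fs, k = 3) {
  n <- nrow(seg)
  tp <- sineTapers(n, k)
  nf <- n %/% 2 + 1L
  X <- array(0i, c(nf, ncol(seg), k))
  for (j in seq_len(k))
    X[, , j] <- stats::mvfft(seg * tp[j, ])[seq_len(nf), , drop = FALSE]
  Sxx <- apply(X, c(1, 2), function(v) mean(Mod(v)^2)) / fs
  Sxx[2:(nf - 1L), ] <- 2 * Sxx[2:(nf - 1L), ]
  list(freq = (seq_len(nf) - 1L) * fs / n, X = X, Sxx = Sxx)
}

#' Short-window multitaper coherence matrix
#'
#' Magnitude-squared coherence between all unordered channel pairs on a
#' single analysis window, band-averaged. A multitaper estimate (3 sine
#' tapers by default) keeps the coherence defined on windows as short as
#' 1 s without sub-segmentation; with K tapers the no-coupling bias is
#' about 1/K.
#'
#' @param eeg an [EEGRecording-class].
#' @param window c(start, end) of the analysis window, s.
#' @param band frequency band to average over, Hz.
#' @param channels channels to include (>= 2).
#' @param k number of sine tapers.
#' @return List with \code{matrix} (channel x channel, 1 on the
#'   diagonal) and \code{mean} (average over unordered pairs).
#' @export
coherenceMatrix <- function(eeg, window, band,
                            channels = channelNames(eeg), k = 3) {
  stopifnot(is(eeg, "EEGRecording"), length(channels) >= 2L,
            length(window) == 2L, window[1] < window[2])
  fs <- samplingRate(eeg)
  i1 <- round(window[1] * fs) + 1L
  i2 <- min(round(window[2] * fs), nSamples(eeg))
  if (any(artifactMask(eeg)[i1:i2]))
    stop("analysis window overlaps the artifact mask")
  seg <- signalMatrix(eeg)[i1:i2, channels, drop = FALSE]
  seg <- sweep(seg, 2, colMeans(seg))
  mt <- mtSpectra(seg, fs, k)
  sel <- mt$freq >= band[1] & mt$freq <= band[2]
  if (!any(sel)) stop("band contains no frequency bins for this window")
  nch <- length(channels)
  C <- diag(1, nch)
  dimnames(C) <- list(channels, channels)
  for (a in seq_len(nch - 1L)) {
    for (b in (a + 1L):nch) {
      Sxy <- rowMeans(mt$X[, a, , drop = FALSE][, 1, ] *
                        Conj(mt$X[, b, , drop = FALSE][, 1, ]))
      Sxx <- rowMeans(Mod(mt$X[, a, , drop = FALSE][, 1, ])^2)
      Syy <- rowMeans(Mod(mt$X[, b, , drop = FALSE][, 1, ])^2)
      coh <- Mod(Sxy)^2 / (Sxx * Syy)
      C[a, b] <- C[b, a] <- mean(coh[sel])
    }
  }
  list(matrix = C, mean = mean(C[upper.tri(C)]))
}
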