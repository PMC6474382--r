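# Retrospective per-stimulation analysis: 1-s pre-stimulation
# power/coherence features versus the number of SOs in the 20 s after
# artifact recovery, stratified by sleep stage.

PRESTIM_CHANNELS <- c("Fp1", "Fp2", "F7", "Fz", "FC1")

#' Pre-stimulation spectral features
#'
#' For each stimulation cycle, computes per-band mean spectral power
#' (measured per channel on the 1-s window [onset - 1, onset) with the
#' multitaper estimator, then averaged across the channel set) and mean
#' pairwise coherence (all unordered pairs of the set). Events whose
#' pre-window overlaps the artifact mask of an earlier cycle are dropped
#' and reported in the \code{"dropped"} attribute.
#'
#' @param eeg an [EEGRecording-class].
#' @param stimEvents fired cycles from [scheduleStimulation()].
#' @param bands a [bandSet()]; the named analysis bands (delta, theta,
#'   alpha, sigma, beta, gamma, total by default).
#' @param channels channel set (default the five channels with the
#'   strongest SO-rate response: Fp1, Fp2, F7, Fz, FC1).
#' @param bandNames which bands to evaluate.
#' @param k sine tapers for the 1-s estimates.
#' @return Long-format data.frame: \code{stim_id}, \code{stage},
#'   \code{band}, \code{power}, \code{coherence}; attribute
#'   \code{"dropped"} lists skipped stim ids.
#' @export
prestimFeatures <- function(eeg, stimEvents, bands = bandSet(),
                            channels = PRESTIM_CHANNELS,
                            bandNames = c("delta", "theta", "alpha",
                                          "sigma", "beta", "gamma",
                                          "total"),
                            k = 3) {
  stopifnot(is(eeg, "EEGRecording"))
  fs <- samplingRate(eeg)
  mask <- artifactMask(eeg)
  rows <- list()
  dropped <- integer()
  for (i in seq_len(nrow(stimEvents))) {
    on <- stimEvents$onset[i]
    i1 <- round((on - 1) * fs) + 1L
    i2 <- round(on * fs)
    if (i1 < 1L || any(mask[i1:i2])) {
      dropped <- c(dropped, i)
      next
    }
    seg <- signalMatrix(eeg)[i1:i2, channels, drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg))
    mt <- mtSpectra(seg, fs, k)
    # pairwise coherence spectra, reused across bands
    nch <- length(channels)
    pairCoh <- list()
    p <- 0L
    for (a in seq_len(nch - 1L)) for (b in (a + 1L):nch) {
      Sxy <- rowMeans(mt$X[, a, , drop = FALSE][, 1, ] *
                        Conj(mt$X[, b, , drop = FALSE][, 1, ]))
      Sxx <- rowMeans(Mod(mt$X[, a, , drop = FALSE][, 1, ])^2)
      Syy <- rowMeans(Mod(mt$X[, b, , drop = FALSE][, 1, ])^2)
      p <- p + 1L
      pairCoh[[p]] <- Mod(Sxy)^2 / (Sxx * Syy)
    }
    cohSpec <- Reduce(`+`, pairCoh) / length(pairCoh)
    for (bn in bandNames) {
      bd <- bands[[bn]]
      sel <- mt$freq >= bd[1] & mt$freq <= bd[2]
      if (!any(sel)) next
      pw <- mean(vapply(seq_along(channels), function(j)
        if (sum(sel) >= 2L) trapz(mt$freq[sel], mt$Sxx[sel, j]) else
          mean(mt$Sxx[sel, j]), numeric(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        stim_id = i,
        stage = as.character(stimEvents$stage_at_onset[i]),
        band = bn, power = pw, coherence = mean(cohSpec[sel]))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stim_id = integer(), stage = character(),
               band = character(), power = numeric(),
               coherence = numeric())
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Post-stimulation SO count
#'
#' Number of merged SO events whose negative peak falls in the first 20 s
#' after recovery from the stimulation artifact, i.e. in
#' (artifact_end, artifact_end + window]. The right boundary is closed.
#'
#' @param mergedEvents merged cross-channel events from
#'   [mergeEventsAcrossChannels()] (detections restricted to the
#'   responding channel set before merging).
#' @param stimEvents fired cycles from [scheduleStimulation()].
#' @param window counting window after artifact end, s.
#' @return Integer vector, one count per stimulation.
#' @export
poststimSOCount <- function(mergedEvents, stimEvents, window = 20) {
  vapply(seq_len(nrow(stimEvents)), function(i) {
    a <- stimEvents$artifact_end[i]
    sum(mergedEvents$t_negpeak > a &
          mergedEvents$t_negpeak <= a + window)
  }, integer(1))
}

#' Pre-stimulation predictors of stimulation efficacy
#'
#' Spearman rank correlation (mid-rank ties, p from the t-approximation)
#' between each pre-stimulation feature (power and coherence per band)
#' and the post-stimulation SO count, separately for stimulations
#' delivered in NREM3 and NREM2. Strata with fewer than \code{minN}
#' outcomes, or with a constant feature or outcome, are flagged NA.
#'
#' @param features long-format table from [prestimFeatures()].
#' @param counts integer vector from [poststimSOCount()], indexed by
#'   \code{stim_id}.
#' @param strata stage strata to report.
#' @param minN minimum outcomes per stratum.
#' @return data.frame: \code{stage}, \code{band}, \code{measure}
#'   (power/coherence), \code{n}, \code{r}, \code{p}.
#' @export
correlateEfficacy <- function(features, counts,
                              strata = c("N3", "N2"), minN = 10) {
  rows <- list()
  for (stg in strata) {
    sub <- features[features$stage == stg, , drop = FALSE]
    for (bn in unique(sub$band)) {
      bsub <- sub[sub$band == bn, , drop = FALSE]
      y <- counts[bsub$stim_id]
      for (meas in c("power", "coherence")) {
        x <- bsub[[meas]]
        ok <- is.finite(x) & is.finite(y)
        r <- p <- NA_real_
        if (sum(ok) >= minN && stats::sd(x[ok]) > 0 &&
            stats::sd(y[ok]) > 0) {
          ct <- suppressWarnings(
            stats::cor.test(x[ok], y[ok], method = "spearman",
                            exact = FALSE))
          r <- unname(ct$estimate)
          p <- ct$p.value
        }
        rows[[length(rows) + 1L]] <- data.frame(
          stage = stg, band = bn, measure = meas, n = sum(ok),
          r = r, p = p)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
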